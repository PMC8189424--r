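# shared test constructors: everything is generated in code

# a small, deterministic instrument table with non-trivial heterogeneity
toy_instruments <- function(J = 6, seed = 101, theta = 0.1, alpha = 0) {
  set.seed(seed)
  beta_exp <- runif(J, 0.04, 0.12)
  se_exp <- runif(J, 0.005, 0.012)
  se_out <- runif(J, 0.005, 0.012)
  beta_out <- theta * beta_exp + alpha + rnorm(J, 0, 0.004)
  as_mr_instruments(data.frame(
    rsid = sprintf("rs%d", seq_len(J)),
    beta_exp = beta_exp, se_exp = se_exp,
    beta_out = beta_out, se_out = se_out))
}

# a valid summary dataset for IO round-trips
toy_dataset <- function(J = 5, seed = 7, n = 10000) {
  set.seed(seed)
  alleles <- c("A", "C", "G", "T")
  ea <- sample(alleles, J, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1), "")
  summary_dataset(data.frame(
    rsid = sprintf("rs%d", seq_len(J)),
    effect_allele = ea, other_allele = unname(oa),
    eaf = round(runif(J, 0.05, 0.95), 4),
    beta = round(rnorm(J, 0, 0.05), 5),
    se = round(runif(J, 0.004, 0.02), 5),
    pvalue = round(runif(J, 1e-12, 0.9), 14),
    n = n), trait_name = "toy", trait_type = "continuous")
}

fixture_instruments <- function() {
  fx <- load_fixture_hcy_af()
  harmonize(fx$exposure, fx$outcome)
}

# quiet estimator config for fast bootstrap-based tests
fast_cfg <- function(seed = 42) estimator_config(n_boot = 200, seed = seed)
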