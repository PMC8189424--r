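#' Simulation configuration for synthetic two-sample summary statistics
#'
#' Generative parameters for summary-level simulation of a continuous
#' exposure GWAS and a binary-outcome GWAS sharing a set of independent
#' SNPs, with a known causal effect and an explicit pleiotropy law.
#'
#' @param n_snps number of SNPs J.
#' @param n_exposure exposure GWAS sample size.
#' @param n_outcome outcome GWAS sample size.
#' @param theta true causal effect (log-odds per SD of exposure).
#' @param eaf_range interval for effect-allele frequencies (default
#'   0.05-0.95).
#' @param exposure_effect_sd SD of the true per-SNP exposure effects
#'   \eqn{\gamma_j} (SD units; default 0.06, the scale of instruments a
#'   well-powered biomarker GWAS yields).
#' @param pleiotropy_mean mean direct (pleiotropic) effect on the outcome,
#'   log-odds (0 = no directional pleiotropy).
#' @param pleiotropy_sd SD of the per-SNP pleiotropic effects.
#' @param inside_violation when TRUE, the pleiotropic effect gains a
#'   component proportional to \eqn{\gamma_j}, breaking the InSiDE
#'   assumption.
#' @param allow_weak when FALSE (default), \eqn{\gamma_j} is resampled until
#'   the per-SNP F-statistic at `n_exposure` exceeds 10.
#' @param seed integer seed; identical configurations generate identical
#'   datasets.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 50, n_exposure = 44147, n_outcome = 100000,
                       theta = 0, eaf_range = c(0.05, 0.95),
                       exposure_effect_sd = 0.06, pleiotropy_mean = 0,
                       pleiotropy_sd = 0, inside_violation = FALSE,
                       allow_weak = FALSE, seed = 1L) {
  stopifnot(n_snps >= 1, n_exposure >= 10, n_outcome >= 10,
            length(eaf_range) == 2, eaf_range[1] > 0, eaf_range[2] < 1,
            eaf_range[1] <= eaf_range[2], exposure_effect_sd > 0,
            pleiotropy_sd >= 0)
  structure(list(n_snps = as.integer(n_snps), n_exposure = n_exposure,
                 n_outcome = n_outcome, theta = theta,
                 eaf_range = eaf_range,
                 exposure_effect_sd = exposure_effect_sd,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 inside_violation = inside_violation,
                 allow_weak = allow_weak, seed = as.integer(seed)),
            class = "sim_config")
}

# outcome-GWAS case fraction baked into the generator's SE law
.sim_case_fraction <- 0.1

#' Simulate two-sample GWAS summary statistics with known truth
#'
#' Summary-level generation under the standard normal measurement model.
#' Per SNP j: `eaf_j ~ U(eaf_range)`; true exposure effect
#' `gamma_j ~ N(0, exposure_effect_sd^2)` (resampled until the implied
#' per-SNP F at `n_exposure` exceeds 10 unless `allow_weak`);
#' `se_Xj = 1/sqrt(2 eaf (1-eaf) n_exposure)` and
#' `beta_Xj ~ N(gamma_j, se_Xj^2)`; pleiotropic effect
#' `alpha_j ~ N(pleiotropy_mean, pleiotropy_sd^2)`, shifted by
#' `0.5 * gamma_j` under `inside_violation`;
#' `se_Yj = 1/sqrt(2 eaf (1-eaf) n_outcome K (1-K))` with the case fraction
#' K fixed at 0.1, and `beta_Yj ~ N(theta * gamma_j + alpha_j, se_Yj^2)`.
#' P-values are two-sided normal.
#'
#' @param cfg a [sim_config()].
#' @return list with `exposure` and `outcome` (`summary_dataset`s over
#'   `snp1..snpJ`, alleles A/G pre-aligned) and `truth` (list: `theta`,
#'   `gamma`, `alpha`, `case_fraction`, `seed`).
#' @export
simulate_summary_stats <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed, {
    J <- cfg$n_snps
    eaf <- stats::runif(J, cfg$eaf_range[1], cfg$eaf_range[2])
    gamma <- stats::rnorm(J, 0, cfg$exposure_effect_sd)
    if (!cfg$allow_weak) {
      for (j in seq_len(J)) {
        repeat {
          r2 <- 2 * eaf[j] * (1 - eaf[j]) * gamma[j]^2
          if (f_statistic(r2, cfg$n_exposure) > 10) break
          gamma[j] <- stats::rnorm(1, 0, cfg$exposure_effect_sd)
        }
      }
    }
    # report every SNP for its exposure-increasing allele, the convention
    # of published instrument tables; the pleiotropy law applies to that
    # oriented allele
    gamma <- abs(gamma)
    se_x <- 1 / sqrt(2 * eaf * (1 - eaf) * cfg$n_exposure)
    beta_x <- stats::rnorm(J, gamma, se_x)
    alpha <- stats::rnorm(J, cfg$pleiotropy_mean, cfg$pleiotropy_sd)
    if (cfg$inside_violation) alpha <- alpha + 0.5 * gamma
    K <- .sim_case_fraction
    se_y <- 1 / sqrt(2 * eaf * (1 - eaf) * cfg$n_outcome * K * (1 - K))
    beta_y <- stats::rnorm(J, cfg$theta * gamma + alpha, se_y)
    rsid <- sprintf("snp%d", seq_len(J))
    mk <- function(beta, se, n, trait, type) {
      p <- 2 * stats::pnorm(-abs(beta / se))
      p[p == 0] <- .Machine$double.xmin
      summary_dataset(data.frame(
        rsid = rsid, effect_allele = "A", other_allele = "G", eaf = eaf,
        beta = beta, se = se, pvalue = p, n = n,
        stringsAsFactors = FALSE), trait_name = trait, trait_type = type)
    }
    list(exposure = mk(beta_x, se_x, cfg$n_exposure, "simulated exposure",
                       "continuous"),
         outcome = mk(beta_y, se_y, cfg$n_outcome, "simulated outcome",
                      "binary"),
         truth = list(theta = cfg$theta, gamma = gamma, alpha = alpha,
                      case_fraction = K, seed = cfg$seed))
  })
}

#' Block-structured LD scenario
#'
#' Builds a block-diagonal LD matrix over the rsids of a dataset: `within_r2`
#' inside each block, 0 across blocks, 1 on the diagonal. rsids not covered
#' by any block become singletons. Useful for known-answer pruning tests.
#'
#' @param base a `summary_dataset` (or anything with an `rsid` column).
#' @param blocks list of character vectors partitioning (a subset of) the
#'   rsids; overlapping blocks are an error.
#' @param within_r2 r2 shared by all pairs inside a block.
#' @return an `ld_matrix` over all rsids of `base`.
#' @export
make_ld_scenario <- function(base, blocks, within_r2) {
  stopifnot(within_r2 >= 0, within_r2 <= 1)
  rsids <- base$rsid
  flat <- unlist(blocks)
  if (anyDuplicated(flat))
    stop("make_ld_scenario: blocks overlap")
  if (length(setdiff(flat, rsids)))
    stop("make_ld_scenario: blocks name rsids absent from the dataset")
  m <- matrix(0, length(rsids), length(rsids),
              dimnames = list(rsids, rsids))
  for (b in blocks) {
    m[b, b] <- within_r2
  }
  diag(m) <- 1
  ld_matrix(m)
}
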