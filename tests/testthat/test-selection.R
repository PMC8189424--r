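make_ds <- function(rsid, pvalue, eaf = 0.5, beta = 0.05, se = 0.007,
                    n = 44147) {
  summary_dataset(data.frame(
    rsid = rsid, effect_allele = "A", other_allele = "G", eaf = eaf,
    beta = beta, se = se, pvalue = pvalue, n = n),
    trait_name = "exposure", trait_type = "continuous")
}

test_that("genome-wide filtering uses a strict threshold", {
  ds <- make_ds(c("rs1", "rs2", "rs3"), c(1e-9, 5e-8, 4.99e-8))
  kept <- filter_genomewide(ds, 5e-8)
  expect_setequal(kept$rsid, c("rs1", "rs3"))  # exactly 5e-8 is dropped
  empty <- summary_dataset(data.frame(
    rsid = character(0), effect_allele = character(0),
    other_allele = character(0), eaf = numeric(0), beta = numeric(0),
    se = numeric(0), pvalue = numeric(0), n = numeric(0)))
  expect_identical(nrow(filter_genomewide(empty)), 0L)
  # the whole fixture survives: its largest p is 1.97e-8
  fx <- load_fixture_hcy_af()
  expect_identical(nrow(filter_genomewide(fx$exposure)), 9L)
  expect_lt(max(fx$exposure$pvalue), 5e-8)
})

test_that("LD pruning drops the most-correlated SNP first", {
  ds <- make_ds(c("a", "b", "c"), rep(1e-9, 3))
  ld <- ld_matrix_from_pairs(c("a", "a"), c("b", "c"), c(0.9, 0.9),
                             rsids = c("a", "b", "c"))
  pr <- ld_prune(ds, ld, 0.001)
  expect_setequal(pr$dataset$rsid, c("b", "c"))
  expect_identical(pr$audit$action[pr$audit$rsid == "a"], "dropped")
})

test_that("LD pruning ties break by the larger exposure p-value", {
  ds <- make_ds(c("a", "b"), c(1e-9, 1e-8))
  ld <- ld_matrix_from_pairs("a", "b", 0.5)
  pr <- ld_prune(ds, ld, 0.001)
  expect_identical(pr$dataset$rsid, "a")
})

test_that("LD pruning below threshold is the identity", {
  ds <- make_ds(c("a", "b", "c"), rep(1e-9, 3))
  ld <- ld_matrix_from_pairs("a", "b", 0.0009, rsids = c("a", "b", "c"))
  pr <- ld_prune(ds, ld, 0.001)
  expect_identical(pr$dataset$rsid, c("a", "b", "c"))
  expect_true(all(pr$audit$action == "kept"))
})

test_that("LD pruning is order-invariant without ties and deterministic with", {
  set.seed(5)
  ids <- sprintf("rs%d", 1:8)
  ds <- make_ds(ids, pvalue = sample(seq(1e-12, 1e-9, length.out = 8)))
  pairs <- t(combn(ids, 2))
  r2 <- ifelse(runif(nrow(pairs)) < 0.3, runif(nrow(pairs), 0.1, 0.9), 0)
  ld <- ld_matrix_from_pairs(pairs[, 1], pairs[, 2], r2, rsids = ids)
  ref <- sort(ld_prune(ds, ld, 0.001)$dataset$rsid)
  for (i in 1:5) {
    perm <- sample(nrow(ds))
    shuffled <- summary_dataset(as.data.frame(ds)[perm, ],
                                trait_name = "exposure")
    expect_identical(sort(ld_prune(shuffled, ld, 0.001)$dataset$rsid), ref)
  }
  # equal p everywhere: the lexicographic final key still gives one answer
  ds_tie <- make_ds(ids, rep(1e-9, 8))
  expect_identical(ld_prune(ds_tie, ld, 0.001)$dataset$rsid,
                   ld_prune(ds_tie, ld, 0.001)$dataset$rsid)
})

test_that("confounder-annotated SNPs are excluded at the strict threshold", {
  ds <- make_ds(c("rs2251468", "rs2"), c(1e-9, 1e-9))
  ann <- data.frame(rsid = c("rs2251468", "rs2"),
                    trait = c("Coronary artery disease", "height"),
                    pvalue = c(1e-9, 1e-10))
  cfg <- selection_config(confounder_traits = "coronary artery disease")
  res <- exclude_confounder_associated(ds, ann, cfg)
  expect_identical(res$dataset$rsid, "rs2")
  expect_match(res$audit$reason[res$audit$rsid == "rs2251468"],
               "Coronary artery disease")
  # sub-threshold annotation does not exclude
  ann$pvalue[1] <- 1e-6
  expect_identical(nrow(exclude_confounder_associated(ds, ann, cfg)$dataset), 2L)
  # empty annotation table is the identity
  empty <- ann[0, ]
  expect_identical(nrow(exclude_confounder_associated(ds, empty, cfg)$dataset), 2L)
})

test_that("outcome resolution keeps, proxies, and excludes correctly", {
  fx <- load_fixture_hcy_af()
  res <- resolve_in_outcome(fx$exposure, fx$outcome)
  expect_identical(nrow(res$pairs), 9L)
  expect_true(all(is.na(res$pairs$proxy_rsid)))
  expect_true(all(res$audit$action == "kept"))
  expect_gt(min(fx$outcome$pvalue), 0.05)  # none near genome-wide significance

  # absent SNP with a strong proxy gets substituted
  out <- summary_dataset(
    transform(as.data.frame(fx$outcome),
              rsid = sub("^rs12134663$", "rs_proxy", rsid)),
    trait_name = "af", trait_type = "binary")
  ld <- ld_matrix_from_pairs("rs12134663", "rs_proxy", 0.95)
  res2 <- resolve_in_outcome(fx$exposure, out, proxies = ld)
  expect_identical(nrow(res2$pairs), 9L)
  prow <- res2$pairs[res2$pairs$rsid == "rs12134663", ]
  expect_identical(prow$proxy_rsid, "rs_proxy")
  expect_identical(
    res2$audit$action[res2$audit$rsid == "rs12134663"], "proxied")
  # the proxy row stands in under the exposure SNP's rsid
  expect_true("rs12134663" %in% res2$outcome$rsid)

  # a direct outcome association excludes the SNP
  out2 <- as.data.frame(fx$outcome)
  out2$pvalue[out2$rsid == "rs838133"] <- 1e-9
  res3 <- resolve_in_outcome(
    fx$exposure, summary_dataset(out2, trait_name = "af", trait_type = "binary"))
  expect_identical(nrow(res3$pairs), 8L)
  expect_identical(res3$audit$action[res3$audit$rsid == "rs838133"], "dropped")
})

test_that("variance explained follows 2p(1-p)b^2 with EAF symmetry", {
  expect_equal(variance_explained(0.2, 0.101), 0.00326432, tolerance = 1e-8)
  expect_equal(variance_explained(0.5, 0), 0)
  expect_equal(variance_explained(0.3, 0.07), variance_explained(0.7, 0.07))
  expect_error(variance_explained(NA, 0.1), "missing")
})

test_that("F statistics reproduce the fixture's printed integers", {
  fx <- load_fixture_hcy_af()
  st <- instrument_strength(fx$exposure)
  printed <- c(rs12134663 = 145, rs12780845 = 56, rs1801222 = 41,
               rs2275565 = 43, rs234709 = 113, rs42648 = 33,
               rs4660306 = 37, rs7130284 = 89, rs838133 = 39)
  expect_equal(round(st$f[match(names(printed), st$rsid)]),
               unname(printed))
  expect_true(all(st$f > 10))
  expect_equal(f_statistic(0, 100), 0)
})

test_that("f_statistic is strictly increasing in r2 and n", {
  r2 <- seq(0.001, 0.2, length.out = 20)
  expect_true(all(diff(f_statistic(r2, 1000)) > 0))
  n <- seq(100, 10000, length.out = 20)
  expect_true(all(diff(f_statistic(0.01, n)) > 0))
})

test_that("the full selection pipeline reduces 18 candidates to the 9 instruments", {
  fx <- load_fixture_hcy_af()
  ld_drops <- c("rs12921383", "rs1801133", "rs2851391", "rs957140")
  conf_drops <- c("rs154657", "rs2251468", "rs548987", "rs7422339", "rs9369898")
  extra <- make_ds(c(ld_drops, conf_drops),
                   pvalue = rep(2e-8, 9), beta = 0.04)
  cands <- summary_dataset(rbind(as.data.frame(fx$exposure),
                                 as.data.frame(extra)),
                           trait_name = "homocysteine")
  expect_identical(nrow(cands), 18L)
  # each LD-dropped SNP is correlated with one retained instrument and has
  # the larger p-value
  keepers <- c("rs12134663", "rs234709", "rs12780845", "rs42648")
  ld <- ld_matrix_from_pairs(keepers, ld_drops, rep(0.9, 4),
                             rsids = cands$rsid)
  ann <- data.frame(
    rsid = conf_drops,
    trait = c("hypertension", "coronary artery disease", "body mass index",
              "cholesterol", "cholesterol"),
    pvalue = rep(1e-10, 5))
  cfg <- selection_config(confounder_traits = c(
    "hypertension", "coronary artery disease", "body mass index",
    "cholesterol"))
  sel <- select_instruments(cands, fx$outcome, ld = ld, annotations = ann,
                            config = cfg)
  expect_setequal(sel$exposure$rsid, fx$exposure$rsid)
  expect_identical(nrow(sel$exposure), 9L)
  expect_true(all(sel$strength$f > 10))
  # audit conservation at every stage: kept + proxied + dropped = stage input
  audit <- sel$audit
  counts <- table(audit$stage)
  expect_identical(unname(counts[["pthreshold"]]), 18L)
  expect_identical(unname(counts[["ld_prune"]]), 18L)
  expect_identical(unname(counts[["confounder"]]), 14L)
  expect_identical(unname(counts[["outcome_assoc"]]), 9L)
  ld_stage <- audit[audit$stage == "ld_prune", ]
  expect_setequal(ld_stage$rsid[ld_stage$action == "dropped"], ld_drops)
  cf_stage <- audit[audit$stage == "confounder", ]
  expect_setequal(cf_stage$rsid[cf_stage$action == "dropped"], conf_drops)
})
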