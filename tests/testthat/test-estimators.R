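test_that("IVW equals weighted least squares through the origin", {
  # independent oracle: lm of beta_out on beta_exp without intercept,
  # weights 1/se_out^2, matches the closed-form ratio meta-analysis
  for (seed in c(1, 2, 3)) {
    instr <- toy_instruments(J = 8, seed = seed)
    fit <- ivw_fixed(instr)
    wls <- lm(beta_out ~ beta_exp - 1, data = instr,
              weights = 1 / instr$se_out^2)
    expect_equal(fit$beta, unname(coef(wls)), tolerance = 1e-12)
  }
})

test_that("single-instrument IVW reduces to the Wald ratio", {
  instr <- toy_instruments(J = 1)
  fit <- ivw_fixed(instr)
  expect_equal(fit$beta, instr$ratio)
  expect_equal(fit$se, instr$ratio_se)
  expect_error(ivw_fixed(instr[0, ]), "at least 1")
})

test_that("fixture IVW matches the frozen hand computation", {
  instr <- fixture_instruments()
  fit <- ivw_fixed(instr)
  expect_equal(fit$beta, 0.0739114, tolerance = 1e-6)
  expect_equal(fit$se, 0.0415123, tolerance = 1e-6)
  expect_equal(fit$q_statistic, 2.542048, tolerance = 1e-5)
  expect_identical(fit$q_df, 8)
  expect_equal(round(fit$or_, 3), 1.077)
  expect_equal(round(c(fit$or_low, fit$or_high), 3), c(0.993, 1.168))
  expect_equal(exp(fit$beta), fit$or_)
  expect_true(fit$ci_low <= fit$beta && fit$beta <= fit$ci_high)
})

test_that("random-effects IVW applies the truncated multiplicative scale", {
  instr <- fixture_instruments()
  fe <- ivw_fixed(instr); re <- ivw_random(instr)
  # fixture is under-dispersed: Q/(J-1) < 1 so the rows coincide
  expect_lt(fe$q_statistic / fe$q_df, 1)
  expect_equal(re$beta, fe$beta)
  expect_equal(re$se, fe$se)
  # inflate heterogeneity: the scale must bite
  noisy <- instr
  noisy$ratio <- noisy$ratio + rep_len(c(0.5, -0.5), nrow(noisy))
  noisy <- as_mr_instruments(as.data.frame(noisy))
  fe2 <- ivw_fixed(noisy); re2 <- ivw_random(noisy)
  expect_gt(fe2$q_statistic / fe2$q_df, 1)
  expect_gt(re2$se, fe2$se)
  expect_equal(re2$beta, fe2$beta)
  # two identical instruments: Q = 0, RE = FE
  twin <- as_mr_instruments(data.frame(
    beta_exp = c(0.1, 0.1), se_exp = c(0.01, 0.01),
    beta_out = c(0.02, 0.02), se_out = c(0.01, 0.01)))
  expect_equal(ivw_random(twin)$se, ivw_fixed(twin)$se)
  expect_equal(ivw_fixed(twin)$q_statistic, 0)
})

test_that("maximum likelihood matches a dense grid search on small instances", {
  # oracle: brute-force the profile negative log-likelihood on a fine grid
  for (seed in c(4, 9)) {
    instr <- toy_instruments(J = 3, seed = seed)
    fit <- max_likelihood(instr)
    grid <- seq(fit$beta - 0.5, fit$beta + 0.5, length.out = 20001)
    nll <- vapply(grid, function(th) {
      g <- (instr$beta_exp / instr$se_exp^2 + th * instr$beta_out / instr$se_out^2) /
        (1 / instr$se_exp^2 + th^2 / instr$se_out^2)
      sum((instr$beta_exp - g)^2 / (2 * instr$se_exp^2) +
            (instr$beta_out - th * g)^2 / (2 * instr$se_out^2))
    }, numeric(1))
    expect_equal(fit$beta, grid[which.min(nll)], tolerance = 1e-4)
  }
})

test_that("maximum likelihood approaches IVW as exposure SEs vanish", {
  instr <- toy_instruments(J = 6, seed = 2)
  instr$se_exp <- rep(1e-8, 6)
  instr <- as_mr_instruments(as.data.frame(instr))
  expect_equal(max_likelihood(instr)$beta, ivw_fixed(instr)$beta,
               tolerance = 1e-6)
})

test_that("fixture maximum likelihood reproduces the published row", {
  fit <- max_likelihood(fixture_instruments())
  expect_equal(round(fit$or_, 3), 1.077)
  expect_equal(round(fit$or_high, 3), 1.169)
})

test_that("Egger regression recovers constructed directional pleiotropy", {
  # by construction: beta_out = alpha + theta * beta_exp exactly, so the
  # weighted regression must return (alpha, theta) with zero residuals
  set.seed(31)
  bx <- runif(6, 0.03, 0.12)
  instr <- as_mr_instruments(data.frame(
    beta_exp = bx, se_exp = runif(6, 0.004, 0.01),
    beta_out = 0.05 + 0.2 * bx, se_out = runif(6, 0.004, 0.01)))
  fit <- mr_egger(instr)
  expect_equal(fit$beta, 0.2, tolerance = 1e-8)
  expect_equal(fit$intercept, 0.05, tolerance = 1e-8)
  # noisy version: estimates near truth
  instr2 <- toy_instruments(J = 40, seed = 8, theta = 0.2, alpha = 0.05)
  fit2 <- mr_egger(instr2)
  expect_lt(abs(fit2$intercept - 0.05), 0.02)
  expect_lt(abs(fit2$beta - 0.2), 0.1)
})

test_that("fixture Egger matches the published slope and intercept", {
  fit <- mr_egger(fixture_instruments())
  expect_equal(round(fit$or_, 3), 1.071)
  expect_equal(round(c(fit$or_low, fit$or_high), 3), c(0.856, 1.340))
  expect_equal(round(fit$intercept, 3), 0)
  expect_equal(round(fit$intercept_se, 3), 0.007)
  expect_equal(round(c(fit$intercept_ci_low, fit$intercept_ci_high), 3),
               c(-0.013, 0.014))
  expect_equal(round(fit$intercept_p, 3), 0.958)
})

test_that("Egger orientation makes the fit invariant to allele flips", {
  instr <- toy_instruments(J = 10, seed = 14, theta = 0.15, alpha = 0.02)
  flipped <- as.data.frame(instr)
  flip <- c(rep(-1, 4), rep(1, 6))
  flipped$beta_exp <- flipped$beta_exp * flip
  flipped$beta_out <- flipped$beta_out * flip
  f1 <- mr_egger(instr)
  f2 <- mr_egger(as_mr_instruments(flipped))
  expect_equal(f2$beta, f1$beta)
  expect_equal(f2$intercept, f1$intercept)
  expect_equal(f2$se, f1$se)
})

test_that("median estimators follow the half-step interpolation convention", {
  instr <- fixture_instruments()
  fit_s <- median_estimator(instr, weighted = FALSE, cfg = fast_cfg())
  fit_w <- median_estimator(instr, weighted = TRUE, cfg = fast_cfg())
  expect_equal(round(fit_s$or_, 3), 1.114)
  expect_equal(round(fit_w$or_, 3), 1.106)
  # equal weights, odd J: estimate lies between the two central order stats
  r <- sort(instr$ratio)
  expect_gte(fit_s$beta, r[4]); expect_lte(fit_s$beta, r[6])
  # all ratios identical: the estimate is that value
  same <- as_mr_instruments(data.frame(
    beta_exp = rep(0.1, 4), se_exp = 0.01,
    beta_out = rep(0.02, 4), se_out = c(0.01, 0.02, 0.01, 0.02)))
  expect_equal(median_estimator(same, TRUE, fast_cfg())$beta, 0.2)
  expect_error(median_estimator(instr[1:2, ]), "at least 3")
})

test_that("mode estimators locate the kernel-density argmax", {
  instr <- fixture_instruments()
  fit_s <- mode_estimator(instr, weighted = FALSE, cfg = fast_cfg())
  fit_w <- mode_estimator(instr, weighted = TRUE, cfg = fast_cfg())
  expect_equal(fit_s$or_, 1.121, tolerance = 0.005)
  expect_equal(fit_w$or_, 1.108, tolerance = 0.005)
  # a dominant cluster pulls the mode to itself regardless of outliers
  clustered <- as_mr_instruments(data.frame(
    beta_exp = rep(0.1, 7), se_exp = 0.01,
    beta_out = c(rep(0.020, 5), 0.09, -0.06) + (1:7) * 1e-4,
    se_out = 0.01))
  fit_c <- mode_estimator(clustered, weighted = FALSE, cfg = fast_cfg())
  expect_equal(fit_c$beta, 0.2, tolerance = 0.02)
  # degenerate: all ratios identical
  same <- as_mr_instruments(data.frame(
    beta_exp = rep(0.1, 4), se_exp = 0.01,
    beta_out = rep(0.02, 4), se_out = 0.01))
  expect_equal(mode_estimator(same, FALSE, fast_cfg())$beta, 0.2)
})

test_that("negating every outcome beta negates every estimate", {
  instr <- toy_instruments(J = 9, seed = 19, theta = 0.12)
  neg <- as.data.frame(instr)
  neg$beta_out <- -neg$beta_out
  neg$ratio <- NULL; neg$ratio_se <- NULL  # recompute from the flipped betas
  neg <- as_mr_instruments(neg)
  cfg <- fast_cfg()
  for (m in c("ivw_fixed", "ivw_random", "max_likelihood", "simple_median",
              "weighted_median", "simple_mode", "weighted_mode", "egger")) {
    f1 <- mrkit:::.run_method(m, instr, cfg)
    f2 <- mrkit:::.run_method(m, neg, cfg)
    expect_equal(f2$beta, -f1$beta, tolerance = 1e-6,
                 label = sprintf("%s sign equivariance", m))
  }
})

test_that("bootstrap SEs are reproducible under a fixed seed", {
  instr <- fixture_instruments()
  a <- median_estimator(instr, TRUE, fast_cfg(seed = 7))
  b <- median_estimator(instr, TRUE, fast_cfg(seed = 7))
  c <- median_estimator(instr, TRUE, fast_cfg(seed = 8))
  expect_identical(a$se, b$se)
  expect_false(identical(a$se, c$se))
  # the bootstrap must not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(median_estimator(instr, TRUE, fast_cfg()))
  expect_identical(rnorm(1), before)
})

test_that("estimate_all reports all eight methods coherently", {
  instr <- fixture_instruments()
  suite <- estimate_all(instr, fast_cfg())
  df <- as.data.frame(suite)
  expect_identical(nrow(df), 8L)
  expect_identical(df$method,
                   c("ivw_fixed", "ivw_random", "max_likelihood",
                     "simple_mode", "weighted_mode", "simple_median",
                     "weighted_median", "egger"))
  # under-dispersed fixture: fixed and random IVW rows identical
  expect_equal(df$or_[1], df$or_[2])
  # permuting instrument order leaves deterministic rows unchanged
  perm <- as_mr_instruments(as.data.frame(instr)[sample(9), ])
  df2 <- as.data.frame(estimate_all(perm, fast_cfg()))
  det <- df$method %in% c("ivw_fixed", "ivw_random", "max_likelihood", "egger")
  expect_equal(df2$or_[det], df$or_[det], tolerance = 1e-9)
})

test_that("estimate_all marks underpowered methods not-applicable", {
  instr <- toy_instruments(J = 2)
  df <- as.data.frame(estimate_all(instr, fast_cfg()))
  ok <- df$method %in% c("ivw_fixed", "ivw_random", "max_likelihood")
  expect_true(all(!is.na(df$or_[ok])))
  expect_true(all(is.na(df$or_[!ok])))
  expect_true(all(nzchar(df$note[!ok])))
})
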