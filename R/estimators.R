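#' Estimator configuration
#'
#' @param ci_level confidence-interval coverage (default 0.95). Normal
#'   quantiles are used throughout.
#' @param n_boot parametric-bootstrap replicates for median/mode standard
#'   errors (default 1000, minimum 100).
#' @param seed integer seed for the bootstrap RNG (default 42; recorded in
#'   reports).
#' @param mode_phi bandwidth multiplier for the mode estimators (default 1).
#' @param ratio_se_order `"first"` or `"second"` delta-method Wald-ratio SE.
#' @return list of class `estimator_config`.
#' @export
estimator_config <- function(ci_level = 0.95, n_boot = 1000, seed = 42,
                             mode_phi = 1,
                             ratio_se_order = c("first", "second")) {
  stopifnot(ci_level > 0, ci_level < 1, n_boot >= 100, mode_phi > 0)
  structure(list(ci_level = ci_level, n_boot = as.integer(n_boot),
                 seed = as.integer(seed), mode_phi = mode_phi,
                 ratio_se_order = match.arg(ratio_se_order)),
            class = "estimator_config")
}

# evaluate `code` under a private RNG stream, restoring the caller's state
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Construct an MR estimate record
#'
#' Normal-quantile CI and two-sided p are derived from `beta` and `se`;
#' odds-ratio-scale columns are the exponentials of the log-odds columns.
#'
#' @param method method name.
#' @param beta,se causal estimate and SE on the log-odds-per-SD scale.
#' @param n_snps number of instruments used.
#' @param ci_level CI coverage.
#' @param q_statistic,q_df Cochran's Q and its degrees of freedom (optional).
#' @param intercept,intercept_se Egger intercept and SE (optional).
#' @return list of class `mr_estimate`.
#' @export
mr_estimate <- function(method, beta, se, n_snps, ci_level = 0.95,
                        q_statistic = NA_real_, q_df = NA_real_,
                        intercept = NA_real_, intercept_se = NA_real_) {
  stopifnot(se > 0)
  z <- stats::qnorm((1 + ci_level) / 2)
  est <- list(
    method = method, beta = beta, se = se,
    ci_low = beta - z * se, ci_high = beta + z * se,
    pvalue = 2 * stats::pnorm(-abs(beta / se)),
    or_ = exp(beta), or_low = exp(beta - z * se), or_high = exp(beta + z * se),
    n_snps = n_snps, ci_level = ci_level,
    q_statistic = q_statistic, q_df = q_df,
    q_pvalue = if (!is.na(q_statistic) && !is.na(q_df) && q_df > 0)
      stats::pchisq(q_statistic, q_df, lower.tail = FALSE) else NA_real_,
    intercept = intercept, intercept_se = intercept_se,
    intercept_ci_low = if (!is.na(intercept)) intercept - z * intercept_se else NA_real_,
    intercept_ci_high = if (!is.na(intercept)) intercept + z * intercept_se else NA_real_,
    intercept_p = if (!is.na(intercept))
      2 * stats::pnorm(-abs(intercept / intercept_se)) else NA_real_)
  structure(est, class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s (%d SNPs): OR %.3f (%.3f, %.3f), p = %.3g\n",
              x$method, x$n_snps, x$or_, x$or_low, x$or_high, x$pvalue))
  if (!is.na(x$intercept))
    cat(sprintf("  intercept %.3f (%.3f, %.3f), p = %.3g\n",
                x$intercept, x$intercept_ci_low, x$intercept_ci_high,
                x$intercept_p))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, beta = x$beta, se = x$se, ci_low = x$ci_low,
             ci_high = x$ci_high, pvalue = x$pvalue, or_ = x$or_,
             or_low = x$or_low, or_high = x$or_high, n_snps = x$n_snps,
             q_statistic = x$q_statistic, intercept = x$intercept,
             intercept_se = x$intercept_se, stringsAsFactors = FALSE)
}

.check_instr <- function(instr, min_snps, method) {
  if (nrow(instr) < min_snps)
    stop(sprintf("%s requires at least %d instrument(s), got %d",
                 method, min_snps, nrow(instr)))
}

#' Fixed-effect inverse-variance-weighted estimator
#'
#' Weighted mean of the per-SNP Wald ratios with weights
#' \eqn{w_j = 1/se_{ratio,j}^2} (under first-order SEs, equivalently
#' \eqn{\beta_{Xj}^2 / se_{Yj}^2}):
#' \eqn{\hat\theta = \sum w_j r_j / \sum w_j}, \eqn{se = 1/\sqrt{\sum w_j}}.
#' Also returns Cochran's Q, \eqn{\sum w_j (r_j - \hat\theta)^2} on J-1 df.
#'
#' @param instr an `mr_instruments` table (>= 1 row).
#' @param cfg an [estimator_config()].
#' @return an [mr_estimate()] with method `"ivw_fixed"`.
#' @export
ivw_fixed <- function(instr, cfg = estimator_config()) {
  .check_instr(instr, 1, "ivw_fixed")
  w <- 1 / instr$ratio_se^2
  theta <- sum(w * instr$ratio) / sum(w)
  se <- sqrt(1 / sum(w))
  q <- sum(w * (instr$ratio - theta)^2)
  mr_estimate("ivw_fixed", theta, se, nrow(instr), cfg$ci_level,
              q_statistic = q, q_df = nrow(instr) - 1)
}

#' Multiplicative random-effects IVW estimator
#'
#' Same point estimate as [ivw_fixed()]; the SE is inflated by
#' \eqn{\max(1, \sqrt{Q/(J-1)})} (overdispersion truncated at 1), so with
#' under-dispersed instruments it coincides with the fixed-effect row.
#'
#' @inheritParams ivw_fixed
#' @return an [mr_estimate()] with method `"ivw_random"`.
#' @export
ivw_random <- function(instr, cfg = estimator_config()) {
  .check_instr(instr, 2, "ivw_random")
  fe <- ivw_fixed(instr, cfg)
  scale <- max(1, sqrt(fe$q_statistic / (nrow(instr) - 1)))
  mr_estimate("ivw_random", fe$beta, fe$se * scale, nrow(instr),
              cfg$ci_level, q_statistic = fe$q_statistic, q_df = fe$q_df)
}

# profile negative log-likelihood machinery for max_likelihood:
# for fixed theta the per-SNP true effects have the closed form
# gamma_j = (bx/sx^2 + theta*by/sy^2) / (1/sx^2 + theta^2/sy^2)
.ml_gamma <- function(theta, instr) {
  (instr$beta_exp / instr$se_exp^2 + theta * instr$beta_out / instr$se_out^2) /
    (1 / instr$se_exp^2 + theta^2 / instr$se_out^2)
}
.ml_nll <- function(theta, instr) {
  g <- .ml_gamma(theta, instr)
  sum((instr$beta_exp - g)^2 / (2 * instr$se_exp^2) +
        (instr$beta_out - theta * g)^2 / (2 * instr$se_out^2))
}

#' Maximum-likelihood causal estimator
#'
#' Maximizes the joint normal likelihood
#' \deqn{\prod_j N(\beta_{Xj};\ \gamma_j,\ se_{Xj}^2)\
#'       N(\beta_{Yj};\ \theta \gamma_j,\ se_{Yj}^2)}
#' over the causal slope \eqn{\theta} and the per-SNP true exposure effects
#' \eqn{\gamma_j}. The profile over \eqn{\gamma} is available in closed form,
#' leaving a one-dimensional optimization in \eqn{\theta} (initialized at the
#' IVW estimate); the SE comes from the inverse observed information of the
#' full (J+1)-parameter likelihood at the optimum.
#'
#' @inheritParams ivw_fixed
#' @return an [mr_estimate()] with method `"max_likelihood"`.
#' @export
max_likelihood <- function(instr, cfg = estimator_config()) {
  .check_instr(instr, 2, "max_likelihood")
  ivw <- ivw_fixed(instr, cfg)
  span <- max(20 * ivw$se, 1)
  opt <- stats::optimize(.ml_nll, instr = instr,
                         interval = c(ivw$beta - span, ivw$beta + span),
                         tol = 1e-10)
  theta <- opt$minimum
  if (abs(theta - ivw$beta) > 0.99 * span)
    stop("max_likelihood: optimizer hit the search boundary; estimate not trusted")
  g <- .ml_gamma(theta, instr)
  # observed information of the full likelihood, partitioned as
  # [theta | gamma]: H_tt = sum g^2/sy^2, H_tg_j = (2 theta g_j - by_j)/sy^2,
  # H_gg = diag(1/sx^2 + theta^2/sy^2)
  h_tt <- sum(g^2 / instr$se_out^2)
  h_tg <- (2 * theta * g - instr$beta_out) / instr$se_out^2
  h_gg <- 1 / instr$se_exp^2 + theta^2 / instr$se_out^2
  info <- h_tt - sum(h_tg^2 / h_gg)  # Schur complement
  if (info <= 0) stop("max_likelihood: singular observed information")
  mr_estimate("max_likelihood", theta, sqrt(1 / info), nrow(instr),
              cfg$ci_level)
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome betas on the exposure betas with an
#' intercept, weights \eqn{1/se_{Yj}^2}, after orienting every instrument so
#' its exposure beta is nonnegative (flipping the outcome beta in tandem).
#' The slope estimates the causal effect under the InSiDE assumption; the
#' intercept estimates average directional pleiotropy. Coefficient SEs carry
#' a multiplicative overdispersion factor truncated below at 1.
#'
#' @param instr an `mr_instruments` table (>= 3 rows).
#' @param cfg an [estimator_config()].
#' @return an [mr_estimate()] with method `"egger"` and the intercept fields
#'   populated.
#' @export
mr_egger <- function(instr, cfg = estimator_config()) {
  .check_instr(instr, 3, "mr_egger")
  flip <- sign(instr$beta_exp)
  flip[flip == 0] <- 1
  bx <- instr$beta_exp * flip
  by <- instr$beta_out * flip
  w <- 1 / instr$se_out^2
  fit <- stats::lm(by ~ bx, weights = w)
  cf <- stats::coef(fit)
  J <- nrow(instr)
  sigma2 <- sum(w * stats::residuals(fit)^2) / (J - 2)
  vc_unit <- stats::vcov(fit) / summary(fit)$sigma^2  # (X'WX)^-1
  vc <- vc_unit * max(1, sigma2)
  q <- sum(w * stats::residuals(fit)^2)
  mr_estimate("egger", unname(cf["bx"]), sqrt(vc["bx", "bx"]), J,
              cfg$ci_level, q_statistic = q, q_df = J - 2,
              intercept = unname(cf["(Intercept)"]),
              intercept_se = sqrt(vc["(Intercept)", "(Intercept)"]))
}

# weighted 50th-percentile with the half-step convention:
# p_j = (cumsum(w)_j - w_j/2) / sum(w), linear interpolation in between
.weighted_median <- function(ratio, w) {
  o <- order(ratio)
  r <- ratio[o]; w <- w[o] / sum(w)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(r[1])
  if (0.5 >= p[length(p)]) return(r[length(p)])
  stats::approx(p, r, xout = 0.5, ties = "ordered")$y
}

# parametric bootstrap SE: redraw each ratio from N(ratio_j, ratio_se_j),
# re-estimate with fixed weights, SD across replicates
.boot_se <- function(estimator, ratio, ratio_se, w, n_boot, seed) {
  .with_seed(seed, {
    est <- replicate(n_boot, {
      r <- stats::rnorm(length(ratio), ratio, ratio_se)
      estimator(r, w)
    })
    stats::sd(est)
  })
}

#' Median-based causal estimators
#'
#' Orders the per-SNP Wald ratios and interpolates the 50th weighted
#' percentile, with equal weights (simple median) or inverse-variance
#' weights \eqn{1/se_{ratio}^2} (weighted median; consistent when at least
#' half the weight comes from valid instruments). The SE is a parametric
#' bootstrap: each ratio is redrawn from \eqn{N(r_j, se_{ratio,j})} and the
#' median re-estimated, `cfg$n_boot` times under `cfg$seed`.
#'
#' @param instr an `mr_instruments` table (>= 3 rows).
#' @param weighted TRUE for the weighted median.
#' @param cfg an [estimator_config()].
#' @return an [mr_estimate()] with method `"weighted_median"` or
#'   `"simple_median"`.
#' @export
median_estimator <- function(instr, weighted = TRUE,
                             cfg = estimator_config()) {
  .check_instr(instr, 3, "median_estimator")
  w <- if (weighted) 1 / instr$ratio_se^2 else rep(1, nrow(instr))
  theta <- .weighted_median(instr$ratio, w)
  se <- .boot_se(.weighted_median, instr$ratio, instr$ratio_se, w,
                 cfg$n_boot, cfg$seed)
  mr_estimate(if (weighted) "weighted_median" else "simple_median",
              theta, se, nrow(instr), cfg$ci_level)
}

# mode of the kernel-smoothed ratio distribution; weights enter as kernel
# masses; bandwidth: modified Silverman rule on the ratios times phi
.mode_point <- function(ratio, w, phi = 1, grid_n = 10000L) {
  disp <- min(stats::sd(ratio), stats::mad(ratio))
  h <- phi * 0.9 * disp * length(ratio)^(-1 / 5)
  if (!is.finite(h) || h <= 0) return(ratio[1])  # all ratios identical
  grid <- seq(min(ratio) - 2 * h, max(ratio) + 2 * h, length.out = grid_n)
  dens <- stats::dnorm(outer(grid, ratio, "-") / h) %*% w
  grid[which.max(dens)]
}

#' Mode-based causal estimators
#'
#' Takes the argmax of a Gaussian-kernel-smoothed density of the Wald
#' ratios, with weights applied as kernel masses: equal (simple mode) or
#' \eqn{1/se_{ratio}^2} (weighted mode). Bandwidth is
#' \eqn{h = \phi \cdot 0.9 \min(sd, \widehat{mad}) J^{-1/5}} on the ratios
#' (`phi = cfg$mode_phi`), the argmax located on a 10,000-point grid spanning
#' `[min - 2h, max + 2h]`. SE by the same parametric bootstrap as the
#' medians. Consistent when the largest group of instruments is valid.
#'
#' @inheritParams median_estimator
#' @return an [mr_estimate()] with method `"weighted_mode"` or
#'   `"simple_mode"`.
#' @export
mode_estimator <- function(instr, weighted = TRUE,
                           cfg = estimator_config()) {
  .check_instr(instr, 3, "mode_estimator")
  w <- if (weighted) 1 / instr$ratio_se^2 else rep(1, nrow(instr))
  est_fun <- function(r, w) .mode_point(r, w, phi = cfg$mode_phi)
  theta <- est_fun(instr$ratio, w)
  se <- .boot_se(est_fun, instr$ratio, instr$ratio_se, w,
                 cfg$n_boot, cfg$seed)
  mr_estimate(if (weighted) "weighted_mode" else "simple_mode",
              theta, se, nrow(instr), cfg$ci_level)
}

.mr_methods <- c("ivw_fixed", "ivw_random", "max_likelihood", "simple_mode",
                 "weighted_mode", "simple_median", "weighted_median", "egger")

.run_method <- function(method, instr, cfg) {
  switch(method,
         ivw_fixed = ivw_fixed(instr, cfg),
         ivw_random = ivw_random(instr, cfg),
         max_likelihood = max_likelihood(instr, cfg),
         simple_mode = mode_estimator(instr, weighted = FALSE, cfg = cfg),
         weighted_mode = mode_estimator(instr, weighted = TRUE, cfg = cfg),
         simple_median = median_estimator(instr, weighted = FALSE, cfg = cfg),
         weighted_median = median_estimator(instr, weighted = TRUE, cfg = cfg),
         egger = mr_egger(instr, cfg),
         stop(sprintf("unknown method '%s'", method)))
}

#' Run the full estimator suite
#'
#' Runs all eight methods (fixed/random IVW, maximum likelihood, simple and
#' weighted mode, simple and weighted median, MR-Egger) with one shared
#' bootstrap seed. Methods whose instrument-count requirement is not met are
#' reported as not-applicable rows rather than aborting the suite.
#'
#' @param instr an `mr_instruments` table.
#' @param cfg an [estimator_config()].
#' @param methods methods to run (default: all eight, Table-layout order).
#' @return object of class `mr_estimate_suite`: list of `mr_estimate` (or
#'   condition objects for failed methods), with a `summary()` /
#'   `as.data.frame()` giving the method / OR / LCI / UCI / p table.
#' @export
estimate_all <- function(instr, cfg = estimator_config(),
                         methods = .mr_methods) {
  stopifnot(all(methods %in% .mr_methods))
  fits <- lapply(methods, function(m)
    tryCatch(.run_method(m, instr, cfg), error = function(e) e))
  names(fits) <- methods
  structure(list(fits = fits, seed = cfg$seed, n_snps = nrow(instr)),
            class = "mr_estimate_suite")
}

#' @export
as.data.frame.mr_estimate_suite <- function(x, ...) {
  rows <- lapply(names(x$fits), function(m) {
    f <- x$fits[[m]]
    if (inherits(f, "mr_estimate")) {
      data.frame(method = m, or_ = f$or_, or_low = f$or_low,
                 or_high = f$or_high, pvalue = f$pvalue, n_snps = f$n_snps,
                 note = "", stringsAsFactors = FALSE)
    } else {
      data.frame(method = m, or_ = NA_real_, or_low = NA_real_,
                 or_high = NA_real_, pvalue = NA_real_, n_snps = x$n_snps,
                 note = conditionMessage(f), stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' @export
print.mr_estimate_suite <- function(x, ...) {
  df <- as.data.frame(x)
  df$or_ <- round(df$or_, 3); df$or_low <- round(df$or_low, 3)
  df$or_high <- round(df$or_high, 3); df$pvalue <- signif(df$pvalue, 3)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
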