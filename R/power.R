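#' Power configuration for two-sample MR with a binary outcome
#'
#' @param n_outcome total outcome-GWAS sample size.
#' @param case_fraction proportion of cases among the outcome sample,
#'   in (0,1).
#' @param r2_sum total exposure variance explained by the instruments,
#'   in `[0, 1)`.
#' @param or_alt odds ratio per SD of exposure under the alternative.
#' @param alpha two-sided test size (default 0.05).
#' @return list of class `power_config`.
#' @export
power_config <- function(n_outcome, case_fraction, r2_sum, or_alt,
                         alpha = 0.05) {
  stopifnot(n_outcome >= 10, case_fraction > 0, case_fraction < 1,
            r2_sum >= 0, r2_sum < 1, or_alt > 0, alpha > 0, alpha < 1)
  structure(list(n_outcome = n_outcome, case_fraction = case_fraction,
                 r2_sum = r2_sum, or_alt = or_alt, alpha = alpha),
            class = "power_config")
}

#' Statistical power of a two-sample MR analysis (binary outcome)
#'
#' Noncentrality-based approximation: with \eqn{b = \log(OR_{alt})}, the
#' Wald statistic for the causal effect has approximate noncentrality
#' \eqn{\sqrt{N \cdot R^2 \cdot K(1-K)} \cdot |b|}, giving
#' \deqn{power = \Phi\left(\sqrt{N R^2 K (1-K)}\,|b| - z_{1-\alpha/2}\right).}
#' Power is nondecreasing in `n_outcome`, `r2_sum`, `|log(or_alt)|`, and in
#' `case_fraction` on (0, 0.5]. At `or_alt = 1` the power equals `alpha`.
#'
#' @param cfg a [power_config()].
#' @return power in (0, 1). A design with `r2_sum = 0` returns `alpha` with
#'   a warning.
#' @export
mr_power_binary <- function(cfg) {
  stopifnot(inherits(cfg, "power_config"))
  z <- stats::qnorm(1 - cfg$alpha / 2)
  if (cfg$r2_sum == 0) {
    warning("r2_sum = 0: instruments explain no exposure variance; power equals alpha")
    return(cfg$alpha)
  }
  b <- log(cfg$or_alt)
  if (b == 0) return(cfg$alpha)
  ncp <- sqrt(cfg$n_outcome * cfg$r2_sum * cfg$case_fraction *
                (1 - cfg$case_fraction)) * abs(b)
  # both rejection tails of the two-sided test
  stats::pnorm(ncp - z) + stats::pnorm(-ncp - z)
}

#' Total exposure variance explained by a set of instruments
#'
#' Sum of per-SNP [variance_explained()] over (assumed independent)
#' instruments. Requires EAF on every record.
#'
#' @param ds a `summary_dataset` (or any data.frame with `eaf` and `beta`).
#' @return the summed r2 (0 for an empty set).
#' @export
r2_total <- function(ds) {
  if (nrow(ds) == 0) return(0)
  if (any(is.na(ds$eaf)))
    stop("r2_total: EAF missing for some records")
  sum(variance_explained(ds$eaf, ds$beta))
}
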