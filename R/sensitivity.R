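#' Leave-one-out sensitivity analysis
#'
#' Re-runs an estimator (fixed-effect IVW by default) with each instrument
#' omitted in turn, appending the all-SNP row last (`omitted = "none"`).
#' Every row equals the estimator run directly on that subset. Subsets
#' falling below the method's instrument-count requirement are reported as
#' not-applicable rows.
#'
#' @param instr an `mr_instruments` table (>= 2 rows).
#' @param method one of the suite's method names (default `"ivw_fixed"`).
#' @param cfg an [estimator_config()].
#' @return data.frame with columns `omitted`, `beta`, `se`, `ci_low`,
#'   `ci_high`, `pvalue`, `or_`, `or_low`, `or_high`, `n_snps`, `note`;
#'   J + 1 rows for J instruments.
#' @export
leave_one_out <- function(instr, method = "ivw_fixed",
                          cfg = estimator_config()) {
  .check_instr(instr, 2, "leave_one_out")
  one_row <- function(omitted, sub) {
    fit <- tryCatch(.run_method(method, sub, cfg), error = function(e) e)
    if (inherits(fit, "mr_estimate")) {
      data.frame(omitted = omitted, beta = fit$beta, se = fit$se,
                 ci_low = fit$ci_low, ci_high = fit$ci_high,
                 pvalue = fit$pvalue, or_ = fit$or_, or_low = fit$or_low,
                 or_high = fit$or_high, n_snps = fit$n_snps, note = "",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(omitted = omitted, beta = NA_real_, se = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_, pvalue = NA_real_,
                 or_ = NA_real_, or_low = NA_real_, or_high = NA_real_,
                 n_snps = nrow(sub), note = conditionMessage(fit),
                 stringsAsFactors = FALSE)
    }
  }
  rows <- lapply(seq_len(nrow(instr)), function(i)
    one_row(instr$rsid[i], instr[-i, , drop = FALSE]))
  rows[[length(rows) + 1]] <- one_row("none", instr)
  .rbind_all(rows)
}

#' Single-SNP forest-plot data
#'
#' Per-SNP Wald-ratio estimates with normal-quantile CIs, followed by the
#' pooled fixed-effect IVW summary row (`rsid = "All (IVW)"`), ready for a
#' forest plot.
#'
#' @param instr an `mr_instruments` table (>= 1 row).
#' @param cfg an [estimator_config()].
#' @return data.frame with columns `rsid`, `beta`, `se`, `ci_low`,
#'   `ci_high`, `or_`, `or_low`, `or_high`, `summary_row`.
#' @export
single_snp_forest <- function(instr, cfg = estimator_config()) {
  .check_instr(instr, 1, "single_snp_forest")
  z <- stats::qnorm((1 + cfg$ci_level) / 2)
  per_snp <- data.frame(
    rsid = instr$rsid, beta = instr$ratio, se = instr$ratio_se,
    ci_low = instr$ratio - z * instr$ratio_se,
    ci_high = instr$ratio + z * instr$ratio_se,
    summary_row = FALSE, stringsAsFactors = FALSE)
  ivw <- ivw_fixed(instr, cfg)
  all_row <- data.frame(rsid = "All (IVW)", beta = ivw$beta, se = ivw$se,
                        ci_low = ivw$ci_low, ci_high = ivw$ci_high,
                        summary_row = TRUE, stringsAsFactors = FALSE)
  out <- rbind(per_snp, all_row, make.row.names = FALSE)
  out$or_ <- exp(out$beta); out$or_low <- exp(out$ci_low)
  out$or_high <- exp(out$ci_high)
  out
}

#' Funnel-plot data
#'
#' Per-SNP (Wald ratio, precision = 1/SE) pairs for visual inspection of
#' directional pleiotropy, with the fixed-effect IVW estimate as the
#' reference line and a crude symmetry score: the Spearman rank correlation
#' between the ratio deviations from the reference and the precisions
#' (0 for a symmetric funnel; defined as 0 when degenerate).
#'
#' @param instr an `mr_instruments` table (>= 1 row).
#' @param cfg an [estimator_config()].
#' @return list with `points` (data.frame rsid / ratio / precision),
#'   `reference` (IVW fixed estimate, log-odds per SD) and
#'   `symmetry_score`.
#' @export
funnel_data <- function(instr, cfg = estimator_config()) {
  .check_instr(instr, 1, "funnel_data")
  ivw <- ivw_fixed(instr, cfg)
  dev <- instr$ratio - ivw$beta
  prec <- 1 / instr$ratio_se
  score <- if (stats::sd(dev) == 0 || stats::sd(prec) == 0) 0 else
    suppressWarnings(stats::cor(dev, prec, method = "spearman"))
  if (is.na(score)) score <- 0
  list(points = data.frame(rsid = instr$rsid, ratio = instr$ratio,
                           precision = prec, stringsAsFactors = FALSE),
       reference = ivw$beta, symmetry_score = score)
}

#' MR-Egger pleiotropy intercept report
#'
#' The intercept row of the Egger regression: estimate, SE, normal CI and
#' two-sided p, plus a flag reading "no evidence of horizontal pleiotropy"
#' when p >= 0.05.
#'
#' @param instr an `mr_instruments` table (>= 3 rows).
#' @param cfg an [estimator_config()].
#' @return one-row data.frame: `estimate`, `se`, `ci_low`, `ci_high`,
#'   `pvalue`, `pleiotropy_evidence` (logical).
#' @export
egger_intercept_report <- function(instr, cfg = estimator_config()) {
  fit <- mr_egger(instr, cfg)
  data.frame(estimate = fit$intercept, se = fit$intercept_se,
             ci_low = fit$intercept_ci_low, ci_high = fit$intercept_ci_high,
             pvalue = fit$intercept_p,
             pleiotropy_evidence = fit$intercept_p < 0.05)
}
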