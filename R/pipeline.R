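#' End-to-end run configuration
#'
#' Bundles the inputs and stage configurations of a full two-sample MR run:
#' selection, harmonization, estimation, sensitivity diagnostics, and
#' (optionally) power. Inputs may be given as file paths (read with the
#' package readers) or as in-memory objects.
#'
#' @param exposure path to the exposure summary-statistic file, or a
#'   `summary_dataset`.
#' @param outcome path or `summary_dataset` for the outcome.
#' @param ld optional path or `ld_matrix` (skips LD pruning when NULL; with
#'   all candidate instruments pre-pruned this stage is a no-op anyway).
#' @param annotations optional path or data.frame of trait annotations.
#' @param confounders character vector of confounder trait names.
#' @param selection a [selection_config()] (confounders are folded into it).
#' @param policy a [harmonize_policy()].
#' @param estimator an [estimator_config()]; its seed drives every
#'   stochastic stage.
#' @param power_or odds ratio at which to evaluate power (default: the IVW
#'   fixed estimate of the run).
#' @param case_fraction proportion of cases in the outcome GWAS, needed for
#'   the power stage; NULL (default) skips power.
#' @param out_dir output directory (created if needed); NULL writes nothing.
#' @return list of class `run_config`.
#' @export
run_config <- function(exposure, outcome, ld = NULL, annotations = NULL,
                       confounders = character(0),
                       selection = selection_config(),
                       policy = harmonize_policy(),
                       estimator = estimator_config(),
                       power_or = NULL, case_fraction = NULL,
                       out_dir = NULL) {
  selection$confounder_traits <- tolower(confounders)
  structure(list(exposure = exposure, outcome = outcome, ld = ld,
                 annotations = annotations, selection = selection,
                 policy = policy, estimator = estimator,
                 power_or = power_or, case_fraction = case_fraction,
                 out_dir = out_dir),
            class = "run_config")
}

.load_input <- function(x, reader, ...) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) stop(sprintf("input file does not exist: %s", x))
    reader(x, ...)
  } else x
}

#' Run the complete two-sample MR pipeline
#'
#' Select instruments, harmonize, estimate with the full method suite,
#' compute leave-one-out / forest / funnel / pleiotropy-intercept
#' diagnostics and (for binary outcomes with EAF available) statistical
#' power, writing all report tables as TSV plus one `report.json` when
#' `cfg$out_dir` is set.
#'
#' @param cfg a [run_config()].
#' @return object of class `mr_run_report`: list with `selection_audit`,
#'   `instruments`, `strength`, `estimates` (`mr_estimate_suite`),
#'   `leave_one_out`, `forest`, `funnel`, `intercept`, `power`,
#'   `provenance`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  exposure <- .load_input(cfg$exposure, read_summary_stats,
                          trait_name = "exposure", trait_type = "continuous")
  outcome <- .load_input(cfg$outcome, read_summary_stats,
                         trait_name = "outcome", trait_type = "binary")
  ld <- .load_input(cfg$ld, read_ld_matrix)
  annotations <- .load_input(cfg$annotations, read_trait_annotations)

  sel <- select_instruments(exposure, outcome, ld = ld,
                            annotations = annotations,
                            config = cfg$selection)
  if (nrow(sel$exposure) < 1)
    stop("run_pipeline: no instrument survived selection; see the audit")
  instr <- harmonize(sel$exposure, sel$outcome, cfg$policy)
  if (nrow(instr) < 1)
    stop("run_pipeline: no instrument survived harmonization; see the log")

  suite <- estimate_all(instr, cfg$estimator)
  loo <- tryCatch(leave_one_out(instr, "ivw_fixed", cfg$estimator),
                  error = function(e) NULL)
  forest <- single_snp_forest(instr, cfg$estimator)
  funnel <- funnel_data(instr, cfg$estimator)
  intercept <- tryCatch(egger_intercept_report(instr, cfg$estimator),
                        error = function(e) NULL)

  power <- NULL
  if (!is.null(cfg$case_fraction) &&
      attr(outcome, "trait_type") == "binary" &&
      !any(is.na(instr$eaf_exp))) {
    n_out <- stats::median(sel$outcome$n, na.rm = TRUE)
    or_alt <- cfg$power_or
    if (is.null(or_alt)) {
      ivw <- suite$fits$ivw_fixed
      or_alt <- if (inherits(ivw, "mr_estimate")) ivw$or_ else NA_real_
    }
    if (is.finite(n_out) && is.finite(or_alt)) {
      r2s <- sum(variance_explained(instr$eaf_exp, instr$beta_exp))
      power <- mr_power_binary(power_config(
        n_outcome = n_out, case_fraction = cfg$case_fraction,
        r2_sum = r2s, or_alt = or_alt))
    }
  }

  report <- structure(list(
    selection_audit = sel$audit, instruments = instr,
    strength = sel$strength, estimates = suite, leave_one_out = loo,
    forest = forest, funnel = funnel, intercept = intercept, power = power,
    provenance = list(package = "mrkit",
                      version = as.character(utils::packageVersion("mrkit")),
                      seed = cfg$estimator$seed)),
    class = "mr_run_report")
  if (!is.null(cfg$out_dir)) write_run_report(report, cfg$out_dir)
  report
}

#' Write a pipeline report to disk
#'
#' Emits one TSV per table (`selection_audit.tsv`, `instruments.tsv`,
#' `strength.tsv`, `estimates.tsv`, `loo.tsv`, `forest.tsv`, `funnel.tsv`,
#' `intercept.tsv`) plus a consolidated `report.json`.
#'
#' @param report an `mr_run_report`.
#' @param out_dir output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    if (is.null(df)) return()
    utils::write.table(as.data.frame(df), file.path(out_dir, name),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(report$selection_audit, "selection_audit.tsv")
  wt(report$instruments, "instruments.tsv")
  wt(report$strength, "strength.tsv")
  wt(as.data.frame(report$estimates), "estimates.tsv")
  wt(report$leave_one_out, "loo.tsv")
  wt(report$forest, "forest.tsv")
  wt(report$funnel$points, "funnel.tsv")
  wt(report$intercept, "intercept.tsv")
  json <- list(
    provenance = report$provenance,
    estimates = as.data.frame(report$estimates),
    intercept = report$intercept,
    funnel_reference = report$funnel$reference,
    funnel_symmetry = report$funnel$symmetry_score,
    power = report$power,
    n_instruments = nrow(report$instruments))
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", null = "null")
  invisible(out_dir)
}

#' @export
print.mr_run_report <- function(x, ...) {
  cat(sprintf("Two-sample MR run: %d instruments\n", nrow(x$instruments)))
  print(x$estimates)
  if (!is.null(x$intercept))
    cat(sprintf("Egger intercept: %.3f (%.3f, %.3f), p = %.3g\n",
                x$intercept$estimate, x$intercept$ci_low,
                x$intercept$ci_high, x$intercept$pvalue))
  if (!is.null(x$power))
    cat(sprintf("Power at the estimated OR: %.1f%%\n", 100 * x$power))
  invisible(x)
}
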