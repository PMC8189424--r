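#' Harmonization policy
#'
#' Controls how exposure and outcome records are placed on a common effect
#' allele. Palindromic SNPs (A/T or C/G) cannot be strand-resolved from
#' alleles alone; when the exposure EAF lies inside the intermediate window
#' `0.5 +/- palindrome_eaf_window` they are dropped (if
#' `drop_intermediate_palindromes`). Outside the window, orientation is
#' resolved by comparing allele frequencies when both sides report an EAF;
#' with the outcome EAF missing, palindromes are dropped.
#'
#' @param palindrome_eaf_window half-width of the ambiguous EAF band around
#'   0.5 (default 0.08, i.e. 0.42-0.58).
#' @param drop_intermediate_palindromes drop palindromic SNPs whose EAF falls
#'   in the window (default TRUE).
#' @param ratio_se_order `"first"` (delta-method SE `se_out / |beta_exp|`) or
#'   `"second"` (adds the exposure-uncertainty term).
#' @return list of class `harmonize_policy`.
#' @export
harmonize_policy <- function(palindrome_eaf_window = 0.08,
                             drop_intermediate_palindromes = TRUE,
                             ratio_se_order = c("first", "second")) {
  stopifnot(palindrome_eaf_window >= 0, palindrome_eaf_window < 0.5)
  structure(list(palindrome_eaf_window = palindrome_eaf_window,
                 drop_intermediate_palindromes = drop_intermediate_palindromes,
                 ratio_se_order = match.arg(ratio_se_order)),
            class = "harmonize_policy")
}

#' Per-SNP Wald ratio and its standard error
#'
#' The single-instrument causal estimate `beta_out / beta_exp`. The
#' first-order delta-method SE is `se_out / |beta_exp|`; the second-order SE
#' adds the exposure-side uncertainty:
#' `sqrt(se_out^2/beta_exp^2 + beta_out^2 * se_exp^2 / beta_exp^4)`.
#'
#' @param beta_exp,se_exp exposure association and SE (SD units).
#' @param beta_out,se_out outcome association and SE (log-odds for a binary
#'   outcome).
#' @param order `"first"` or `"second"`.
#' @return list with `ratio` and `ratio_se`.
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out,
                       order = c("first", "second")) {
  order <- match.arg(order)
  if (any(beta_exp == 0)) stop("wald_ratio: beta_exp must be nonzero")
  ratio <- beta_out / beta_exp
  ratio_se <- if (order == "first") {
    se_out / abs(beta_exp)
  } else {
    sqrt(se_out^2 / beta_exp^2 + beta_out^2 * se_exp^2 / beta_exp^4)
  }
  list(ratio = ratio, ratio_se = ratio_se)
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")
.is_palindromic <- function(ea, oa) identical(unname(.complement[ea]), oa)

.dropped <- function(reason) structure(list(reason = reason), class = "mr_dropped")

#' Was a SNP dropped during harmonization?
#' @param x result of [harmonize_pair()].
#' @return TRUE when the SNP was dropped rather than harmonized.
#' @export
is_dropped <- function(x) inherits(x, "mr_dropped")

#' Harmonize one exposure/outcome record pair
#'
#' Places the outcome record on the exposure's effect allele. If the outcome
#' reports the same allele pair in the same orientation, betas pass through;
#' if the alleles are swapped, the outcome beta is sign-flipped and its EAF
#' complemented. Palindromic SNPs are resolved or dropped per `policy`.
#' Irreconcilable allele sets are an error.
#'
#' @param exp,out single-row `summary_dataset` slices (or data.frames with
#'   the canonical columns) sharing one rsid.
#' @param policy a [harmonize_policy()].
#' @return one-row data.frame of the harmonized instrument (columns `rsid`,
#'   `beta_exp`, `se_exp`, `beta_out`, `se_out`, `eaf_exp`, `ratio`,
#'   `ratio_se`, `flipped`, `palindromic`), or an `mr_dropped` object (test
#'   with [is_dropped()]; carries `$reason`) when the SNP is dropped.
#' @export
harmonize_pair <- function(exp, out, policy = harmonize_policy()) {
  exp <- as.data.frame(exp); out <- as.data.frame(out)
  stopifnot(nrow(exp) == 1, nrow(out) == 1)
  if (.norm_rsid(exp$rsid) != .norm_rsid(out$rsid))
    stop("harmonize_pair: rsids differ")
  ea_x <- exp$effect_allele; oa_x <- exp$other_allele
  ea_y <- out$effect_allele; oa_y <- out$other_allele
  pal <- .is_palindromic(ea_x, oa_x)

  aligned <- identical(ea_y, ea_x) && identical(oa_y, oa_x)
  swapped <- identical(ea_y, oa_x) && identical(oa_y, ea_x)
  if (!aligned && !swapped)
    stop(sprintf("harmonization error for %s: allele sets %s/%s vs %s/%s irreconcilable",
                 exp$rsid, ea_x, oa_x, ea_y, oa_y))

  beta_out <- if (swapped) -out$beta else out$beta
  eaf_out <- if (swapped && !is.na(out$eaf)) 1 - out$eaf else out$eaf

  if (pal) {
    win <- policy$palindrome_eaf_window
    intermediate <- !is.na(exp$eaf) && abs(exp$eaf - 0.5) <= win
    if (intermediate && policy$drop_intermediate_palindromes)
      return(.dropped("palindromic SNP with intermediate EAF"))
    if (is.na(exp$eaf) || is.na(eaf_out))
      return(.dropped("palindromic SNP without both EAFs"))
    if (abs(eaf_out - 0.5) <= win)
      return(.dropped("palindromic SNP with intermediate outcome EAF"))
    # allele labels carry no strand information for palindromes: align by
    # frequency; opposite sides of 0.5 imply the outcome reports the
    # complementary allele, so flip
    if ((exp$eaf - 0.5) * (eaf_out - 0.5) < 0) {
      beta_out <- -beta_out
      eaf_out <- 1 - eaf_out
    }
  }

  wr <- wald_ratio(exp$beta, exp$se, beta_out, out$se,
                   order = policy$ratio_se_order)
  data.frame(rsid = exp$rsid, beta_exp = exp$beta, se_exp = exp$se,
             beta_out = beta_out, se_out = out$se, eaf_exp = exp$eaf,
             eaf_out = eaf_out, ratio = wr$ratio, ratio_se = wr$ratio_se,
             flipped = swapped, palindromic = pal,
             stringsAsFactors = FALSE)
}

#' Harmonize two summary datasets into an instrument table
#'
#' Pairs records by rsid (case-insensitive) and applies [harmonize_pair()]
#' to each. SNPs absent from either dataset are dropped with a logged reason.
#'
#' @param exposure,outcome `summary_dataset`s.
#' @param policy a [harmonize_policy()].
#' @return an `mr_instruments` data.frame (one row per retained SNP) with a
#'   `log` attribute: data.frame (rsid, action, reason) covering every input
#'   exposure SNP.
#' @export
harmonize <- function(exposure, outcome, policy = harmonize_policy()) {
  out_idx <- match(.norm_rsid(exposure$rsid), .norm_rsid(outcome$rsid))
  rows <- list(); log <- list()
  for (i in seq_len(nrow(exposure))) {
    rsid <- exposure$rsid[i]
    if (is.na(out_idx[i])) {
      log[[length(log) + 1]] <- data.frame(rsid = rsid, action = "dropped",
                                           reason = "absent from outcome dataset")
      next
    }
    h <- harmonize_pair(exposure[i, ], outcome[out_idx[i], ], policy)
    if (is_dropped(h)) {
      log[[length(log) + 1]] <- data.frame(rsid = rsid, action = "dropped",
                                           reason = h$reason)
    } else {
      rows[[length(rows) + 1]] <- h
      log[[length(log) + 1]] <- data.frame(
        rsid = rsid, action = "kept",
        reason = if (h$flipped) "alleles swapped: outcome beta sign-flipped" else "aligned")
    }
  }
  instr <- if (length(rows)) do.call(rbind, rows) else
    data.frame(rsid = character(0), beta_exp = numeric(0), se_exp = numeric(0),
               beta_out = numeric(0), se_out = numeric(0), eaf_exp = numeric(0),
               eaf_out = numeric(0), ratio = numeric(0), ratio_se = numeric(0),
               flipped = logical(0), palindromic = logical(0))
  rownames(instr) <- NULL
  structure(instr, log = .rbind_all(log),
            class = c("mr_instruments", "data.frame"))
}

#' Coerce a data.frame to an instrument table
#'
#' Accepts any data.frame with `beta_exp`, `se_exp`, `beta_out`, `se_out`
#' (and optionally precomputed `ratio`/`ratio_se`; recomputed when absent),
#' for feeding the estimators directly.
#'
#' @param df data.frame of harmonized per-SNP associations.
#' @param ratio_se_order `"first"` or `"second"`.
#' @return an `mr_instruments` data.frame.
#' @export
as_mr_instruments <- function(df, ratio_se_order = c("first", "second")) {
  ratio_se_order <- match.arg(ratio_se_order)
  df <- as.data.frame(df)
  need <- c("beta_exp", "se_exp", "beta_out", "se_out")
  if (!all(need %in% names(df)))
    stop(sprintf("as_mr_instruments: need columns %s", paste(need, collapse = ", ")))
  if (!"rsid" %in% names(df)) df$rsid <- sprintf("snp%d", seq_len(nrow(df)))
  if (!all(c("ratio", "ratio_se") %in% names(df))) {
    wr <- wald_ratio(df$beta_exp, df$se_exp, df$beta_out, df$se_out,
                     order = ratio_se_order)
    df$ratio <- wr$ratio; df$ratio_se <- wr$ratio_se
  }
  if (any(df$ratio_se <= 0)) stop("ratio_se must be > 0")
  rownames(df) <- NULL
  structure(df, class = c("mr_instruments", "data.frame"))
}
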