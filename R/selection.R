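#' Instrument-selection configuration
#'
#' Thresholds for the four-stage instrument-selection procedure: genome-wide
#' significance filtering of exposure associations, greedy LD pruning,
#' exclusion of SNPs annotated to confounding traits, and resolution against
#' the outcome dataset (proxy substitution and exclusion of SNPs directly
#' associated with the outcome). All p-value comparisons are strict (`<`).
#'
#' @param gw_threshold genome-wide significance p-value (default 5e-8).
#' @param ld_r2_threshold pairwise r2 above which two instruments are
#'   considered correlated (default 0.001).
#' @param proxy_r2_threshold minimum r2 for a proxy substitute (default 0.8).
#' @param confounder_traits character vector of confounding trait names
#'   (matched exactly after case-folding).
#' @param confounder_threshold p-value below which a confounder annotation
#'   triggers exclusion (default 5e-8).
#' @param outcome_threshold p-value below which a direct outcome association
#'   triggers exclusion (default 5e-8).
#' @return list of class `selection_config`.
#' @export
selection_config <- function(gw_threshold = 5e-8, ld_r2_threshold = 0.001,
                             proxy_r2_threshold = 0.8,
                             confounder_traits = character(0),
                             confounder_threshold = 5e-8,
                             outcome_threshold = 5e-8) {
  stopifnot(gw_threshold > 0, gw_threshold <= 1,
            confounder_threshold > 0, confounder_threshold <= 1,
            outcome_threshold > 0, outcome_threshold <= 1,
            ld_r2_threshold >= 0, ld_r2_threshold <= 1,
            proxy_r2_threshold > 0, proxy_r2_threshold <= 1)
  structure(list(gw_threshold = gw_threshold,
                 ld_r2_threshold = ld_r2_threshold,
                 proxy_r2_threshold = proxy_r2_threshold,
                 confounder_traits = tolower(confounder_traits),
                 confounder_threshold = confounder_threshold,
                 outcome_threshold = outcome_threshold),
            class = "selection_config")
}

.audit <- function(stage, rsid, action, reason) {
  n <- length(rsid)
  if (n == 0) return(NULL)
  data.frame(stage = rep_len(stage, n), rsid = rsid,
             action = rep_len(action, n), reason = rep_len(reason, n),
             stringsAsFactors = FALSE)
}

#' Genome-wide significance filter
#'
#' Keeps records with `pvalue < threshold`, strictly.
#'
#' @param ds a `summary_dataset`.
#' @param threshold p-value threshold (default 5e-8).
#' @return the filtered `summary_dataset`.
#' @export
filter_genomewide <- function(ds, threshold = 5e-8) {
  keep <- ds$pvalue < threshold
  summary_dataset(as.data.frame(ds)[keep, , drop = FALSE],
                  trait_name = attr(ds, "trait_name"),
                  trait_type = attr(ds, "trait_type"))
}

#' Greedy LD pruning
#'
#' Enforces pairwise independence of instruments. While any remaining pair
#' has `r2 > r2_threshold`, the SNP involved in an offending pair that is
#' correlated (above threshold) with the greatest number of other remaining
#' SNPs is dropped; ties are broken by dropping the SNP with the larger
#' exposure p-value, then the lexicographically larger rsid. Correlation
#' degree is recomputed on the shrinking set after each drop. Missing pairs
#' count as r2 = 0.
#'
#' @param ds a `summary_dataset`.
#' @param ld an `ld_matrix` covering (at least) the rsids of `ds`.
#' @param r2_threshold maximum tolerated pairwise r2 (default 0.001).
#' @return list with `dataset` (pruned `summary_dataset`) and `audit`
#'   (stage/rsid/action/reason rows, one per input SNP).
#' @export
ld_prune <- function(ds, ld, r2_threshold = 0.001) {
  df <- as.data.frame(ds)
  keep <- df$rsid
  dropped <- list()
  repeat {
    J <- length(keep)
    if (J < 2) break
    r2 <- outer(seq_len(J), seq_len(J),
                Vectorize(function(i, j) .ld_r2(ld, keep[i], keep[j])))
    diag(r2) <- 0
    deg <- rowSums(r2 > r2_threshold)
    if (!any(deg > 0)) break
    cand <- which(deg == max(deg))
    if (length(cand) > 1) {
      p <- df$pvalue[match(keep[cand], df$rsid)]
      cand <- cand[p == max(p)]
    }
    if (length(cand) > 1) cand <- cand[order(keep[cand], decreasing = TRUE)][1]
    victim <- keep[cand[1]]
    partners <- keep[r2[cand[1], ] > r2_threshold]
    dropped[[victim]] <- .audit(
      "ld_prune", victim, "dropped",
      sprintf("r2 > %g with %s", r2_threshold, paste(partners, collapse = ", ")))
    keep <- setdiff(keep, victim)
  }
  audit <- .rbind_all(list(
    .rbind_all(unname(dropped)),
    .audit("ld_prune", keep, "kept", "pairwise independent")))
  out <- summary_dataset(df[df$rsid %in% keep, , drop = FALSE],
                         trait_name = attr(ds, "trait_name"),
                         trait_type = attr(ds, "trait_type"))
  list(dataset = out, audit = audit)
}

#' Exclude SNPs annotated to confounding traits
#'
#' Drops any SNP carrying an annotation to one of the configured confounder
#' traits at `pvalue < confounder_threshold`. Trait matching is an exact
#' string comparison after case-folding and whitespace-trimming.
#'
#' @param ds a `summary_dataset`.
#' @param annotations data.frame with columns rsid, trait, pvalue (as from
#'   [read_trait_annotations()]).
#' @param config a [selection_config()] supplying `confounder_traits` and
#'   `confounder_threshold`.
#' @return list with `dataset` and `audit`; the audit names the offending
#'   trait(s) for every dropped SNP.
#' @export
exclude_confounder_associated <- function(ds, annotations,
                                          config = selection_config()) {
  df <- as.data.frame(ds)
  hits <- character(0)
  audit <- list()
  for (rsid in df$rsid) {
    ann <- annotations[.norm_rsid(annotations$rsid) == .norm_rsid(rsid), , drop = FALSE]
    ann <- ann[tolower(trimws(ann$trait)) %in% config$confounder_traits &
                 ann$pvalue < config$confounder_threshold, , drop = FALSE]
    if (nrow(ann)) {
      hits <- c(hits, rsid)
      audit[[length(audit) + 1]] <- .audit(
        "confounder", rsid, "dropped",
        sprintf("associated with %s", paste(unique(ann$trait), collapse = ", ")))
    } else {
      audit[[length(audit) + 1]] <- .audit("confounder", rsid, "kept",
                                           "no confounder association")
    }
  }
  out <- summary_dataset(df[!df$rsid %in% hits, , drop = FALSE],
                         trait_name = attr(ds, "trait_name"),
                         trait_type = attr(ds, "trait_type"))
  list(dataset = out, audit = .rbind_all(audit))
}

#' Resolve exposure instruments in the outcome dataset
#'
#' Pairs every exposure SNP with its outcome record. A SNP absent from the
#' outcome dataset is substituted by the available proxy with the highest
#' `r2 > proxy_r2_threshold` (audit action `proxied`); with no such proxy it
#' is dropped. SNPs whose outcome association is genome-wide significant
#' (`pvalue < outcome_threshold`) are excluded as direct-effect candidates.
#'
#' @param ds exposure `summary_dataset` (post selection).
#' @param outcome outcome `summary_dataset`.
#' @param proxies an `ld_matrix` used for proxy lookup (may be NULL: no
#'   proxying).
#' @param config a [selection_config()].
#' @return list with `pairs` (data.frame: rsid, proxy_rsid, exposure row
#'   index, outcome row index), `exposure` and `outcome` (matched
#'   `summary_dataset`s in pair order), and `audit`.
#' @export
resolve_in_outcome <- function(ds, outcome, proxies = NULL,
                               config = selection_config()) {
  df <- as.data.frame(ds); out <- as.data.frame(outcome)
  audit <- list(); pairs <- list()
  out_ids <- .norm_rsid(out$rsid)
  for (i in seq_len(nrow(df))) {
    rsid <- df$rsid[i]
    j <- match(.norm_rsid(rsid), out_ids)
    proxy <- NA_character_
    if (is.na(j) && !is.null(proxies) && rsid %in% rownames(proxies)) {
      cand_ids <- out$rsid[!is.na(out_ids)]
      r2s <- vapply(cand_ids, function(b) .ld_r2(proxies, rsid, b), numeric(1))
      ok <- r2s > config$proxy_r2_threshold
      if (any(ok)) {
        proxy <- cand_ids[which.max(ifelse(ok, r2s, -Inf))]
        j <- match(.norm_rsid(proxy), out_ids)
      }
    }
    if (is.na(j)) {
      audit[[length(audit) + 1]] <- .audit(
        "outcome_assoc", rsid, "dropped",
        sprintf("absent from outcome dataset, no proxy with r2 > %g",
                config$proxy_r2_threshold))
      next
    }
    if (out$pvalue[j] < config$outcome_threshold) {
      audit[[length(audit) + 1]] <- .audit(
        "outcome_assoc", rsid, "dropped",
        "directly associated with outcome at genome-wide significance")
      next
    }
    if (!is.na(proxy)) {
      audit[[length(audit) + 1]] <- .audit(
        "outcome_assoc", rsid, "proxied",
        sprintf("substituted by proxy %s (r2 = %g)", proxy,
                .ld_r2(proxies, rsid, proxy)))
    } else {
      audit[[length(audit) + 1]] <- .audit("outcome_assoc", rsid, "kept",
                                           "present in outcome dataset")
    }
    pairs[[length(pairs) + 1]] <- data.frame(
      rsid = rsid, proxy_rsid = proxy, exposure_row = i, outcome_row = j,
      stringsAsFactors = FALSE)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(rsid = character(0), proxy_rsid = character(0),
               exposure_row = integer(0), outcome_row = integer(0))
  list(
    pairs = pairs,
    exposure = summary_dataset(df[pairs$exposure_row, , drop = FALSE],
                               trait_name = attr(ds, "trait_name"),
                               trait_type = attr(ds, "trait_type")),
    outcome = {
      o <- out[pairs$outcome_row, , drop = FALSE]
      o$rsid <- pairs$rsid  # proxy rows stand in for the exposure SNP
      summary_dataset(o, trait_name = attr(outcome, "trait_name"),
                      trait_type = attr(outcome, "trait_type"))
    },
    audit = .rbind_all(audit))
}

#' Per-SNP variance in the exposure explained
#'
#' Under a standardized exposure (unit variance) and Hardy-Weinberg
#' genotype frequencies, a variant with effect-allele frequency `eaf` and
#' per-allele effect `beta` (SD units) explains
#' \eqn{r^2 = 2 \, eaf (1 - eaf) \beta^2} of the exposure variance.
#'
#' @param eaf effect-allele frequency in (0,1).
#' @param beta per-allele effect in SD units.
#' @return r2, same length as the inputs.
#' @export
variance_explained <- function(eaf, beta) {
  if (any(is.na(eaf))) stop("variance_explained: EAF is missing")
  stopifnot(all(eaf > 0), all(eaf < 1))
  2 * eaf * (1 - eaf) * beta^2
}

#' Instrument-strength F-statistic
#'
#' \eqn{F = r^2 (n - 2) / (1 - r^2)} for a single variant explaining a
#' fraction `r2` of the exposure variance in a sample of size `n`. The
#' conventional weak-instrument cutoff is F <= 10.
#'
#' @param r2 variance explained, in `[0, 1)`.
#' @param n exposure GWAS sample size (> 2).
#' @return the F-statistic (unrounded).
#' @export
f_statistic <- function(r2, n) {
  stopifnot(all(r2 >= 0), all(r2 < 1), all(n > 2))
  r2 * (n - 2) / (1 - r2)
}

#' Instrument-strength table
#'
#' Convenience wrapper computing per-SNP variance explained and F from a
#' summary dataset (requires EAF and N on every record).
#'
#' @param ds a `summary_dataset`.
#' @return data.frame with rsid, r2, f, weak (F <= 10).
#' @export
instrument_strength <- function(ds) {
  if (any(is.na(ds$eaf))) stop("instrument_strength: EAF missing for some records")
  if (any(is.na(ds$n))) stop("instrument_strength: sample size missing for some records")
  r2 <- variance_explained(ds$eaf, ds$beta)
  f <- f_statistic(r2, ds$n)
  data.frame(rsid = ds$rsid, r2 = r2, f = f, weak = f <= 10,
             stringsAsFactors = FALSE)
}

#' Run the full instrument-selection pipeline
#'
#' Applies, in order: genome-wide significance filter, LD pruning,
#' confounder exclusion, and outcome resolution, returning the matched
#' exposure/outcome datasets together with the complete selection audit.
#'
#' @param exposure,outcome `summary_dataset`s.
#' @param ld `ld_matrix` for pruning (NULL skips pruning).
#' @param annotations trait-annotation data.frame (NULL skips confounder
#'   exclusion).
#' @param config a [selection_config()].
#' @return list with `exposure`, `outcome`, `pairs`, `audit`, `strength`
#'   (F-statistic table when EAF and N are available, else NULL).
#' @export
select_instruments <- function(exposure, outcome, ld = NULL,
                               annotations = NULL,
                               config = selection_config()) {
  audits <- list()
  ds <- filter_genomewide(exposure, config$gw_threshold)
  audits[[1]] <- .rbind_all(list(
    .audit("pthreshold", ds$rsid, "kept",
           sprintf("p < %g", config$gw_threshold)),
    .audit("pthreshold", setdiff(exposure$rsid, ds$rsid), "dropped",
           sprintf("p >= %g", config$gw_threshold))))
  if (!is.null(ld)) {
    pr <- ld_prune(ds, ld, config$ld_r2_threshold)
    ds <- pr$dataset; audits[[length(audits) + 1]] <- pr$audit
  }
  if (!is.null(annotations) && length(config$confounder_traits)) {
    cf <- exclude_confounder_associated(ds, annotations, config)
    ds <- cf$dataset; audits[[length(audits) + 1]] <- cf$audit
  }
  res <- resolve_in_outcome(ds, outcome, proxies = ld, config = config)
  audits[[length(audits) + 1]] <- res$audit
  strength <- if (!any(is.na(res$exposure$eaf)) && !any(is.na(res$exposure$n)) &&
                  nrow(res$exposure))
    instrument_strength(res$exposure) else NULL
  list(exposure = res$exposure, outcome = res$outcome, pairs = res$pairs,
       audit = .rbind_all(audits), strength = strength)
}
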