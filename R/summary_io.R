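# canonical column set for summary-statistic tables
.mrkit_canonical_cols <- c("rsid", "chrom", "nearest_gene", "effect_allele",
                           "other_allele", "eaf", "beta", "se", "pvalue", "n")
.mrkit_mandatory_cols <- c("rsid", "effect_allele", "other_allele",
                           "beta", "se", "pvalue")

.norm_rsid <- function(x) tolower(trimws(as.character(x)))

.read_delim_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "", quote = "\"",
                    na.strings = c("NA", ""))
}

#' Validate rows of a summary-statistic table
#'
#' Applies the per-record invariants (distinct alleles, `se > 0`,
#' `0 < eaf < 1`, `0 < pvalue <= 1`, unique rsid) and reports every violation
#' with its row index.
#'
#' @param df data.frame with canonical columns.
#' @return character vector of diagnostics, empty when all rows are valid.
#' @keywords internal
.validate_summary_rows <- function(df) {
  msgs <- character(0)
  bad <- function(i, what) sprintf("row %d (%s): %s", i, df$rsid[i], what)
  for (i in seq_len(nrow(df))) {
    if (is.na(df$rsid[i]) || !nzchar(df$rsid[i]))
      msgs <- c(msgs, sprintf("row %d: missing rsid", i))
    ea <- toupper(df$effect_allele[i]); oa <- toupper(df$other_allele[i])
    if (!ea %in% c("A", "C", "G", "T"))
      msgs <- c(msgs, bad(i, sprintf("effect_allele '%s' not in A/C/G/T", ea)))
    if (!oa %in% c("A", "C", "G", "T"))
      msgs <- c(msgs, bad(i, sprintf("other_allele '%s' not in A/C/G/T", oa)))
    if (identical(ea, oa))
      msgs <- c(msgs, bad(i, "effect_allele equals other_allele"))
    if (is.na(df$beta[i]))
      msgs <- c(msgs, bad(i, "missing beta"))
    if (is.na(df$se[i]) || df$se[i] <= 0)
      msgs <- c(msgs, bad(i, "se must be > 0"))
    if (!is.na(df$eaf[i]) && (df$eaf[i] <= 0 || df$eaf[i] >= 1))
      msgs <- c(msgs, bad(i, sprintf("eaf %g outside (0,1)", df$eaf[i])))
    if (is.na(df$pvalue[i]) || df$pvalue[i] <= 0 || df$pvalue[i] > 1)
      msgs <- c(msgs, bad(i, "pvalue outside (0,1]"))
  }
  dup <- unique(df$rsid[duplicated(.norm_rsid(df$rsid))])
  if (length(dup))
    msgs <- c(msgs, sprintf("duplicate rsid: %s", paste(dup, collapse = ", ")))
  msgs
}

#' Read GWAS summary statistics
#'
#' Reads a delimited text file (TSV by default, CSV when the extension is
#' `.csv`) of per-SNP association statistics into a validated summary
#' dataset. Nonstandard headers are resolved through `column_map`. Missing
#' `eaf` or `n` is tolerated at read time; operations that need them
#' (F-statistics, palindrome resolution) fail explicitly later.
#'
#' @param path path to a delimited text file with a header row.
#' @param trait_name trait label stored on the dataset.
#' @param trait_type `"continuous"` or `"binary"`; for binary traits betas are
#'   interpreted as log-odds.
#' @param column_map named character vector mapping canonical names
#'   (`rsid`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`,
#'   `n`, `chrom`, `nearest_gene`) to the file's actual headers, e.g.
#'   `c(rsid = "SNP", pvalue = "P")`. Canonical headers need no mapping.
#' @return a `summary_dataset`: a data.frame with canonical columns and
#'   attributes `trait_name` and `trait_type`.
#' @export
read_summary_stats <- function(path, trait_name = "trait",
                               trait_type = c("continuous", "binary"),
                               column_map = NULL) {
  trait_type <- match.arg(trait_type)
  df <- .read_delim_auto(path)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(df))
        stop(sprintf("column_map: column '%s' not found in %s", src, path))
      names(df)[names(df) == src] <- canon
    }
  }
  missing_cols <- setdiff(.mrkit_mandatory_cols, names(df))
  if (length(missing_cols))
    stop(sprintf("missing mandatory column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  for (col in setdiff(.mrkit_canonical_cols, names(df)))
    df[[col]] <- rep(NA, nrow(df))
  df <- df[, .mrkit_canonical_cols]
  df$rsid <- trimws(as.character(df$rsid))
  df$effect_allele <- toupper(trimws(df$effect_allele))
  df$other_allele <- toupper(trimws(df$other_allele))
  for (col in c("eaf", "beta", "se", "pvalue", "n"))
    df[[col]] <- as.numeric(df[[col]])
  if (nrow(df)) {
    msgs <- .validate_summary_rows(df)
    if (length(msgs))
      stop(sprintf("invalid summary statistics in %s:\n  %s",
                   path, paste(msgs, collapse = "\n  ")))
  }
  summary_dataset(df, trait_name = trait_name, trait_type = trait_type)
}

# rbind a list of data.frames, NULL when empty
.rbind_all <- function(lst) {
  lst <- Filter(Negate(is.null), lst)
  if (!length(lst)) return(NULL)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}

#' Construct a summary dataset from a data.frame
#'
#' @param df data.frame carrying at least rsid, alleles, beta, se, pvalue.
#' @inheritParams read_summary_stats
#' @return a validated `summary_dataset`.
#' @export
summary_dataset <- function(df, trait_name = "trait",
                            trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  for (col in setdiff(.mrkit_canonical_cols, names(df)))
    df[[col]] <- rep(NA, nrow(df))
  df <- as.data.frame(df)[, .mrkit_canonical_cols]
  rownames(df) <- NULL
  if (nrow(df)) {
    msgs <- .validate_summary_rows(df)
    if (length(msgs))
      stop(sprintf("invalid summary statistics:\n  %s",
                   paste(msgs, collapse = "\n  ")))
  }
  structure(df, trait_name = trait_name, trait_type = trait_type,
            class = c("summary_dataset", "data.frame"))
}

#' Write summary statistics to delimited text
#'
#' Inverse of [read_summary_stats()]: writes the canonical columns with a
#' header, TSV by default or CSV when `path` ends in `.csv`.
#'
#' @param ds a `summary_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(ds, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(as.data.frame(ds), path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a pairwise LD matrix
#'
#' Accepts either long-format triples (`rsid_a`, `rsid_b`, `r2`) or a square
#' matrix with rsid header and first column. Missing pairs default to
#' \eqn{r^2 = 0}; the diagonal is fixed at 1. Conflicting asymmetric entries
#' (differing by more than `1e-9`) are an error.
#'
#' @param path delimited text file.
#' @return an `ld_matrix`: symmetric numeric matrix with unit diagonal,
#'   dimnames the rsids.
#' @export
read_ld_matrix <- function(path) {
  df <- .read_delim_auto(path)
  if (ncol(df) == 3 && !all(vapply(df[, 2], is.numeric, TRUE))) {
    ld_matrix_from_pairs(df[[1]], df[[2]], as.numeric(df[[3]]))
  } else if (ncol(df) >= 2 && all(vapply(df[-1], is.numeric, TRUE)) &&
             ncol(df) == nrow(df) + 1) {
    m <- as.matrix(df[-1])
    rsids <- as.character(df[[1]])
    dimnames(m) <- list(rsids, rsids)
    if (max(abs(m - t(m))) > 1e-9)
      stop("LD matrix is not symmetric")
    diag(m) <- 1
    ld_matrix(m)
  } else {
    # three numeric-looking columns can still be triples with rsid-like ids
    ld_matrix_from_pairs(as.character(df[[1]]), as.character(df[[2]]),
                         as.numeric(df[[3]]))
  }
}

#' Build an LD matrix from long-format pairs
#'
#' @param rsid_a,rsid_b rsids of each pair.
#' @param r2 squared correlation of each pair, in `[0, 1]`.
#' @param rsids optional full rsid universe (SNPs absent from all pairs get a
#'   row/column of zeros off-diagonal).
#' @return an `ld_matrix`.
#' @export
ld_matrix_from_pairs <- function(rsid_a, rsid_b, r2, rsids = NULL) {
  rsid_a <- trimws(as.character(rsid_a)); rsid_b <- trimws(as.character(rsid_b))
  all_ids <- unique(c(rsids, rsid_a, rsid_b))
  m <- matrix(0, length(all_ids), length(all_ids),
              dimnames = list(all_ids, all_ids))
  seen <- matrix(FALSE, length(all_ids), length(all_ids),
                 dimnames = list(all_ids, all_ids))
  for (k in seq_along(rsid_a)) {
    a <- rsid_a[k]; b <- rsid_b[k]
    if (seen[a, b] && abs(m[a, b] - r2[k]) > 1e-9)
      stop(sprintf("conflicting LD entries for pair (%s, %s): %g vs %g",
                   a, b, m[a, b], r2[k]))
    m[a, b] <- r2[k]; m[b, a] <- r2[k]
    seen[a, b] <- TRUE; seen[b, a] <- TRUE
  }
  diag(m) <- 1
  ld_matrix(m)
}

#' Validate and classify an LD matrix
#'
#' @param m symmetric numeric matrix of squared correlations with rsid
#'   dimnames.
#' @return the matrix with class `ld_matrix`.
#' @export
ld_matrix <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (is.null(rownames(m))) stop("ld_matrix requires rsid dimnames")
  if (any(m < 0 | m > 1)) stop("LD r2 entries must lie in [0, 1]")
  if (max(abs(m - t(m))) > 1e-9) stop("LD matrix is not symmetric")
  if (any(abs(diag(m) - 1) > 1e-9)) stop("LD matrix diagonal must be 1")
  structure(m, class = c("ld_matrix", class(matrix())))
}

#' Look up pairwise r2 with a zero default
#' @param ld an `ld_matrix`.
#' @param a,b rsids.
#' @return r2, or 0 when either rsid is absent.
#' @keywords internal
.ld_r2 <- function(ld, a, b) {
  if (!(a %in% rownames(ld)) || !(b %in% rownames(ld))) return(0)
  unname(ld[a, b])
}

#' Read a SNP-to-trait annotation table
#'
#' PhenoScanner-export-like table with columns `rsid`, `trait`, `pvalue`
#' (extra columns are ignored; nonstandard headers resolved case-insensitively
#' for these three names).
#'
#' @param path delimited text file.
#' @return data.frame with columns rsid, trait, pvalue.
#' @export
read_trait_annotations <- function(path) {
  df <- .read_delim_auto(path)
  names(df) <- tolower(names(df))
  need <- c("rsid", "trait", "pvalue")
  if (!all(need %in% names(df)))
    stop(sprintf("annotation table needs columns %s", paste(need, collapse = ", ")))
  df <- df[, need]
  df$rsid <- trimws(as.character(df$rsid))
  df$pvalue <- as.numeric(df$pvalue)
  if (any(is.na(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1))
    stop("annotation pvalue outside (0,1]")
  df
}

#' The packaged homocysteine / atrial-fibrillation instrument table
#'
#' Loads the nine-SNP fixture: per-SNP associations with plasma homocysteine
#' (SD units, N = 44,147) and with atrial fibrillation (log-odds,
#' N = 1,030,836; 60,620 cases). Values are stored at published precision;
#' the outcome table carries no effect-allele frequencies. Alleles in the two
#' tables are already aligned.
#'
#' @return list with elements `exposure` and `outcome`, both
#'   `summary_dataset`s over the identical nine rsids.
#' @export
load_fixture_hcy_af <- function() {
  exp_path <- system.file("extdata", "hcy_exposure.tsv", package = "mrkit",
                          mustWork = TRUE)
  out_path <- system.file("extdata", "af_outcome.tsv", package = "mrkit",
                          mustWork = TRUE)
  list(
    exposure = read_summary_stats(exp_path, trait_name = "homocysteine",
                                  trait_type = "continuous"),
    outcome = read_summary_stats(out_path, trait_name = "atrial fibrillation",
                                 trait_type = "binary")
  )
}
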