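#' Flag hemolysed samples from the miR-23a/miR-451a delta-Ct indicator
#'
#' Hemolysis contaminates serum with red-blood-cell miRNAs, most prominently
#' miR-451a, while miR-23a-3p is comparatively unaffected. The widely used
#' serum-QC rule scores each sample as
#' `delta Ct = Ct(miR-23a-3p) - Ct(miR-451a)` and calls hemolysis when the
#' score exceeds a threshold (default 7 Ct).
#'
#' On quantified data (a `mirna_expression` object or copies/mL matrix) the
#' equivalent score `log2(copies(miR-451a) / copies(miR-23a-3p))` is used
#' with the same threshold; the two scores coincide under perfect
#' amplification efficiency, but the expression-scale score is additionally
#' robust to assay-specific standard-curve offsets, so it is the one the
#' orchestrator applies.
#'
#' @param ct Either a long plate-level Ct table (with a `replicate` column;
#'   duplicates are collapsed first), an already collapsed table with columns
#'   `sample_id`, `assay_id`, `ct`, or quantified expression (a
#'   `mirna_expression` object / copies-per-mL matrix).
#' @param indicator Character pair `c(reference, rbc)` of assay ids; the score
#'   is `Ct(reference) - Ct(rbc)`, or `log2(x_rbc / x_reference)` on
#'   expression input.
#' @param threshold Score threshold above which a sample is called hemolysed.
#' @return Data frame (one row per sample): `sample_id`, `hemolysis_score`,
#'   `hemolysed_call` (logical; `NA` when un-assessable), `reason`.
#' @export
flag_hemolysis <- function(ct,
                           indicator = c("hsa-miR-23a-3p", "hsa-miR-451a"),
                           threshold = 7) {
  stopifnot(length(indicator) == 2L)
  if (inherits(ct, "mirna_expression") || is.matrix(ct)) {
    x <- if (inherits(ct, "mirna_expression")) ct$values else ct
    samples <- rownames(x)
    get_col <- function(a) if (a %in% colnames(x)) x[, a] else
      rep(NA_real_, nrow(x))
    score <- log2(get_col(indicator[2]) / get_col(indicator[1]))
  } else {
    if ("replicate" %in% names(ct)) ct <- collapse_duplicates(ct)
    stopifnot(all(c("sample_id", "assay_id", "ct") %in% names(ct)))
    samples <- sort(unique(ct$sample_id))
    pick <- function(assay) {
      d <- ct[ct$assay_id == assay, , drop = FALSE]
      d$ct[match(samples, d$sample_id)]
    }
    score <- pick(indicator[1]) - pick(indicator[2])
  }
  call <- score > threshold
  reason <- ifelse(is.na(score), "indicator assay undetermined or missing",
                   ifelse(call, sprintf("deltaCt %.2f > %.1f", score, threshold),
                          "pass"))
  data.frame(sample_id = samples,
             hemolysis_score = score,
             hemolysed_call = call,
             reason = reason,
             stringsAsFactors = FALSE)
}

#' Expression filter: miRNAs detected in all subjects
#'
#' Retains a miRNA only if its quantified abundance is at or above
#' `min_copies` copies per mL serum in every sample (inclusive boundary).
#'
#' @param expression A `mirna_expression` object or a numeric matrix
#'   (samples x miRNAs, copies/mL).
#' @param min_copies Threshold in copies per mL serum (default 500).
#' @return Character vector of retained miRNA ids (in input column order).
#' @export
expression_filter <- function(expression, min_copies = 500) {
  x <- if (inherits(expression, "mirna_expression")) expression$values
       else as.matrix(expression)
  if (!nrow(x) || !ncol(x)) stop("expression matrix must be non-empty")
  keep <- apply(x, 2, function(col) all(is.finite(col)) && all(col >= min_copies))
  colnames(x)[keep]
}
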