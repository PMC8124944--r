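#' Global geometric-mean normalization
#'
#' Per-sample centering of log2 expression by the log2 geometric mean of the
#' retained miRNAs: `normalized[i, j] = log2(x[i, j]) - mean_j log2(x[i, j])`.
#' This removes sample-level scale (every row of the result has mean zero),
#' so no training statistics are needed to normalize new samples.
#'
#' @param expression A `mirna_expression` object or strictly positive matrix
#'   (samples x miRNAs, copies/mL).
#' @param retained Optional character vector restricting (and ordering) the
#'   miRNAs used; the geometric mean is computed over exactly these.
#' @return Matrix of normalized log2 expression (rows sum to zero).
#' @export
global_geomean_normalize <- function(expression, retained = NULL) {
  x <- if (inherits(expression, "mirna_expression")) expression$values
       else as.matrix(expression)
  if (!is.null(retained)) {
    miss <- setdiff(retained, colnames(x))
    if (length(miss)) stop("retained miRNA(s) missing from matrix: ",
                           paste(utils::head(miss, 5), collapse = ", "))
    x <- x[, retained, drop = FALSE]
  }
  if (any(!is.finite(x)) || any(x <= 0))
    stop("all expression values must be strictly positive and finite")
  l <- log2(x)
  l - rowMeans(l)
}

# Rank-based AUC (Mann-Whitney with midrank tie handling):
# P(score_case > score_control) + 0.5 * P(tie).
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stop("scores/labels must be complete")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Single-marker classification AUC
#'
#' Rank-based AUC of one normalized expression column against case/control
#' labels, reported in the "higher in cases" orientation:
#' `max(AUC, 1 - AUC)` with the orientation recorded.
#'
#' @param x Numeric vector (one miRNA's normalized expression).
#' @param labels Logical or two-level vector; `TRUE`/`"malignant"` = case.
#' @return List with `auc` (oriented), `auc_raw` (P(case > control) + ties/2)
#'   and `direction` (`"up"` or `"down"`).
#' @export
single_marker_auc <- function(x, labels) {
  labels <- as_case_labels(labels)
  a <- auc_rank(x, labels)
  list(auc = max(a, 1 - a), auc_raw = a,
       direction = if (a >= 0.5) "up" else "down")
}

as_case_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels != 0)
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if ("malignant" %in% lv) return(labels == "malignant")
  if (length(lv) != 2L) stop("labels must be logical or two-level")
  labels == lv[2]
}

#' Differential expression between malignant and benign groups
#'
#' Per-miRNA two-sample Student's (pooled-variance) t-test on normalized log2
#' expression, with Benjamini-Hochberg FDR adjustment across all tested
#' miRNAs. The log2 fold change is the malignant-minus-benign difference of
#' group means on the normalized log2 scale. Each miRNA's individual
#' classification AUC is reported alongside.
#'
#' @param normalized Matrix samples x miRNAs of normalized log2 expression.
#' @param labels Case/control labels (one per row); `TRUE`/`"malignant"` =
#'   case.
#' @param alpha FDR level for the significance call (default 0.05).
#' @return Data frame, one row per miRNA, ordered by p-value: `mirna_id`,
#'   `log2fc`, `t`, `p`, `q`, `auc_single` (oriented), `direction`,
#'   `significant`, `zero_variance`.
#' @export
differential_expression <- function(normalized, labels, alpha = 0.05) {
  x <- as.matrix(normalized)
  y <- as_case_labels(labels)
  if (length(y) != nrow(x)) stop("one label per sample (row) required")
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 < 2L || n0 < 2L) stop("need at least 2 samples per group")
  m1 <- colMeans(x[y, , drop = FALSE])
  m0 <- colMeans(x[!y, , drop = FALSE])
  v1 <- apply(x[y, , drop = FALSE], 2, stats::var)
  v0 <- apply(x[!y, , drop = FALSE], 2, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n0))
  log2fc <- m1 - m0
  tstat <- log2fc / se
  df <- n1 + n0 - 2
  p <- 2 * stats::pt(-abs(tstat), df)
  zero_var <- !is.finite(se) | se == 0
  p[zero_var] <- 1; tstat[zero_var] <- 0
  q <- stats::p.adjust(p, method = "BH")
  auc <- vapply(seq_len(ncol(x)), function(j) auc_rank(x[, j], y), numeric(1))
  out <- data.frame(mirna_id = colnames(x),
                    log2fc = unname(log2fc),
                    t = unname(tstat),
                    p = unname(p),
                    q = unname(q),
                    auc_single = pmax(auc, 1 - auc),
                    direction = ifelse(log2fc >= 0, "up", "down"),
                    significant = unname(q < alpha),
                    zero_variance = unname(zero_var),
                    stringsAsFactors = FALSE)
  out[order(out$p, out$mirna_id), , drop = FALSE]
}
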