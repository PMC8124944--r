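#' ROC curve and AUC
#'
#' Rank-based AUC with midrank tie correction, plus the ROC polygon: at every
#' distinct score threshold `t` a sample is called positive when its score is
#' `>= t`, yielding one (1 - specificity, sensitivity) point.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels Case/control labels.
#' @return Object of class `roc`: `auc` and `curve` (data frame `threshold`,
#'   `sensitivity`, `specificity`).
#' @export
roc_auc <- function(scores, labels) {
  y <- as_case_labels(labels)
  auc <- auc_rank(scores, y)
  thr <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(y); n0 <- sum(!y)
  sens <- vapply(thr, function(t) sum(scores[y] >= t) / n1, numeric(1))
  spec <- vapply(thr, function(t) sum(scores[!y] < t) / n0, numeric(1))
  structure(list(auc = auc,
                 curve = data.frame(threshold = thr, sensitivity = sens,
                                    specificity = spec)),
            class = "roc")
}

#' @export
print.roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f over %d thresholds\n", x$auc, nrow(x$curve)))
  invisible(x)
}

#' Choose an operating cutoff on the score scale
#'
#' Candidate cutoffs are the midpoints between consecutive distinct observed
#' scores. In `high_specificity` mode the smallest cutoff whose specificity
#' reaches the target is returned (maximising sensitivity subject to the
#' specificity constraint); in `high_sensitivity` mode the largest cutoff
#' whose sensitivity reaches the target (maximising specificity subject to
#' the sensitivity constraint). A sample is called positive when its score is
#' `>= cutoff`.
#'
#' @param scores,labels Scores and case/control labels.
#' @param mode `"high_specificity"` or `"high_sensitivity"`.
#' @param target Target value of the constrained metric; defaults to 0.90 for
#'   specificity and 0.80 for sensitivity.
#' @return List: `mode`, `target`, `cutoff`, `sensitivity`, `specificity` at
#'   the cutoff. Errors if the target is unreachable, naming the best
#'   attainable value.
#' @export
choose_cutoff <- function(scores, labels,
                          mode = c("high_specificity", "high_sensitivity"),
                          target = NULL) {
  mode <- match.arg(mode)
  y <- as_case_labels(labels)
  if (is.null(target)) target <- if (mode == "high_specificity") 0.90 else 0.80
  s <- sort(unique(scores))
  if (length(s) < 2L) stop("need at least two distinct scores")
  mids <- (s[-1] + s[-length(s)]) / 2
  n1 <- sum(y); n0 <- sum(!y)
  sens <- vapply(mids, function(t) sum(scores[y] >= t) / n1, numeric(1))
  spec <- vapply(mids, function(t) sum(scores[!y] < t) / n0, numeric(1))
  if (mode == "high_specificity") {
    ok <- which(spec >= target)
    if (!length(ok))
      stop(sprintf("specificity target %.3f unreachable; best attainable is %.3f",
                   target, max(spec)))
    i <- min(ok)   # smallest qualifying cutoff -> max sensitivity
  } else {
    ok <- which(sens >= target)
    if (!length(ok))
      stop(sprintf("sensitivity target %.3f unreachable; best attainable is %.3f",
                   target, max(sens)))
    i <- max(ok)   # largest qualifying cutoff -> max specificity
  }
  list(mode = mode, target = target, cutoff = mids[i],
       sensitivity = sens[i], specificity = spec[i])
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return Numeric vector `c(estimate, lower, upper)`; all `NA` when `n = 0`.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(estimate = NA_real_, lower = NA_real_, upper = NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(estimate = p, lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Confusion metrics at a score cutoff
#'
#' Samples with `score >= cutoff` are called positive. Sensitivity,
#' specificity, PPV and NPV are reported with 95% Wilson score intervals.
#' Metrics with an empty denominator are flagged rather than propagated as
#' NaN.
#'
#' @param scores,labels Scores and case/control labels.
#' @param cutoff Finite score threshold.
#' @param conf Confidence level of the intervals.
#' @return Object of class `cutoff_report`: `cutoff`, `counts` (TP/FP/TN/FN),
#'   `metrics` (data frame: metric, estimate, lower, upper, defined).
#' @export
confusion_metrics <- function(scores, labels, cutoff, conf = 0.95) {
  stopifnot(is.finite(cutoff))
  y <- as_case_labels(labels)
  pos <- scores >= cutoff
  tp <- sum(pos & y);  fn <- sum(!pos & y)
  fp <- sum(pos & !y); tn <- sum(!pos & !y)
  rows <- list(sensitivity = c(tp, tp + fn),
               specificity = c(tn, tn + fp),
               ppv = c(tp, tp + fp),
               npv = c(tn, tn + fn))
  metrics <- do.call(rbind, lapply(names(rows), function(m) {
    kN <- rows[[m]]
    ci <- wilson_ci(kN[1], kN[2], conf)
    data.frame(metric = m, estimate = ci[1], lower = ci[2], upper = ci[3],
               defined = kN[2] > 0, stringsAsFactors = FALSE)
  }))
  rownames(metrics) <- NULL
  structure(list(cutoff = cutoff,
                 counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 metrics = metrics),
            class = "cutoff_report")
}

#' @export
print.cutoff_report <- function(x, ...) {
  cat(sprintf("Cutoff %.4f: TP %d FP %d TN %d FN %d\n", x$cutoff,
              x$counts["TP"], x$counts["FP"], x$counts["TN"], x$counts["FN"]))
  print(x$metrics)
  invisible(x)
}

# Jonckheere-Terpstra statistic: sum over ordered group pairs (i < j) of
# Mann-Whitney counts #(x_j > x_i) + 0.5 #(ties).
jt_statistic <- function(scores, g) {
  lev <- sort(unique(g))
  stat <- 0
  for (a in seq_along(lev)[-length(lev)]) for (b in (a + 1):length(lev)) {
    xa <- scores[g == lev[a]]; xb <- scores[g == lev[b]]
    d <- outer(xb, xa, `-`)
    stat <- stat + sum(d > 0) + 0.5 * sum(d == 0)
  }
  stat
}

#' Ordered trend of biomarker scores across clinicopathological groups
#'
#' Per-group summaries (n, median, quartiles) over an ordinal grouping
#' (tumour size class, stage, nodal class) plus a Jonckheere-Terpstra test
#' for an increasing trend, with a seeded permutation null. Samples with
#' missing group values are excluded and counted.
#'
#' @param scores Numeric biomarker scores (typically of malignant samples).
#' @param groups Ordinal grouping (ordered factor, or a vector whose sorted
#'   unique values give the intended order).
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Seed for the permutation null.
#' @return Object of class `trend_report`: `summary` (per-group table),
#'   `statistic`, `z` (permutation-standardised), `p_value` (one-sided,
#'   increasing trend), `n_missing`, `n_perm`.
#' @export
trend_by_group <- function(scores, groups, n_perm = 10000L, seed = 1L) {
  if (is.ordered(groups) || is.factor(groups)) {
    lev <- levels(groups)
    g <- as.integer(groups)
  } else {
    lev <- sort(unique(groups[!is.na(groups)]))
    g <- match(groups, lev)
  }
  keep <- !is.na(g) & !is.na(scores)
  n_missing <- sum(!keep)
  g <- g[keep]; x <- scores[keep]
  used <- sort(unique(g))
  if (length(used) < 2L) stop("need at least 2 non-empty ordered groups")
  smry <- do.call(rbind, lapply(used, function(l) {
    v <- x[g == l]
    data.frame(group = lev[l], n = length(v),
               median = stats::median(v),
               q1 = unname(stats::quantile(v, 0.25)),
               q3 = unname(stats::quantile(v, 0.75)),
               stringsAsFactors = FALSE)
  }))
  obs <- jt_statistic(x, g)
  set.seed(child_seed(seed, "jt-perm"))
  perm <- vapply(seq_len(n_perm),
                 function(i) jt_statistic(x, g[sample.int(length(g))]),
                 numeric(1))
  p <- (1 + sum(perm >= obs)) / (n_perm + 1)
  z <- (obs - mean(perm)) / stats::sd(perm)
  structure(list(summary = smry, statistic = obs, z = z, p_value = p,
                 n_missing = n_missing, n_perm = as.integer(n_perm)),
            class = "trend_report")
}

#' @export
print.trend_report <- function(x, ...) {
  print(x$summary)
  cat(sprintf("JT statistic %.1f (z = %.2f), one-sided permutation p = %.4g (%d perms, %d excluded)\n",
              x$statistic, x$z, x$p_value, x$n_perm, x$n_missing))
  invisible(x)
}

#' Evaluate a frozen panel model on an evaluation set
#'
#' No refitting: scores are computed with the model's frozen coefficients and
#' standardization. Because the normalization is per-sample (geometric-mean
#' centering), evaluation sets need no training statistics. Reports the AUC
#' against the chosen control definition plus both operating points
#' (high-specificity and high-sensitivity) with their confusion metrics.
#'
#' @param model A `panel_model`.
#' @param normalized Normalized log2 expression matrix of the evaluation set.
#' @param labels Case/control labels (`TRUE`/`"malignant"` = case; controls
#'   may be benign only, or benign plus normals — the caller chooses which
#'   rows to pass).
#' @param spec_target,sens_target Operating-point targets (defaults 0.90 and
#'   0.80).
#' @return List: `auc`, `roc`, `scores`, `cutoffs` (named list of operating
#'   points, each with the `choose_cutoff()` result and a `cutoff_report`;
#'   `NULL` with a message when a target is unreachable).
#' @export
evaluate_frozen <- function(model, normalized, labels,
                            spec_target = 0.90, sens_target = 0.80) {
  scores <- score_panel(model, normalized)
  y <- as_case_labels(labels)
  roc <- roc_auc(scores, y)
  mk <- function(mode, target) {
    cut <- tryCatch(choose_cutoff(scores, y, mode, target),
                    error = function(e) conditionMessage(e))
    if (is.character(cut)) return(list(error = cut))
    list(cutoff = cut, report = confusion_metrics(scores, y, cut$cutoff))
  }
  list(auc = roc$auc, roc = roc, scores = scores,
       cutoffs = list(high_specificity = mk("high_specificity", spec_target),
                      high_sensitivity = mk("high_sensitivity", sens_target)))
}
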