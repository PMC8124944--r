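#' Candidate sets for the panel search strategies
#'
#' `focused_candidates()` implements the focused strategy: restrict the
#' search to the differentially expressed miRNAs (FDR-adjusted p < alpha),
#' ordered by increasing p-value. `unbiased_candidates()` implements the
#' unbiased strategy: search among all retained (expressed) miRNAs.
#'
#' @param de Differential-expression table from [differential_expression()].
#' @param alpha FDR significance level.
#' @return Character vector of candidate miRNA ids.
#' @export
focused_candidates <- function(de, alpha = 0.05) {
  stopifnot(all(c("mirna_id", "p", "q") %in% names(de)))
  sig <- de[de$q < alpha, , drop = FALSE]
  if (!nrow(sig))
    stop("no miRNA passes the FDR threshold (q < ", alpha,
         "); consider the unbiased strategy")
  sig$mirna_id[order(sig$p, sig$mirna_id)]
}

#' @rdname focused_candidates
#' @param retained Character vector of retained miRNA ids (the expression
#'   filter output).
#' @export
unbiased_candidates <- function(retained) {
  retained <- as.character(retained)
  if (!length(retained)) stop("retained miRNA list is empty")
  unique(retained)
}

# stratified half/half split: returns logical vector, TRUE = fold A.
# Class ratio is preserved to +/- 1 sample; the odd member of each class
# alternates folds so both halves stay balanced.
stratified_half_split <- function(y) {
  inA <- logical(length(y))
  for (cls in c(TRUE, FALSE)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    half <- floor(length(idx) / 2)
    extraA <- length(idx) %% 2 == 1 && stats::runif(1) < 0.5
    nA <- half + as.integer(extraA)
    inA[idx[seq_len(nA)]] <- TRUE
  }
  inA
}

#' Repeated two-fold cross-validated panel search
#'
#' For each of `rounds` rounds, samples are partitioned into equally-sized
#' (stratified) training and test halves. Both fold assignments are
#' evaluated: on the training half, SFFS selects exactly `k` candidate
#' miRNAs, with the objective being the training AUC of a ridge-stabilised
#' logistic model refit on each examined subset; the selected panel is then
#' refit on the training half and its AUC measured on the held-out half
#' (features standardized by frozen training-fold mean/SD). The optimal
#' panel is the top-`k` miRNAs by selection frequency over all round x fold
#' entries, refit once on the full input.
#'
#' @param normalized Matrix samples x miRNAs (normalized log2 expression).
#' @param labels Case/control labels (`TRUE`/`"malignant"` = case).
#' @param candidates Candidate miRNA ids (must be columns of `normalized`);
#'   ties everywhere are broken by this order.
#' @param k Panel size.
#' @param rounds Number of cross-validation rounds (default 200).
#' @param seed Integer seed controlling the random splits.
#' @param lambda Ridge penalty of the logistic fits.
#' @return Object of class `panel_search_result`: `k`, `rounds` (per-fold
#'   log: round, fold, panel, test_auc), `median_auc` (median of all per-fold
#'   test AUCs), `selection_frequency` (per candidate), `model` (the optimal
#'   `panel_model` refit on the full input), `resubstitution_auc`, `seed`.
#' @export
cv_panel_search <- function(normalized, labels, candidates, k, rounds = 200L,
                            seed = 1L, lambda = 1e-4) {
  x <- as.matrix(normalized)
  y <- as_case_labels(labels)
  candidates <- as.character(candidates)
  miss <- setdiff(candidates, colnames(x))
  if (length(miss)) stop("candidate miRNA(s) missing from matrix: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  if (k > length(candidates))
    stop("k must not exceed the number of candidates")
  if (!sum(y) || !sum(!y)) stop("both classes must be present")
  X <- x[, candidates, drop = FALSE]

  set.seed(as.integer(seed))
  log_rows <- vector("list", 2L * rounds)
  sel_count <- stats::setNames(numeric(length(candidates)), candidates)
  entry <- 0L
  for (r in seq_len(rounds)) {
    inA <- stratified_half_split(y)
    for (fold in 1:2) {
      tr <- if (fold == 1L) inA else !inA
      Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
      Xte <- X[!tr, , drop = FALSE]; yte <- y[!tr]
      ctr <- colMeans(Xtr)
      sc <- apply(Xtr, 2, stats::sd)
      sc[!is.finite(sc) | sc <= 0] <- 1
      Ztr <- sweep(sweep(Xtr, 2, ctr, `-`), 2, sc, `/`)
      Zte <- sweep(sweep(Xte, 2, ctr, `-`), 2, sc, `/`)
      obj <- function(sub) {
        fit <- fit_ridge_logistic(Ztr[, sub, drop = FALSE], ytr,
                                  lambda = lambda)
        lp <- drop(Ztr[, sub, drop = FALSE] %*% fit$coefficients)
        auc_rank(lp, ytr)
      }
      sel <- sffs(candidates, k, obj)$selected
      fit <- fit_ridge_logistic(Ztr[, sel, drop = FALSE], ytr,
                                lambda = lambda)
      lp_te <- drop(fit$intercept +
                      Zte[, sel, drop = FALSE] %*% fit$coefficients)
      test_auc <- auc_rank(lp_te, yte)
      entry <- entry + 1L
      log_rows[[entry]] <- data.frame(round = r, fold = fold,
                                      panel = paste(sel, collapse = ";"),
                                      test_auc = test_auc,
                                      stringsAsFactors = FALSE)
      sel_count[sel] <- sel_count[sel] + 1
    }
  }
  log_df <- do.call(rbind, log_rows)
  freq <- sel_count / (2 * rounds)
  ord <- order(-freq, seq_along(freq))
  opt <- candidates[ord[seq_len(k)]]

  ctr <- colMeans(X[, opt, drop = FALSE])
  scl <- apply(X[, opt, drop = FALSE], 2, stats::sd)
  scl[!is.finite(scl) | scl <= 0] <- 1
  Z <- sweep(sweep(X[, opt, drop = FALSE], 2, ctr, `-`), 2, scl, `/`)
  fit <- fit_ridge_logistic(Z, y, lambda = lambda)
  model <- panel_model(opt, fit$coefficients, fit$intercept, ctr, scl)
  resub <- auc_rank(score_panel(model, x), y)

  structure(list(k = as.integer(k),
                 strategy = NA_character_,
                 rounds = log_df,
                 median_auc = stats::median(log_df$test_auc),
                 selection_frequency = freq,
                 model = model,
                 resubstitution_auc = resub,
                 seed = as.integer(seed),
                 lambda = lambda),
            class = "panel_search_result")
}

#' @export
print.panel_search_result <- function(x, ...) {
  cat(sprintf("Panel search (k = %d, %d rounds x 2 folds%s)\n",
              x$k, max(x$rounds$round),
              if (is.na(x$strategy)) "" else paste0(", ", x$strategy)))
  cat(sprintf("  median CV test AUC: %.3f; resubstitution AUC: %.3f\n",
              x$median_auc, x$resubstitution_auc))
  cat("  optimal panel:", paste(x$model$mirnas, collapse = ", "), "\n")
  invisible(x)
}
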