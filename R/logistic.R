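# Ridge-penalised logistic regression by Newton-Raphson with step halving.
# The small default penalty (lambda = 1e-4 on standardized features, none on
# the intercept) keeps the fit finite under complete separation, which occurs
# routinely in small cross-validation folds.

#' Fit a ridge-stabilised logistic regression
#'
#' @param X Numeric matrix of (already standardized) features, samples x p.
#' @param y Logical or 0/1 outcome vector.
#' @param lambda Ridge penalty on the feature coefficients (intercept
#'   unpenalised).
#' @param max_iter,tol Newton iteration controls.
#' @return List with `intercept`, `coefficients` (length p), `converged`,
#'   `iterations`, `deviance` (penalised).
#' @export
fit_ridge_logistic <- function(X, y, lambda = 1e-4, max_iter = 50L,
                               tol = 1e-9) {
  X <- as.matrix(X)
  y <- as.numeric(as_case_labels(y))
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("one outcome per row required")
  Xd <- cbind(`(Intercept)` = 1, X)
  pen <- c(0, rep(lambda, p))
  beta <- numeric(p + 1L)
  obj <- function(b) {
    eta <- drop(Xd %*% b)
    # numerically safe -log likelihood + ridge
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) +
      sum(pen * b^2) / 2
  }
  f <- obj(beta)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    g <- drop(crossprod(Xd, y - mu)) - pen * beta
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    H <- crossprod(Xd * w, Xd)
    diag(H) <- diag(H) + pen + 1e-12
    delta <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(delta)) break
    step <- 1
    repeat {
      cand <- beta + step * delta
      fc <- obj(cand)
      if (is.finite(fc) && fc <= f + 1e-12) { beta <- cand; f <- fc; break }
      step <- step / 2
      if (step < 1e-8) break
    }
    if (step < 1e-8) break
  }
  list(intercept = unname(beta[1]),
       coefficients = stats::setNames(beta[-1], colnames(X)),
       converged = converged, iterations = it,
       deviance = 2 * f)
}

#' Sequential forward floating selection (SFFS)
#'
#' Classic SFFS: repeatedly add the single candidate that maximises the
#' objective, then conditionally remove members while removal improves on the
#' best score known at the smaller size. Terminates once the target size `k`
#' is reached and no further floating removal helps; returns the best subset
#' of exactly size `k`. Ties are broken by candidate-list order.
#'
#' @param candidates Vector of candidate identifiers (any type).
#' @param k Target subset size (1 <= k <= length(candidates)).
#' @param objective Function taking a subset of `candidates` (in candidate
#'   order) and returning a scalar score to maximise.
#' @param max_sweeps Safety cap on inclusion steps.
#' @return List with `selected` (subset, candidate order), `score`, and
#'   `evaluations` (number of distinct objective calls).
#' @export
sffs <- function(candidates, k, objective, max_sweeps = NULL) {
  n <- length(candidates)
  if (k < 1L || k > n) stop("k must satisfy 1 <= k <= length(candidates)")
  cache <- new.env(hash = TRUE, parent = emptyenv())
  n_eval <- 0L
  score_of <- function(idx) {
    keyv <- paste(sort(idx), collapse = ",")
    if (!is.null(cache[[keyv]])) return(cache[[keyv]])
    val <- objective(candidates[sort(idx)])
    n_eval <<- n_eval + 1L
    cache[[keyv]] <- val
    val
  }
  best <- vector("list", k)   # best known (idx, score) per size
  best_score <- rep(-Inf, k)
  note_best <- function(idx, s) {
    sz <- length(idx)
    if (sz <= k && s > best_score[sz]) {
      best_score[sz] <<- s
      best[[sz]] <<- sort(idx)
    }
  }
  current <- integer()
  if (is.null(max_sweeps)) max_sweeps <- 4L * k * max(n, 2L)
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    if (sweeps > max_sweeps) break
    # inclusion
    avail <- setdiff(seq_len(n), current)
    sc <- vapply(avail, function(j) score_of(c(current, j)), numeric(1))
    jbest <- avail[which.max(sc)]
    current <- sort(c(current, jbest))
    note_best(current, max(sc))
    # conditional exclusion
    while (length(current) > 2L) {
      sc_rm <- vapply(current, function(j) score_of(setdiff(current, j)),
                      numeric(1))
      jrm <- current[which.max(sc_rm)]
      if (max(sc_rm) > best_score[length(current) - 1L]) {
        current <- setdiff(current, jrm)
        note_best(current, max(sc_rm))
      } else break
    }
    if (length(current) == k) break
  }
  if (!is.finite(best_score[k])) stop("SFFS failed to reach size ", k)
  list(selected = candidates[best[[k]]],
       score = best_score[k],
       evaluations = n_eval)
}
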