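# Independent oracles used to verify the package's statistical primitives.
# These are deliberately naive (brute-force enumeration / textbook formulas)
# and share no code with the implementation.

# AUC by all-pairs concordance counting (ties count one half)
brute_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (a in pos) for (b in neg) {
    if (a > b) total <- total + 1
    else if (a == b) total <- total + 0.5
  }
  total / (length(pos) * length(neg))
}

# Benjamini-Hochberg step-up written from the definition:
# q_(i) = min_{j >= i} m * p_(j) / j, mapped back to input order
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# Jonckheere-Terpstra statistic by explicit triple loops
brute_jt <- function(x, g) {
  lev <- sort(unique(g))
  total <- 0
  for (a in seq_along(lev)) for (b in seq_along(lev)) {
    if (b <= a) next
    for (xi in x[g == lev[a]]) for (xj in x[g == lev[b]]) {
      if (xj > xi) total <- total + 1
      else if (xj == xi) total <- total + 0.5
    }
  }
  total
}

# Ordinary least squares of y on x from the textbook closed form
brute_ols <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  c(intercept = my - slope * mx, slope = slope)
}

# Plain sequential forward selection (no floating), ties by candidate order
forward_selection <- function(candidates, k, objective) {
  current <- c()
  score <- -Inf
  for (i in seq_len(k)) {
    avail <- setdiff(candidates, current)
    sc <- vapply(avail, function(a) objective(sort(c(current, a))), numeric(1))
    current <- c(current, avail[which.max(sc)])
    score <- max(sc)
  }
  list(selected = sort(current), score = score)
}

# Objective with nested optima: features 1 and 2 are individually weak but
# jointly strong, and their best completion is feature 4; feature 3 is the
# best single. Plain forward selection locks onto 3 and ends at {1,2,3};
# floating lets SFFS back out of 3 and reach the exhaustive optimum {1,2,4}.
nested_objective <- function(s) {
  key <- paste(sort(s), collapse = ",")
  switch(key,
         "3" = 0.60,
         "1" = , "2" = , "4" = 0.30,
         "1,2" = 0.80,
         "1,3" = , "2,3" = , "3,4" = 0.65,
         "1,4" = , "2,4" = 0.35,
         "1,2,4" = 0.95,
         "1,2,3" = 0.85,
         "1,3,4" = , "2,3,4" = 0.70,
         0.40)
}

# A small synthetic cohort configuration for fast tests; override any field.
small_config <- function(...) {
  defaults <- list(n_benign_discovery = 40L, n_malignant_discovery = 20L,
                   n_benign_validation = 40L, n_malignant_validation = 20L,
                   n_normal = 10L, n_mirnas = 36L, n_expressed = 24L,
                   seed = 1L)
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_config, args)
}

no_effects <- function() stats::setNames(numeric(0), character(0))

# Run simulate -> quantify for a config, returning expression + cohort
quantified <- function(cfg) {
  std <- generate_standard_curve_plate(cfg)
  coh <- generate_cohort(cfg)
  expr <- quantify(coh$ct, fit_standard_curves(std$ct),
                   floor_ct = cfg$ct_ceiling)
  list(cohort = coh, expr = expr, curves = fit_standard_curves(std$ct))
}
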