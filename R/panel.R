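#' Construct a frozen miRNA panel model
#'
#' A panel is an ordered miRNA list with logistic-regression coefficients, an
#' intercept, and frozen per-feature standardization parameters (training
#' mean and SD). The biomarker score of a sample is
#' `P = plogis(b0 + sum_i beta_i * z_i)` with
#' `z_i = (x_i - center_i) / scale_i`, where `x_i` is the sample's normalized
#' log2 expression of panel miRNA i. Higher scores mean higher probability of
#' malignancy.
#'
#' @param mirnas Ordered character vector of panel miRNA ids.
#' @param coefficients Numeric vector, one coefficient per miRNA.
#' @param intercept Scalar intercept.
#' @param center,scale Frozen standardization parameters (training mean/SD
#'   per miRNA; all scales must be > 0).
#' @return Object of class `panel_model`.
#' @export
panel_model <- function(mirnas, coefficients, intercept, center, scale) {
  mirnas <- as.character(mirnas)
  k <- length(mirnas)
  if (length(coefficients) != k || length(center) != k || length(scale) != k)
    stop("mirnas, coefficients, center and scale must have equal length")
  if (any(!is.finite(scale)) || any(scale <= 0))
    stop("all standardization scales must be strictly positive")
  structure(list(mirnas = mirnas,
                 coefficients = stats::setNames(as.numeric(coefficients), mirnas),
                 intercept = as.numeric(intercept),
                 center = stats::setNames(as.numeric(center), mirnas),
                 scale = stats::setNames(as.numeric(scale), mirnas)),
            class = "panel_model")
}

#' @export
print.panel_model <- function(x, ...) {
  cat(sprintf("miRNA panel model (k = %d), intercept %.4f\n",
              length(x$mirnas), x$intercept))
  print(data.frame(mirna = x$mirnas,
                   coefficient = unname(x$coefficients),
                   center = unname(x$center),
                   scale = unname(x$scale)))
  invisible(x)
}

#' Biomarker score of samples under a frozen panel model
#'
#' @param model A `panel_model`.
#' @param x Matrix of normalized log2 expression (samples x miRNAs; columns
#'   must include all panel miRNAs) or a single named vector.
#' @return Numeric vector of scores in (0, 1).
#' @export
score_panel <- function(model, x) {
  stopifnot(inherits(model, "panel_model"))
  if (is.null(dim(x))) x <- matrix(x, 1, dimnames = list(NULL, names(x)))
  miss <- setdiff(model$mirnas, colnames(x))
  if (length(miss))
    stop("panel miRNA(s) missing from input: ", paste(miss, collapse = ", "))
  z <- sweep(sweep(x[, model$mirnas, drop = FALSE], 2, model$center, `-`),
             2, model$scale, `/`)
  stats::plogis(drop(model$intercept + z %*% model$coefficients))
}

#' @export
predict.panel_model <- function(object, newdata, ...) score_panel(object, newdata)

#' Write / read a panel model as flat JSON text
#'
#' @param model A `panel_model`.
#' @param path File path.
#' @return `write_panel_model()` returns `path` invisibly; `read_panel_model()`
#'   returns a `panel_model`.
#' @export
write_panel_model <- function(model, path) {
  stopifnot(inherits(model, "panel_model"))
  obj <- list(mirnas = model$mirnas,
              coefficients = unname(model$coefficients),
              intercept = model$intercept,
              center = unname(model$center),
              scale = unname(model$scale))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_panel_model
#' @export
read_panel_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  panel_model(obj$mirnas, obj$coefficients, obj$intercept,
              obj$center, obj$scale)
}
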