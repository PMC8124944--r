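#' Read and write the standard CSV interchange formats
#'
#' Plate-level Ct tables use columns `sample_id`, `assay_id`, `replicate`,
#' `ct` (empty `ct` = undetermined); standards tables additionally carry
#' `copies`. Expression matrices are written wide (rows = samples, columns =
#' miRNAs, values = copies/mL or normalized log2).
#'
#' @param x Object to write.
#' @param path File path.
#' @return Readers return data frames / matrices; writers return `path`
#'   invisibly.
#' @export
write_ct_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_ct_table
#' @export
read_ct_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "assay_id", "replicate", "ct")
  miss <- setdiff(setdiff(need, "replicate"), names(d))
  if (length(miss)) stop("Ct table missing column(s): ",
                         paste(miss, collapse = ", "))
  d$ct <- as.numeric(d$ct)
  d
}

#' @rdname write_ct_table
#' @export
write_expression_matrix <- function(x, path) {
  if (inherits(x, "mirna_expression")) x <- x$values
  d <- data.frame(sample_id = rownames(x), as.data.frame(x),
                  check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ct_table
#' @export
read_expression_matrix <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname write_ct_table
#' @export
write_standard_curves <- function(x, path) {
  d <- do.call(rbind, lapply(x, function(cv)
    data.frame(assay_id = cv$assay_id %||% NA_character_,
               slope = cv$slope, intercept = cv$intercept,
               efficiency = cv$efficiency, r2 = cv$r2, n = cv$n,
               stringsAsFactors = FALSE)))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ct_table
#' @export
read_standard_curves <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(d)), function(i)
    structure(list(assay_id = d$assay_id[i], slope = d$slope[i],
                   intercept = d$intercept[i], efficiency = d$efficiency[i],
                   r2 = d$r2[i], n = d$n[i]),
              class = "standard_curve"))
  stats::setNames(out, d$assay_id)
}

#' @rdname write_ct_table
#' @export
write_annotations <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_ct_table
#' @export
read_annotations <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  if (is.character(d$hemolysed_truth))
    d$hemolysed_truth <- d$hemolysed_truth %in% c("TRUE", "true", "1")
  d
}
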