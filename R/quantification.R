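#' Fit a standard curve for one assay
#'
#' Ordinary least squares of Ct on log10(copies) over a serial-dilution
#' calibration series. The amplification efficiency is derived from the slope
#' as `E = 10^(-1/m) - 1` (perfect doubling gives `m = -log2(10) = -3.3219`,
#' `E = 1`).
#'
#' @param dilution_cts Data frame with columns `copies` and `ct` (rows with
#'   undetermined Ct are dropped); typically one assay's subset of a
#'   [generate_standard_curve_plate()] table.
#' @param assay_id Optional assay identifier stored in the result.
#' @return Object of class `standard_curve`: `assay_id`, `slope`,
#'   `intercept`, `efficiency`, `r2`, `n`.
#' @export
fit_standard_curve <- function(dilution_cts, assay_id = NULL) {
  stopifnot(all(c("copies", "ct") %in% names(dilution_cts)))
  d <- dilution_cts[is.finite(dilution_cts$ct), , drop = FALSE]
  if (any(d$copies <= 0)) stop("dilution copies must be strictly positive")
  if (length(unique(d$copies)) < 3L)
    stop("calibration error: need at least 3 distinct dilution levels ",
         "with finite Ct")
  x <- log10(d$copies)
  fit <- stats::lm.fit(cbind(1, x), d$ct)
  b <- unname(fit$coefficients[1]); m <- unname(fit$coefficients[2])
  if (!is.finite(m) || m >= 0)
    stop("calibration error: fitted slope must be negative (got ",
         format(m), ")")
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((d$ct - mean(d$ct))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(assay_id = assay_id %||% attr(dilution_cts, "assay_id"),
                 slope = m, intercept = b,
                 efficiency = 10^(-1 / m) - 1,
                 r2 = r2, n = nrow(d)),
            class = "standard_curve")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve%s: Ct = %.4f %+.4f * log10(copies), E = %.1f%%, R2 = %.4f (n = %d)\n",
              if (is.null(x$assay_id)) "" else paste0(" [", x$assay_id, "]"),
              x$intercept, x$slope, 100 * x$efficiency, x$r2, x$n))
  invisible(x)
}

#' Fit standard curves for every assay on a calibration plate
#'
#' @param standards Long-format standards table with columns `assay_id`,
#'   `copies`, `ct` (e.g. `generate_standard_curve_plate(cfg)$ct`).
#' @return Named list of `standard_curve` objects.
#' @export
fit_standard_curves <- function(standards) {
  stopifnot(all(c("assay_id", "copies", "ct") %in% names(standards)))
  sp <- split(standards, standards$assay_id)
  lapply(sp, function(d) fit_standard_curve(d, assay_id = d$assay_id[1]))
}

#' Interpolate Ct values to copies per reaction
#'
#' Inverts the standard curve: `copies = 10^((b - ct) / (-m))`. Undetermined
#' Ct values (`NA`) are assigned the detection-floor copy number, i.e. the
#' curve value at `floor_ct`; they are never zero so that downstream log
#' transforms stay defined.
#'
#' @param ct Numeric vector of Ct values (`NA` = undetermined).
#' @param curve A `standard_curve`.
#' @param floor_ct Detection floor in Ct units (default 40).
#' @return Numeric vector of copies per reaction.
#' @export
ct_to_copies <- function(ct, curve, floor_ct = 40) {
  stopifnot(inherits(curve, "standard_curve"))
  ct <- ifelse(is.na(ct), floor_ct, ct)
  10 ^ ((curve$intercept - ct) / (-curve$slope))
}

#' @rdname ct_to_copies
#' @param copies Copies per reaction.
#' @export
copies_to_ct <- function(copies, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  curve$intercept + curve$slope * log10(copies)
}

#' Collapse technical duplicate wells
#'
#' One row per sample x assay: the mean of finite replicate Ct values.
#' Replicate pairs differing by more than `discordance_threshold` Ct are
#' flagged `discordant`; pairs with a single finite replicate are flagged
#' `single`; pairs with no finite replicate stay undetermined.
#'
#' @param ct_table Long Ct table (`sample_id`, `assay_id`, `replicate`, `ct`).
#' @param discordance_threshold Maximum |delta Ct| between duplicates before
#'   flagging (default 1.0, a common qPCR QC heuristic).
#' @return Data frame `sample_id`, `assay_id`, `ct`, `n_finite`, `flag`.
#' @export
collapse_duplicates <- function(ct_table, discordance_threshold = 1.0) {
  stopifnot(all(c("sample_id", "assay_id", "replicate", "ct") %in%
                  names(ct_table)))
  if (max(table(paste(ct_table$sample_id, ct_table$assay_id, sep = "\r"))) > 2L)
    stop("more than 2 replicates per sample x assay are not supported")
  key <- paste(ct_table$sample_id, ct_table$assay_id, sep = "\r")
  uk <- unique(key)
  idx <- match(key, uk)
  nk <- length(uk)
  ct1 <- rep(NA_real_, nk); ct2 <- rep(NA_real_, nk)
  first <- !duplicated(idx)
  ct1[idx[first]] <- ct_table$ct[first]
  ct2[idx[!first]] <- ct_table$ct[!first]
  fin1 <- is.finite(ct1); fin2 <- is.finite(ct2)
  n_fin <- fin1 + fin2
  mean_ct <- ifelse(n_fin == 2L, (ct1 + ct2) / 2,
                    ifelse(fin1, ct1, ct2))
  mean_ct[n_fin == 0L] <- NA_real_
  flag <- rep("concordant", nk)
  flag[n_fin == 2L & abs(ct1 - ct2) > discordance_threshold] <- "discordant"
  flag[n_fin == 1L] <- "single"
  flag[n_fin == 0L] <- "undetermined"
  parts <- strsplit(uk, "\r", fixed = TRUE)
  out <- data.frame(sample_id = vapply(parts, `[`, "", 1),
                    assay_id = vapply(parts, `[`, "", 2),
                    ct = mean_ct, n_finite = as.integer(n_fin),
                    flag = flag, stringsAsFactors = FALSE)
  out[order(out$sample_id, out$assay_id), , drop = FALSE]
}

#' Spike-in normalization: copies per reaction to copies per mL serum
#'
#' Applies the volumetric model (200 uL serum, 25 uL eluate, 2 uL per RT:
#' factor 62.5 per mL) and divides by the per-sample RNA isolation recovery
#' estimated from the spike-in controls.
#'
#' @param copies_per_reaction Numeric matrix, samples x miRNAs.
#' @param recovery Per-sample recovery fractions (> 0), one per row; usually
#'   from [estimate_spike_recovery()].
#' @param volume_factor Volumetric conversion constant (default 62.5 per mL).
#' @return Matrix of copies per mL serum.
#' @export
spike_in_normalize <- function(copies_per_reaction, recovery,
                               volume_factor = VOLUME_FACTOR) {
  copies_per_reaction <- as.matrix(copies_per_reaction)
  if (length(recovery) != nrow(copies_per_reaction))
    stop("one recovery value per sample (row) is required")
  if (any(!is.finite(recovery)) || any(recovery <= 0))
    stop("recovery values must be strictly positive")
  copies_per_reaction * volume_factor / recovery
}

#' Per-sample isolation recovery from spike-in controls
#'
#' Geometric mean over the three spike-in assays of measured/nominal copies.
#'
#' @param spike_copies Matrix samples x spike assays (copies per reaction).
#' @param nominal Named nominal inputs (copies per reaction); names must
#'   match `colnames(spike_copies)`.
#' @return Named numeric vector of per-sample recovery fractions.
#' @export
estimate_spike_recovery <- function(spike_copies,
                                    nominal = spike_nominal_copies()) {
  spike_copies <- as.matrix(spike_copies)
  miss <- setdiff(colnames(spike_copies), names(nominal))
  if (length(miss)) stop("no nominal input for spike assay(s): ",
                         paste(miss, collapse = ", "))
  ratio <- sweep(spike_copies, 2, nominal[colnames(spike_copies)], `/`)
  if (any(!is.finite(ratio)) || any(ratio <= 0))
    stop("spike-in measurements must be strictly positive")
  exp(rowMeans(log(ratio)))
}

#' Absolute quantification of a plate-level Ct table
#'
#' Collapses technical duplicates, interpolates each assay's Ct values
#' through its own fitted standard curve (per-assay efficiency correction),
#' estimates per-sample isolation recovery from the spike-in wells, and
#' converts to copies per mL serum.
#'
#' @param ct_table Long Ct table (`sample_id`, `assay_id`, `replicate`, `ct`).
#' @param curves Named list of `standard_curve` objects covering every assay.
#' @param spike_nominal Named nominal spike-in inputs (copies/reaction);
#'   assays with these names are used for recovery and excluded from the
#'   output expression matrix.
#' @param floor_ct Detection floor in Ct units.
#' @param discordance_threshold Duplicate discordance threshold (Ct).
#' @return Object of class `mirna_expression`: `values` (matrix samples x
#'   miRNAs, copies/mL), `flags` (same shape; `ok`, `floored`, `discordant`,
#'   `single`), `recovery` (per sample), `collapsed` (the collapsed Ct
#'   table).
#' @export
quantify <- function(ct_table, curves,
                     spike_nominal = spike_nominal_copies(),
                     floor_ct = 40, discordance_threshold = 1.0) {
  collapsed <- collapse_duplicates(ct_table, discordance_threshold)
  assays <- sort(unique(collapsed$assay_id))
  missing_curves <- setdiff(assays, names(curves))
  if (length(missing_curves))
    stop("no standard curve for assay(s): ",
         paste(utils::head(missing_curves, 5), collapse = ", "))
  samples <- sort(unique(collapsed$sample_id))
  ri <- match(collapsed$sample_id, samples)
  ci <- match(collapsed$assay_id, assays)
  ctm <- matrix(NA_real_, length(samples), length(assays),
                dimnames = list(samples, assays))
  flagm <- matrix("ok", length(samples), length(assays),
                  dimnames = list(samples, assays))
  ctm[cbind(ri, ci)] <- collapsed$ct
  flagm[cbind(ri, ci)] <- ifelse(collapsed$flag %in% c("discordant", "single"),
                                 collapsed$flag, "ok")
  rxn <- ctm
  for (a in assays)
    rxn[, a] <- ct_to_copies(ctm[, a], curves[[a]], floor_ct = floor_ct)
  flagm[is.na(ctm)] <- "floored"

  spikes <- intersect(assays, names(spike_nominal))
  if (length(spikes) < 1L)
    stop("no spike-in assays found in the Ct table")
  recovery <- estimate_spike_recovery(rxn[, spikes, drop = FALSE],
                                      spike_nominal)
  mir <- setdiff(assays, spikes)
  values <- spike_in_normalize(rxn[, mir, drop = FALSE], recovery)
  structure(list(values = values,
                 flags = flagm[, mir, drop = FALSE],
                 recovery = recovery,
                 collapsed = collapsed),
            class = "mirna_expression")
}

#' @export
print.mirna_expression <- function(x, ...) {
  cat(sprintf("miRNA expression: %d samples x %d miRNAs (copies/mL serum)\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  floored cells: %.1f%%; discordant duplicates: %.1f%%\n",
              100 * mean(x$flags == "floored"),
              100 * mean(x$flags == "discordant")))
  invisible(x)
}

#' @export
as.matrix.mirna_expression <- function(x, ...) x$values
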