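# Volumetric model linking copies/mL serum to copies per RT reaction:
# 200 uL serum -> 25 uL eluate, 2 uL eluate per RT reaction, so
# copies/mL = copies/reaction * (25/2) / 0.2 = copies/reaction * 62.5
# (divided by the per-sample isolation recovery). Standards are processed
# concurrently with samples, so pre-amplification cancels and the same fitted
# curve applies to both.
VOLUME_FACTOR <- 62.5

# Per-assay ground truth: amplification efficiency, standard-curve slope and
# intercept, expression status, and baseline abundance. Drawn from child
# seeds of the master seed so the standards plate and the cohort share the
# same true curves.
assay_truth <- function(cfg) {
  panel <- assay_panel(cfg)
  assays <- c(panel$mirnas, panel$spikes)
  n <- length(assays)

  set.seed(child_seed(cfg$seed, "curves"))
  eff <- runif(n, cfg$efficiency_range[1], cfg$efficiency_range[2])
  slope <- -1 / log10(1 + eff)
  intercept <- runif(n, cfg$intercept_range[1], cfg$intercept_range[2])

  set.seed(child_seed(cfg$seed, "baselines"))
  baseline <- rep(NA_real_, n)
  names(baseline) <- assays
  is_spike <- assays %in% panel$spikes
  expressed <- assays %in% panel$expressed
  # expressed fillers: drawn from the configured abundance interval;
  # non-expressed: below the 500 copies/mL filter for at least some samples
  lo <- log2(16); hi <- log2(450)
  draw_expr <- runif(n, cfg$baseline_log2_mean_range[1],
                     cfg$baseline_log2_mean_range[2])
  draw_low <- runif(n, lo, hi)
  baseline[expressed] <- draw_expr[expressed]
  baseline[!expressed & !is_spike] <- draw_low[!expressed & !is_spike]
  fixed <- intersect(assays, names(.special_baselines))
  baseline[fixed] <- .special_baselines[fixed]

  data.frame(assay_id = assays,
             efficiency = eff,
             slope = slope,
             intercept = intercept,
             expressed = expressed,
             is_spike = is_spike,
             baseline_log2 = unname(baseline),
             stringsAsFactors = FALSE)
}

#' Generate a standard-curve dilution plate
#'
#' Simulates the calibration run: for every assay (including the spike-in
#' controls), synthetic templates at a 6-log serial dilution of 1e7 down to
#' 1e2 copies per reaction are measured in technical duplicate. Each well's
#' Ct is drawn from the assay's true line `Ct = b + m * log10(copies)` with
#' `m = -1/log10(1 + E)`, plus Gaussian technical noise.
#'
#' @param config A [cohort_config()].
#' @param dilutions Copies-per-reaction grid (default `10^(7:2)`); must be
#'   strictly positive.
#' @param n_replicates Technical replicates per well (default 2).
#' @return A list of class `standard_plate` with elements `ct` (long-format
#'   data frame: `sample_id`, `assay_id`, `replicate`, `copies`, `ct`) and
#'   `truth` (per-assay true curve parameters, for test oracles).
#' @export
generate_standard_curve_plate <- function(config, dilutions = 10^(7:2),
                                          n_replicates = 2L) {
  stopifnot(inherits(config, "cohort_config"))
  if (any(dilutions <= 0)) stop("dilution grid must be strictly positive")
  truth <- assay_truth(config)
  set.seed(child_seed(config$seed, "standards"))
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      copies = dilutions,
                      assay_id = truth$assay_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  i <- match(grid$assay_id, truth$assay_id)
  ct <- truth$intercept[i] + truth$slope[i] * log10(grid$copies) +
    rnorm(nrow(grid), 0, config$ct_noise_sd)
  out <- data.frame(sample_id = sprintf("STD-1e%02d", round(log10(grid$copies))),
                    assay_id = grid$assay_id,
                    replicate = grid$replicate,
                    copies = grid$copies,
                    ct = ct,
                    stringsAsFactors = FALSE)
  structure(list(ct = out, truth = truth), class = "standard_plate")
}

# internal: counts of clean + hemolysed samples per group
cohort_groups <- function(cfg) {
  g <- data.frame(
    cohort = c("discovery", "discovery", "validation", "validation", "normal"),
    diagnosis = c("benign", "malignant", "benign", "malignant", "normal"),
    n_clean = c(cfg$n_benign_discovery, cfg$n_malignant_discovery,
                cfg$n_benign_validation, cfg$n_malignant_validation,
                cfg$n_normal),
    stringsAsFactors = FALSE)
  # hemolysis affects the abnormal-mammogram samples; extra hemolysed samples
  # are generated on top of the clean counts so that post-QC sizes match the
  # configuration
  f <- cfg$hemolysis_fraction
  g$n_hemo <- ifelse(g$cohort == "normal", 0L,
                     as.integer(round(g$n_clean / (1 - f)) - g$n_clean))
  g
}

#' Generate a synthetic serum miRNA cohort at plate level
#'
#' Draws, per sample, true log2 copies/mL for every miRNA assay
#' (`baseline + diagnosis effect (+ latent factor) + N(0, biological_sd)`),
#' applies the hemolysis shift to red-blood-cell miRNAs of hemolysed samples,
#' multiplies by a per-sample RNA isolation recovery (log-normal), converts
#' copies/mL to copies per RT reaction through the volumetric model, and
#' emits duplicate Ct wells through each assay's true standard curve with
#' Gaussian Ct noise. Spike-in control wells reflect the per-sample recovery.
#' Wells whose expected template is below one copy per reaction, or whose Ct
#' exceeds the detection ceiling, are reported as undetermined (`NA`).
#'
#' @param config A [cohort_config()].
#' @param n_replicates Technical replicates per well (default 2).
#' @return A list of class `sim_cohort`:
#' \describe{
#'   \item{ct}{long Ct table (`sample_id`, `assay_id`, `replicate`, `ct`).}
#'   \item{annotations}{per-sample annotations (cohort, diagnosis,
#'     `hemolysed_truth`, age, race, stage, size/grade/node class).}
#'   \item{truth}{generation record: latent log2 copies/mL matrix (after
#'     hemolysis shift), per-sample recovery and latent factor, malignant
#'     severity, per-assay curve truth, expressed set, and the config.}
#' }
#' @export
generate_cohort <- function(config, n_replicates = 2L) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  truth <- assay_truth(cfg)
  panel <- assay_panel(cfg)
  mirnas <- panel$mirnas
  groups <- cohort_groups(cfg)

  set.seed(child_seed(cfg$seed, "cohort"))

  n_total <- sum(groups$n_clean + groups$n_hemo)
  ann <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    n <- groups$n_clean[i] + groups$n_hemo[i]
    data.frame(cohort = rep(groups$cohort[i], n),
               diagnosis = rep(groups$diagnosis[i], n),
               hemolysed_truth = rep(FALSE, n),
               stringsAsFactors = FALSE)
  }))
  ann$sample_id <- sprintf("S%04d", seq_len(nrow(ann)))
  ann <- ann[, c("sample_id", "cohort", "diagnosis", "hemolysed_truth")]

  # mark the extra samples of each group as hemolysed (random positions)
  for (i in seq_len(nrow(groups))) {
    if (groups$n_hemo[i] == 0L) next
    idx <- which(ann$cohort == groups$cohort[i] &
                   ann$diagnosis == groups$diagnosis[i])
    ann$hemolysed_truth[sample(idx, groups$n_hemo[i])] <- TRUE
  }

  n <- nrow(ann)
  mal <- ann$diagnosis == "malignant"

  # demographics (Chinese-majority population; cancer patients slightly older)
  ann$age <- round(ifelse(mal, rnorm(n, 55, 8), rnorm(n, 50, 8)))
  ann$age <- pmin(pmax(ann$age, 25), 82)
  ann$race <- ifelse(runif(n) < ifelse(mal, 0.88, 0.80),
                     "Chinese", "non-Chinese")

  # latent tumour burden for malignant samples; drives the (optional) effect
  # scaling and the correlated ordinal clinicopathology classes
  u <- rep(NA_real_, n)
  u[mal] <- runif(sum(mal))
  jitter3 <- function(u, p_cum, labels, miss_rate) {
    v <- pmin(pmax(u + rnorm(length(u), 0, 0.12), 0), 1)
    lab <- labels[findInterval(v, p_cum, left.open = TRUE) + 1L]
    lab[runif(length(u)) < miss_rate] <- NA
    lab
  }
  ann$stage <- ann$size_class <- ann$grade <- ann$node_class <- NA_character_
  ann$stage[mal] <- jitter3(u[mal], c(0.36, 0.72, 0.97),
                            c("0", "1", "2", "3"), 0.0)
  ann$size_class[mal] <- jitter3(u[mal], c(0.27, 0.68),
                                 c("<=10mm", "11-20mm", ">20mm"), 0.04)
  ann$grade[mal] <- jitter3(u[mal], c(0.24, 0.66), c("1", "2", "3"), 0.05)
  ann$node_class[mal] <- jitter3(u[mal], c(0.25, 0.75),
                                 c("0", "1-3", ">3"), 0.06)

  # per-sample isolation recovery and shared latent factor
  recovery <- 2 ^ rnorm(n, 0, cfg$isolation_efficiency_sd)
  names(recovery) <- ann$sample_id
  fac <- rnorm(n, 0, cfg$latent_factor_sd)

  # latent log2 copies/mL (samples x miRNA assays)
  m <- length(mirnas)
  baseline <- truth$baseline_log2[match(mirnas, truth$assay_id)]
  eff_vec <- stats::setNames(numeric(m), mirnas)
  eff_vec[names(cfg$informative_mirnas)] <- cfg$informative_mirnas
  mult <- rep(1, n)
  if (cfg$severity_scaling != 0)
    mult[mal] <- 1 + cfg$severity_scaling * (u[mal] - 0.5)
  latent <- matrix(rep(baseline, each = n), nrow = n,
                   dimnames = list(ann$sample_id, mirnas))
  latent <- latent + (mal * mult) %o% eff_vec
  if (cfg$latent_factor_sd > 0 && length(cfg$factor_mirnas)) {
    loading <- as.numeric(mirnas %in% cfg$factor_mirnas)
    latent <- latent + fac %o% loading
  }
  latent <- latent + matrix(rnorm(n * m, 0, cfg$biological_sd), n, m)
  hemo_cols <- which(mirnas %in% cfg$rbc_mirnas)
  if (any(ann$hemolysed_truth) && length(hemo_cols))
    latent[ann$hemolysed_truth, hemo_cols] <-
      latent[ann$hemolysed_truth, hemo_cols] + cfg$hemolysis_shift

  # copies per reaction: samples x (miRNAs + spikes)
  rxn_mir <- (2 ^ latent) * recovery / VOLUME_FACTOR
  rxn_spk <- recovery %o% spike_nominal_copies()
  rxn <- cbind(rxn_mir, rxn_spk)
  assays <- colnames(rxn)
  ti <- match(assays, truth$assay_id)
  b <- truth$intercept[ti]; sl <- truth$slope[ti]

  # Ct wells (n_replicates per sample x assay), undetermined sentinel as NA
  true_ct <- sweep(sweep(log10(rxn), 2, sl, `*`), 2, b, `+`)
  below_floor <- rxn < 1
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    ct <- true_ct + matrix(rnorm(n * length(assays), 0, cfg$ct_noise_sd),
                           n, length(assays))
    ct[below_floor | ct > cfg$ct_ceiling] <- NA_real_
    rows[[r]] <- data.frame(
      sample_id = rep(ann$sample_id, times = length(assays)),
      assay_id = rep(assays, each = n),
      replicate = r,
      ct = as.vector(ct),
      stringsAsFactors = FALSE)
  }
  ct_table <- do.call(rbind, rows)
  ct_table <- ct_table[order(ct_table$sample_id, ct_table$assay_id,
                             ct_table$replicate), ]
  rownames(ct_table) <- NULL

  structure(list(
    ct = ct_table,
    annotations = ann,
    truth = list(latent_log2 = latent,
                 recovery = recovery,
                 factor = stats::setNames(fac, ann$sample_id),
                 severity = stats::setNames(u, ann$sample_id),
                 assays = truth,
                 expressed = panel$expressed,
                 config = cfg)),
    class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  ann <- x$annotations
  cat(sprintf("Synthetic cohort: %d samples (%d hemolysed), %d assays, %d wells\n",
              nrow(ann), sum(ann$hemolysed_truth),
              length(unique(x$ct$assay_id)), nrow(x$ct)))
  print(table(ann$cohort, ann$diagnosis))
  invisible(x)
}
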