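#' Default informative miRNAs and their log2 effect sizes
#'
#' Six serum miRNAs with small log2 fold changes (malignant minus benign, on
#' the normalized log2 scale) of the magnitude typical for circulating
#' biomarkers of solid tumours (|log2FC| roughly 0.1--0.4). Positive values
#' are up-regulated in malignant samples.
#'
#' @return Named numeric vector: names are miRNA assay identifiers, values are
#'   log2 effect sizes.
#' @export
default_informative_mirnas <- function() {
  c("hsa-miR-451a"   =  0.39,
    "hsa-miR-195-5p" =  0.41,
    "hsa-miR-126-5p" =  0.17,
    "hsa-miR-423-3p" = -0.09,
    "hsa-miR-192-5p" = -0.07,
    "hsa-miR-17-5p"  =  0.10)
}

# Fixed baseline abundances (log2 copies/mL serum) for the named assays that
# carry special roles. miR-451a is highly abundant in serum (red-blood-cell
# derived); miR-23a-3p is the stable reference of the hemolysis indicator
# pair. Baselines keep every special assay well above the 500 copies/mL
# expression filter.
.special_baselines <- c(
  "hsa-miR-451a"   = 18.0,
  "hsa-miR-23a-3p" = 14.0,
  "hsa-miR-195-5p" = 13.5,
  "hsa-miR-126-5p" = 14.5,
  "hsa-miR-423-3p" = 14.0,
  "hsa-miR-192-5p" = 13.0,
  "hsa-miR-17-5p"  = 13.5)

#' Nominal spike-in control inputs (copies per RT reaction)
#'
#' Three synthetic spike-in controls at high, medium and low RNA levels are
#' added to the lysis buffer before RNA isolation; their measured-to-nominal
#' ratio tracks per-sample isolation efficiency.
#'
#' @return Named numeric vector of nominal copies per reaction.
#' @export
spike_nominal_copies <- function() {
  c("spike-in-high" = 1e5, "spike-in-med" = 1e4, "spike-in-low" = 1e3)
}

#' Configuration of a synthetic serum miRNA cohort
#'
#' Describes the data-generating process of a two-cohort (Discovery and
#' Validation) case/control study with additional normal-mammogram controls:
#' per-miRNA baseline abundance, diagnosis effects, biological and technical
#' noise, per-sample RNA isolation efficiency tracked by spike-in controls,
#' hemolysis contamination, and per-assay qPCR amplification efficiency.
#'
#' @param n_benign_discovery,n_malignant_discovery Clean (non-hemolysed)
#'   benign / malignant sample counts in the Discovery cohort.
#' @param n_benign_validation,n_malignant_validation Same for Validation.
#' @param n_normal Normal-mammogram controls (evaluation only, never trained
#'   on).
#' @param n_mirnas Number of miRNA assays profiled.
#' @param n_expressed Number of miRNAs whose baseline abundance places them
#'   above the 500 copies/mL expression filter in essentially all samples.
#' @param informative_mirnas Named numeric vector of log2 effect sizes
#'   (malignant minus benign); names must be expressed assays.
#' @param baseline_log2_mean_range Interval (log2 copies/mL) from which the
#'   baseline abundance of expressed filler miRNAs is drawn.
#' @param biological_sd Between-subject SD of log2 abundance.
#' @param ct_noise_sd Technical SD of a single Ct measurement (Ct units).
#' @param isolation_efficiency_sd Log2-scale SD of the per-sample RNA
#'   isolation recovery multiplier.
#' @param hemolysis_fraction Fraction of abnormal-mammogram samples affected
#'   by hemolysis; hemolysed samples are generated in addition to the clean
#'   counts above so that QC exclusion recovers the configured cohort sizes.
#' @param hemolysis_shift Log2 increase of red-blood-cell miRNAs in hemolysed
#'   samples.
#' @param rbc_mirnas Red-blood-cell miRNA assays (must include
#'   \code{"hsa-miR-451a"}).
#' @param efficiency_range Interval of per-assay qPCR amplification
#'   efficiency E (fraction; 1 = perfect doubling). Must lie in (0, 1.2].
#' @param intercept_range Interval of the per-assay standard-curve intercept
#'   (Ct at a single template copy).
#' @param latent_factor_sd SD of an optional shared per-sample latent factor
#'   loaded (with unit loading) on `factor_mirnas`; induces correlation among
#'   those assays. Default 0 (independent miRNAs).
#' @param factor_mirnas Assays carrying the latent factor.
#' @param severity_scaling Scaling of diagnosis effects with a latent tumour
#'   burden in malignant samples: effect multiplier is
#'   `1 + severity_scaling * (u - 0.5)` with `u ~ U(0,1)`. Default 0 so that
#'   the configured effect is the exact group-mean difference.
#' @param ct_ceiling Detection ceiling; wells whose Ct would exceed it (or
#'   whose expected template is below one copy per reaction) are reported as
#'   undetermined.
#' @param seed Master seed; all stage seeds are derived from it
#'   deterministically.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_benign_discovery = 197L,
                          n_malignant_discovery = 72L,
                          n_benign_validation = 196L,
                          n_malignant_validation = 73L,
                          n_normal = 100L,
                          n_mirnas = 324L,
                          n_expressed = 179L,
                          informative_mirnas = default_informative_mirnas(),
                          baseline_log2_mean_range = c(13, 19),
                          biological_sd = 1.0,
                          ct_noise_sd = 0.15,
                          isolation_efficiency_sd = 0.5,
                          hemolysis_fraction = 0.10,
                          hemolysis_shift = 6,
                          rbc_mirnas = "hsa-miR-451a",
                          efficiency_range = c(0.90, 1.05),
                          intercept_range = c(38, 42),
                          latent_factor_sd = 0,
                          factor_mirnas = character(),
                          severity_scaling = 0,
                          ct_ceiling = 40,
                          seed = 1L) {
  cfg <- list(
    n_benign_discovery = as.integer(n_benign_discovery),
    n_malignant_discovery = as.integer(n_malignant_discovery),
    n_benign_validation = as.integer(n_benign_validation),
    n_malignant_validation = as.integer(n_malignant_validation),
    n_normal = as.integer(n_normal),
    n_mirnas = as.integer(n_mirnas),
    n_expressed = as.integer(n_expressed),
    informative_mirnas = informative_mirnas,
    baseline_log2_mean_range = as.numeric(baseline_log2_mean_range),
    biological_sd = as.numeric(biological_sd),
    ct_noise_sd = as.numeric(ct_noise_sd),
    isolation_efficiency_sd = as.numeric(isolation_efficiency_sd),
    hemolysis_fraction = as.numeric(hemolysis_fraction),
    hemolysis_shift = as.numeric(hemolysis_shift),
    rbc_mirnas = as.character(rbc_mirnas),
    efficiency_range = as.numeric(efficiency_range),
    intercept_range = as.numeric(intercept_range),
    latent_factor_sd = as.numeric(latent_factor_sd),
    factor_mirnas = as.character(factor_mirnas),
    severity_scaling = as.numeric(severity_scaling),
    ct_ceiling = as.numeric(ct_ceiling),
    seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  counts <- c(cfg$n_benign_discovery, cfg$n_malignant_discovery,
              cfg$n_benign_validation, cfg$n_malignant_validation,
              cfg$n_normal, cfg$n_mirnas, cfg$n_expressed)
  if (any(!is.finite(counts)) || any(counts <= 0L))
    stop("all cohort/assay counts must be positive")
  if (cfg$n_expressed > cfg$n_mirnas)
    stop("n_expressed must not exceed n_mirnas")
  if (cfg$hemolysis_fraction < 0 || cfg$hemolysis_fraction >= 1)
    stop("hemolysis_fraction must lie in [0, 1)")
  if (length(cfg$efficiency_range) != 2L ||
      cfg$efficiency_range[1] <= 0 || cfg$efficiency_range[2] > 1.2 ||
      diff(cfg$efficiency_range) < 0)
    stop("efficiency_range must be an increasing interval within (0, 1.2]")
  if (!"hsa-miR-451a" %in% cfg$rbc_mirnas)
    stop("rbc_mirnas must include hsa-miR-451a")
  if (is.null(names(cfg$informative_mirnas)) &&
      length(cfg$informative_mirnas) > 0)
    stop("informative_mirnas must be a named numeric vector")
  panel <- assay_panel(cfg)  # also checks expressed-set membership
  invisible(cfg)
}

# Assay identity layout shared by the standards plate and cohort generators.
# Named "special" assays come first (and are therefore all expressed); the
# remainder are synthetic filler assays.
assay_panel <- function(cfg) {
  specials <- unique(c(names(cfg$informative_mirnas), cfg$rbc_mirnas,
                       "hsa-miR-23a-3p"))
  if (length(specials) > cfg$n_expressed)
    stop("n_expressed too small to hold all named informative/indicator ",
         "assays (need >= ", length(specials), ")")
  n_filler <- cfg$n_mirnas - length(specials)
  if (n_filler < 0) stop("n_mirnas too small for the named assay set")
  pool <- setdiff(sprintf("miR-sim-%04d", seq_len(cfg$n_mirnas + length(specials))),
                  specials)
  fillers <- if (n_filler > 0) pool[seq_len(n_filler)] else character()
  mirnas <- c(specials, fillers)
  expressed <- mirnas[seq_len(cfg$n_expressed)]
  bad <- setdiff(names(cfg$informative_mirnas), expressed)
  if (length(bad))
    stop("informative miRNA(s) not in the expressed set: ",
         paste(bad, collapse = ", "))
  badf <- setdiff(cfg$factor_mirnas, mirnas)
  if (length(badf))
    stop("factor_mirnas not among the assay panel: ",
         paste(badf, collapse = ", "))
  list(mirnas = mirnas, expressed = expressed,
       spikes = names(spike_nominal_copies()))
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic serum miRNA cohort configuration\n")
  cat(sprintf("  Discovery: %d benign / %d malignant; Validation: %d / %d; normals: %d\n",
              x$n_benign_discovery, x$n_malignant_discovery,
              x$n_benign_validation, x$n_malignant_validation, x$n_normal))
  cat(sprintf("  Assays: %d (%d expressed), %d informative, hemolysis %.0f%%\n",
              x$n_mirnas, x$n_expressed, length(x$informative_mirnas),
              100 * x$hemolysis_fraction))
  cat(sprintf("  Noise: biological sd %.2f log2, Ct sd %.2f, isolation sd %.2f log2\n",
              x$biological_sd, x$ct_noise_sd, x$isolation_efficiency_sd))
  cat(sprintf("  Seed: %d\n", x$seed))
  invisible(x)
}

#' Write / read a cohort configuration as a flat key=value text file
#'
#' Vector fields are comma-separated; informative miRNAs are stored as
#' `id:effect` pairs.
#'
#' @param cfg A [cohort_config()].
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()` returns
#'   a `cohort_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "cohort_config"))
  fmt <- function(v) {
    if (!is.null(names(v)) && is.numeric(v) && length(v))
      paste(sprintf("%s:%.10g", names(v), unname(v)), collapse = ",")
    else paste(format(v, digits = 15, scientific = FALSE, trim = TRUE),
               collapse = ",")
  }
  lines <- vapply(names(cfg), function(k) paste0(k, "=", fmt(cfg[[k]])),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  args <- list()
  for (p in kv) {
    key <- trimws(p[1]); val <- trimws(p[2])
    parts <- strsplit(val, ",", fixed = TRUE)[[1]]
    if (key == "informative_mirnas") {
      if (!length(parts) || !nzchar(val)) { args[[key]] <- numeric(); next }
      sp <- strsplit(parts, ":", fixed = TRUE)
      args[[key]] <- stats::setNames(as.numeric(vapply(sp, `[`, "", 2)),
                                     vapply(sp, `[`, "", 1))
    } else if (key %in% c("rbc_mirnas", "factor_mirnas")) {
      args[[key]] <- if (nzchar(val)) parts else character()
    } else {
      args[[key]] <- as.numeric(parts)
    }
  }
  do.call(cohort_config, args)
}
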