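test_that("configuration invariants are enforced", {
  expect_error(cohort_config(n_mirnas = 0), "positive")
  expect_error(cohort_config(n_mirnas = 10, n_expressed = 12), "n_expressed")
  expect_error(cohort_config(hemolysis_fraction = 1.2), "hemolysis_fraction")
  expect_error(cohort_config(efficiency_range = c(0.9, 1.5)),
               "efficiency_range")
  expect_error(cohort_config(rbc_mirnas = "hsa-miR-16-5p"), "miR-451a")
  # the expressed set must be able to hold every named informative assay
  expect_error(cohort_config(n_mirnas = 10, n_expressed = 3),
               "n_expressed too small")
  expect_error(cohort_config(factor_mirnas = "miR-not-there"),
               "factor_mirnas")
})

test_that("config round-trips through the flat text format", {
  cfg <- small_config(latent_factor_sd = 1.5,
                      factor_mirnas = c("miR-sim-0001", "miR-sim-0002"))
  path <- withr::local_tempfile(fileext = ".txt")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(cfg2, cfg)
})

test_that("standard-curve plate follows the configured calibration lines", {
  # perfect doubling: adjacent 10-fold dilutions differ by log2(10) Ct
  cfg <- small_config(efficiency_range = c(1, 1), ct_noise_sd = 0,
                      n_mirnas = 8, n_expressed = 8)
  plate <- generate_standard_curve_plate(cfg)
  one <- subset(plate$ct, assay_id == plate$ct$assay_id[1] & replicate == 1)
  one <- one[order(-one$copies), ]
  expect_equal(diff(one$ct), rep(log2(10), 5), tolerance = 1e-12)
  # 6-log serial dilution of 1e7 down to 1e2
  expect_setequal(unique(plate$ct$copies), 10^(7:2))

  # closed-form slope at 90% efficiency
  cfg2 <- small_config(efficiency_range = c(0.9, 0.9), ct_noise_sd = 0,
                       n_mirnas = 8, n_expressed = 8)
  plate2 <- generate_standard_curve_plate(cfg2)
  expect_equal(unique(plate2$truth$slope), -1 / log10(1.9), tolerance = 1e-12)
  expect_equal(-1 / log10(1.9), -3.58739760341, tolerance = 1e-9)

  expect_error(generate_standard_curve_plate(cfg, dilutions = c(100, 0)),
               "positive")
})

test_that("generation is deterministic given config + seed", {
  cfg <- small_config(seed = 33)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$ct, b$ct)
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$truth$latent_log2, b$truth$latent_log2)
  expect_identical(generate_standard_curve_plate(cfg)$ct,
                   generate_standard_curve_plate(cfg)$ct)
  cfg2 <- small_config(seed = 34)
  expect_false(identical(generate_cohort(cfg2)$ct, a$ct))
})

test_that("null effects give identical group distributions", {
  cfg <- small_config(informative_mirnas = no_effects(), biological_sd = 0,
                      ct_noise_sd = 0, hemolysis_fraction = 0)
  coh <- generate_cohort(cfg)
  lat <- coh$truth$latent_log2
  mal <- coh$annotations$diagnosis == "malignant"
  # with no noise and no effects every sample has the same latent profile
  expect_equal(colMeans(lat[mal, ]), colMeans(lat[!mal, ]), tolerance = 1e-12)
})

test_that("hemolysed sample counts mirror the configured fraction", {
  # abnormal-mammogram cohorts at study scale: 538 clean samples at a 10%
  # hemolysis rate give ~60 additional hemolysed samples (about the 59/597
  # seen in practice); few assays keep this fast
  cfg <- cohort_config(n_benign_discovery = 197, n_malignant_discovery = 72,
                       n_benign_validation = 196, n_malignant_validation = 73,
                       n_normal = 100, n_mirnas = 10, n_expressed = 8,
                       informative_mirnas = no_effects(), seed = 5)
  coh <- generate_cohort(cfg)
  ann <- coh$annotations
  expect_equal(sum(ann$hemolysed_truth), 60)
  expect_equal(sum(ann$cohort != "normal"), 598)
  frac <- mean(ann$hemolysed_truth[ann$cohort != "normal"])
  ci <- 0.10 + c(-1, 1) * 1.96 * sqrt(0.1 * 0.9 / 598)
  expect_gt(frac, ci[1]); expect_lt(frac, ci[2])
  # normals are never hemolysed and clean counts match the config
  expect_false(any(ann$hemolysed_truth[ann$cohort == "normal"]))
  clean <- ann[!ann$hemolysed_truth, ]
  expect_equal(sum(clean$cohort == "discovery" & clean$diagnosis == "benign"),
               197)
  expect_equal(sum(clean$cohort == "validation" &
                     clean$diagnosis == "malignant"), 73)
})

test_that("annotations satisfy their structural invariants", {
  coh <- generate_cohort(small_config(seed = 8))
  ann <- coh$annotations
  expect_false(any(duplicated(ann$sample_id)))
  notmal <- ann$diagnosis != "malignant"
  for (col in c("stage", "size_class", "grade", "node_class"))
    expect_true(all(is.na(ann[[col]][notmal])))
  mal <- ann$diagnosis == "malignant"
  expect_true(all(!is.na(ann$stage[mal])))
  expect_true(mean(!is.na(ann$size_class[mal])) > 0.8)
})

test_that("per-sample quantification offset recovers the isolation efficiency", {
  # without spike-in correction, the mean log2 deviation of quantified
  # copies/mL from the latent truth equals the sample's log2 recovery
  cfg <- small_config(ct_noise_sd = 0, hemolysis_fraction = 0, seed = 21)
  q <- quantified(cfg)
  coll <- collapse_duplicates(q$cohort$ct)
  mir <- setdiff(unique(coll$assay_id), names(spike_nominal_copies()))
  samples <- rownames(q$expr$values)
  raw <- sapply(mir, function(a) {
    d <- coll[coll$assay_id == a, ]
    ct_to_copies(d$ct[match(samples, d$sample_id)], q$curves[[a]]) * 62.5
  })
  lat <- q$cohort$truth$latent_log2[samples, mir]
  ok <- q$expr$flags[, mir] == "ok"
  offs <- vapply(seq_along(samples), function(i) {
    mean((log2(raw[i, ]) - lat[i, ])[ok[i, ]])
  }, numeric(1))
  expect_equal(offs, unname(log2(q$cohort$truth$recovery[samples])),
               tolerance = 1e-9)
})

test_that("configured effect sizes are recovered exactly in a noiseless world", {
  cfg <- small_config(biological_sd = 0, ct_noise_sd = 0,
                      hemolysis_fraction = 0, seed = 13)
  q <- quantified(cfg)
  ann <- q$cohort$annotations
  mal <- ann$diagnosis[match(rownames(q$expr$values), ann$sample_id)] ==
    "malignant"
  lx <- log2(q$expr$values)
  eff <- cfg$informative_mirnas
  measured <- colMeans(lx[mal, names(eff), drop = FALSE]) -
    colMeans(lx[!mal, names(eff), drop = FALSE])
  expect_equal(unname(measured), unname(eff), tolerance = 1e-6)
})
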