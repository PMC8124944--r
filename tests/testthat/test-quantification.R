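make_dilution <- function(slope, intercept, copies = 10^(7:2), noise = 0) {
  data.frame(copies = copies,
             ct = intercept + slope * log10(copies) +
               rnorm(length(copies), 0, noise))
}

test_that("standard-curve fitting recovers exact calibration lines", {
  d <- make_dilution(-log2(10), 40)
  cv <- fit_standard_curve(d, "perfect")
  expect_equal(cv$slope, -log2(10), tolerance = 1e-12)
  expect_equal(cv$intercept, 40, tolerance = 1e-12)
  expect_equal(cv$efficiency, 1.0, tolerance = 1e-12)
  expect_equal(cv$r2, 1.0, tolerance = 1e-12)

  cv2 <- fit_standard_curve(make_dilution(-3.45, 41))
  expect_equal(cv2$slope, -3.45, tolerance = 1e-9)
  expect_equal(cv2$intercept, 41, tolerance = 1e-9)
  expect_equal(cv2$efficiency, 10^(1 / 3.45) - 1, tolerance = 1e-12)
  expect_equal(cv2$efficiency, 0.9491940296, tolerance = 1e-9)
})

test_that("standard-curve fitting matches closed-form least squares", {
  set.seed(42)
  for (i in 1:20) {
    d <- make_dilution(runif(1, -3.8, -3.1), runif(1, 37, 42), noise = 0.3)
    cv <- fit_standard_curve(d)
    oracle <- brute_ols(log10(d$copies), d$ct)
    expect_equal(cv$slope, unname(oracle["slope"]), tolerance = 1e-10)
    expect_equal(cv$intercept, unname(oracle["intercept"]), tolerance = 1e-10)
  }
})

test_that("degenerate calibrations are rejected", {
  d <- make_dilution(-3.3, 40)[1:2, ]
  expect_error(fit_standard_curve(d), "3 distinct dilution levels")
  # undetermined wells do not count as levels
  d2 <- make_dilution(-3.3, 40)
  d2$ct[1:4] <- NA
  expect_error(fit_standard_curve(d2), "3 distinct dilution levels")
  up <- make_dilution(+3.3, 10)
  expect_error(fit_standard_curve(up), "slope")
})

test_that("Ct interpolation inverts the curve", {
  cv <- structure(list(assay_id = "a", slope = -log2(10), intercept = 40,
                       efficiency = 1, r2 = 1, n = 6),
                  class = "standard_curve")
  expect_equal(ct_to_copies(40, cv), 1, tolerance = 1e-12)
  # round trip over random curves and copy numbers
  set.seed(7)
  for (i in 1:20) {
    m <- runif(1, -3.8, -3.1)
    cvr <- structure(list(assay_id = "r", slope = m, intercept = runif(1, 37, 42),
                          efficiency = 10^(-1 / m) - 1, r2 = 1, n = 6),
                     class = "standard_curve")
    copies <- 10^runif(5, 0, 7)
    expect_equal(ct_to_copies(copies_to_ct(copies, cvr), cvr), copies,
                 tolerance = 1e-9)
  }
  # pinned closed-form value
  cv2 <- structure(list(assay_id = "p", slope = -3.3219, intercept = 40,
                        efficiency = 10^(1 / 3.3219) - 1, r2 = 1, n = 6),
                   class = "standard_curve")
  expect_equal(ct_to_copies(30, cv2), 1024.06003146, tolerance = 1e-8)
  # undetermined Ct floors at the detection limit, never zero
  fl <- ct_to_copies(NA, cv2, floor_ct = 40)
  expect_equal(fl, 1, tolerance = 1e-12)
  expect_gt(fl, 0)
  # strictly decreasing in Ct
  cts <- seq(15, 39, by = 0.5)
  expect_true(all(diff(ct_to_copies(cts, cv2)) < 0))
})

test_that("duplicate collapsing follows the mean + discordance rule", {
  tab <- data.frame(
    sample_id = rep(c("s1", "s2", "s3", "s4"), each = 2),
    assay_id = "a",
    replicate = rep(1:2, 4),
    ct = c(30.0, 30.0,   30.0, 31.5,   30.0, NA,   NA, NA))
  out <- collapse_duplicates(tab)
  expect_equal(out$ct, c(30.0, 30.75, 30.0, NA))
  expect_equal(out$flag, c("concordant", "discordant", "single",
                           "undetermined"))
  expect_equal(out$n_finite, c(2L, 2L, 1L, 0L))
  bad <- rbind(tab, data.frame(sample_id = "s1", assay_id = "a",
                               replicate = 3, ct = 30))
  expect_error(collapse_duplicates(bad), "2 replicates")
})

test_that("spike-in normalization applies the volumetric model", {
  m <- matrix(100, 1, 1, dimnames = list("s1", "m1"))
  expect_equal(spike_in_normalize(m, 1.0)[1, 1], 6250)
  expect_equal(spike_in_normalize(m, 0.5)[1, 1],
               2 * spike_in_normalize(m, 1.0)[1, 1])
  expect_error(spike_in_normalize(m, 0), "positive")
  expect_error(spike_in_normalize(m, c(1, 1)), "one recovery")
  # equal spike recoveries r give per-sample recovery r
  sp <- matrix(0.7 * spike_nominal_copies(), 1, 3,
               dimnames = list("s1", names(spike_nominal_copies())))
  expect_equal(unname(estimate_spike_recovery(sp)), 0.7, tolerance = 1e-12)
})

test_that("noiseless plates are quantified back to the latent truth", {
  cfg <- small_config(ct_noise_sd = 0, hemolysis_fraction = 0, seed = 3)
  q <- quantified(cfg)
  truth <- 2^q$cohort$truth$latent_log2[rownames(q$expr$values),
                                        colnames(q$expr$values)]
  ok <- q$expr$flags == "ok"
  expect_gt(mean(ok), 0.6)
  expect_lt(max(abs(q$expr$values[ok] / truth[ok] - 1)), 1e-6)
  # floored cells are flagged and strictly positive
  expect_true(all(q$expr$values > 0))
})

test_that("quantify rejects plates with unknown assays", {
  cfg <- small_config(n_mirnas = 8, n_expressed = 8)
  std <- generate_standard_curve_plate(cfg)
  coh <- generate_cohort(cfg)
  curves <- fit_standard_curves(std$ct)
  curves[["hsa-miR-451a"]] <- NULL
  expect_error(quantify(coh$ct, curves), "no standard curve")
})
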