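# Spectral processing: referencing, baseline correction, QC, binning,
# normalization, transforms.

make_clean_spectrum <- function(seed = 1, noise_sd = 0, baseline = c(0),
                                water = 0, tsp_area = 1) {
  cfg <- generator_config(
    n_patients = 2, noise_sd = noise_sd, baseline_params = baseline,
    water_artifact = list(amplitude = water, center = 4.75, fwhm = 0.2),
    seed = seed)
  cfg$tsp$area <- tsp_area
  conc <- exp(default_metabolite_means()$control)
  list(spectrum = generate_spectrum(conc, cfg, seed = seed + 100), config = cfg)
}

test_that("referencing moves a shifted TSP apex to 0.0 ppm", {
  x <- make_clean_spectrum(noise_sd = 0.5)
  sp <- x$spectrum
  sp$ppm_start <- sp$ppm_start + 0.03   # simulate a mis-calibrated axis
  ref <- reference_to_tsp(sp)
  w <- nephroNMR:::spectrum_window(ref, -0.05, 0.05)
  expect_lte(abs(w$ppm[which.max(w$y)]), sp$ppm_step / 2 + 1e-12)
  # intensities untouched
  expect_identical(ref$intensities, sp$intensities)
})

test_that("referencing an already-referenced spectrum is the identity", {
  x <- make_clean_spectrum(noise_sd = 0.5)
  r1 <- reference_to_tsp(x$spectrum)
  r2 <- reference_to_tsp(r1)
  expect_lte(abs(r2$ppm_start - r1$ppm_start), r1$ppm_step / 2 + 1e-12)
})

test_that("a spectrum without TSP cannot be referenced", {
  x <- make_clean_spectrum(noise_sd = 0.5, tsp_area = 0)
  expect_error(reference_to_tsp(x$spectrum),
               class = "nephroNMR_referencing_failure")
})

test_that("baseline correction is near-identity on baseline-free spectra", {
  x <- make_clean_spectrum()
  corrected <- correct_baseline(x$spectrum)
  # peaks preserved: max deviation tiny relative to the largest peak
  expect_lt(max(abs(corrected$intensities - x$spectrum$intensities)),
            0.01 * max(x$spectrum$intensities))
})

test_that("a linear baseline is removed almost completely", {
  x <- make_clean_spectrum(baseline = c(5, 2))   # 5 + 2*ppm
  corrected <- correct_baseline(x$spectrum)
  for (reg in list(c(9.5, 9.9), c(3.5, 3.9), c(-0.4, -0.2))) {
    w <- nephroNMR:::spectrum_window(corrected, reg[1], reg[2])
    orig <- nephroNMR:::poly_baseline(w$ppm, c(5, 2))
    expect_lt(mean(abs(w$y)), 0.01 * mean(abs(orig)))
  }
})

test_that("a constant offset lowers the peak apex by that offset", {
  cfg <- quiet_config()
  cfg$tsp$area <- 0
  sp <- generate_spectrum(c(Lactate = 2), cfg)
  sp_off <- sp
  sp_off$intensities <- sp$intensities + 3
  corrected <- correct_baseline(sp_off)
  apex0 <- max(nephroNMR:::spectrum_window(sp_off, 1.29, 1.37)$y)
  apex1 <- max(nephroNMR:::spectrum_window(corrected, 1.29, 1.37)$y)
  expect_equal(apex0 - apex1, 3, tolerance = 0.02)
})

test_that("clean spectra pass QC; injected artifacts fail with itemized reasons", {
  x <- make_clean_spectrum(noise_sd = 1, water = 150)
  sp <- correct_baseline(reference_to_tsp(x$spectrum))
  rep <- qc_filter(sp)
  expect_true(rep$passed)
  expect_length(rep$reasons, 0)

  thr <- qc_thresholds()
  sloped <- sp
  sloped$intensities <- sloped$intensities +
    10 * thr$slope_max * (ppm_grid(sp) - 5)      # 10x the slope threshold
  rep2 <- qc_filter(sloped)
  expect_false(rep2$passed)
  expect_true(any(grepl("baseline_slope", rep2$reasons)))

  wide <- make_clean_spectrum(noise_sd = 1)
  wide$config$tsp$fwhm <- wide$config$tsp$fwhm * 5
  spw <- generate_spectrum(exp(default_metabolite_means()$control),
                           wide$config, seed = 7)
  rep3 <- qc_filter(correct_baseline(reference_to_tsp(spw)))
  expect_false(rep3$passed)
  expect_true("tsp_width" %in% rep3$reasons)
})

test_that("growing an injected artifact never flips a QC fail back to a pass", {
  x <- make_clean_spectrum(noise_sd = 1)
  base <- correct_baseline(reference_to_tsp(x$spectrum))
  thr <- qc_thresholds()
  failed_yet <- FALSE
  for (mult in c(0.1, 0.5, 2, 5, 20, 100)) {
    sp <- base
    sp$intensities <- sp$intensities + mult * thr$offset_max
    passed <- qc_filter(sp)$passed
    if (failed_yet) expect_false(passed)
    if (!passed) failed_yet <- TRUE
  }
  expect_true(failed_yet)
})

test_that("the shipped binning configuration yields exactly 377 bins", {
  bc <- bin_config()
  expect_equal(sum(bc$keep), 377)
  # the water region is fully excluded from retained bins
  expect_false(any(bc$lo < 5.0 - 1e-9 & bc$hi > 4.5 + 1e-9))
})

test_that("bins integrate intensity: constant spectrum gives h * width", {
  h <- 3.7
  sp <- nmr_spectrum(-0.5, 0.001, rep(h, 10501))
  b <- bin_spectrum(sp)
  expect_equal(unname(b), rep(h * 0.022, 377), tolerance = 1e-9)
})

test_that("a narrow peak lands entirely in one bin with its full area", {
  bc <- bin_config()
  center <- (bc$lo[100] + bc$hi[100]) / 2
  ppm <- seq(-0.5, 10, by = 5e-4)
  y <- pseudo_voigt(ppm, center, area = 2.5, fwhm = 0.002, eta = 0)
  sp <- nmr_spectrum(-0.5, 5e-4, y)
  b <- bin_spectrum(sp)
  expect_equal(unname(b[100]), 2.5, tolerance = 0.01)
  expect_lt(max(abs(b[-100])), 0.01 * 2.5)
})

test_that("binning outside the spectrum grid is an input error", {
  sp <- nmr_spectrum(0, 0.01, rep(1, 500))   # 0..5 ppm only
  expect_error(bin_spectrum(sp), "outside spectrum grid")
})

test_that("total-integral normalization conserves mass and ignores scale", {
  expect_equal(unname(normalize_total_integral(c(a = 2, b = 3, c = 5))),
               c(0.2, 0.3, 0.5))
  x <- make_clean_spectrum(noise_sd = 0.3)
  b1 <- bin_spectrum(x$spectrum)
  sp10 <- x$spectrum
  sp10$intensities <- sp10$intensities * 10
  b10 <- bin_spectrum(sp10)
  expect_equal(normalize_total_integral(b1), normalize_total_integral(b10),
               tolerance = 1e-9)
  expect_equal(sum(normalize_total_integral(b1)), 1, tolerance = 1e-9)
})

test_that("zero-integral samples are flagged invalid, not divided by zero", {
  m <- rbind(s1 = c(1, 3), s2 = c(0, 0))
  out <- normalize_total_integral(m)
  expect_equal(attr(out, "invalid_samples"), "s2")
  expect_true(all(is.na(out["s2", ])))
  expect_equal(sum(out["s1", ]), 1)
})

test_that("cubic-root transform uses the signed real root and autoscales", {
  m <- matrix(c(0.008, -0.001, 0.027, 0.001), nrow = 2)
  cube <- sign(m) * abs(m)^(1/3)
  expect_equal(cube[1, 1], 0.2)
  expect_equal(cube[2, 1], -0.1)
  tr <- transform_bins(m)
  expect_equal(unname(colMeans(tr)), c(0, 0), tolerance = 1e-6)
  expect_equal(unname(apply(tr, 2, sd)), c(1, 1), tolerance = 1e-6)
  # frozen training statistics applied to test data, not re-estimated
  test_m <- matrix(c(0.01, 0.02, 0.03, 0.04), nrow = 2)
  st <- attr(tr, "training_stats")
  tr_test <- transform_bins(test_m, st)
  manual <- sweep(sweep(sign(test_m) * abs(test_m)^(1/3), 2, st$center), 2,
                  st$scale, "/")
  expect_equal(unname(tr_test[1:2, 1:2]), unname(manual), tolerance = 1e-12)
})

test_that("zero-variance bins get unit scale and a flag", {
  m <- cbind(a = c(1, 1, 1), b = c(1, 2, 3)) / 10
  tr <- transform_bins(m)
  st <- attr(tr, "training_stats")
  expect_true(st$zero_variance[["a"]])
  expect_equal(st$scale[["a"]], 1)
  expect_true(all(is.finite(tr)))
})

test_that("spectrum CSV and JCAMP-DX files round-trip", {
  x <- make_clean_spectrum(noise_sd = 0.2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(x$spectrum, f1)
  back <- read_spectrum_csv(f1)
  expect_equal(back$intensities, x$spectrum$intensities, tolerance = 1e-6)
  expect_equal(back$ppm_start, x$spectrum$ppm_start, tolerance = 1e-9)
  f2 <- withr::local_tempfile(fileext = ".jdx")
  write_spectrum_jdx(x$spectrum, f2)
  back2 <- read_spectrum_jdx(f2)
  expect_equal(back2$intensities, x$spectrum$intensities, tolerance = 1e-6)
})
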