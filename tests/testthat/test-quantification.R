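# Pseudo-Voigt quantification: closed-form line-shape values, parameter
# recovery, goodness-of-fit gating, creatinine normalization.

test_that("pseudo-Voigt limits match the Gaussian and Lorentzian closed forms", {
  fwhm <- 0.004
  expect_equal(pseudo_voigt(0.5, 0.5, area = 2, fwhm = fwhm, eta = 0),
               2 * 2 * sqrt(log(2) / pi) / fwhm)
  expect_equal(pseudo_voigt(0.5, 0.5, area = 2, fwhm = fwhm, eta = 1),
               2 * 2 / (pi * fwhm))
  expect_error(pseudo_voigt(0, 0, area = -1, fwhm = 1, eta = 0.5))
})

test_that("the pseudo-Voigt integrates to its area for any mixing fraction", {
  for (eta in c(0, 0.25, 0.5, 0.8, 1)) {
    q <- integrate(pseudo_voigt, lower = -Inf, upper = Inf,
                   center = 0, area = 1.3, fwhm = 0.003, eta = eta,
                   rel.tol = 1e-10, subdivisions = 2000L)
    expect_equal(q$value, 1.3, tolerance = 1e-4)
  }
})

test_that("noiseless single peaks are recovered to high relative accuracy", {
  cfg <- quiet_config()
  cfg$tsp$area <- 0
  cfg$peak$eta <- 0.5
  tpl <- signal_templates()
  for (m in c("Creatinine", "Urea")) {       # singlets: pure pseudo-Voigt
    sp <- generate_spectrum(setNames(1.0, m), cfg)
    fit <- fit_signal(sp, tpl[tpl$metabolite == m, ])
    expect_true(fit$valid)
    expect_lt(abs(fit$area - 1.0), 1e-6)
    expect_lt(abs(fit$center - tpl$center[tpl$metabolite == m]), 1e-6)
    expect_lt(abs(fit$fwhm - cfg$peak$fwhm) / cfg$peak$fwhm, 1e-4)
    expect_lt(abs(fit$eta - 0.5), 1e-4)
  }
  # multiplet round-trip (alanine doublet)
  sp <- generate_spectrum(c(Alanine = 0.7), cfg)
  fit <- fit_signal(sp, tpl[tpl$metabolite == "Alanine", ])
  expect_true(fit$valid)
  expect_lt(abs(fit$area - 0.7) / 0.7, 1e-6)
})

test_that("area error shrinks with SNR and stays within 2% at SNR 100", {
  tpl <- signal_templates()
  errs <- vapply(c(20, 100, 500), function(snr) {
    cfg <- quiet_config()
    cfg$tsp$area <- 0
    # peak height of a unit-area eta=0.5 singlet at fwhm 0.003
    height <- 0.5 * (2 / (pi * 0.003)) + 0.5 * 2 * sqrt(log(2) / pi) / 0.003
    cfg$noise_sd <- height / snr
    err <- vapply(1:5, function(i) {
      sp <- generate_spectrum(c(Creatinine = 1.0), cfg, seed = 40 + i)
      abs(fit_signal(sp, tpl[tpl$metabolite == "Creatinine", ])$area - 1)
    }, numeric(1))
    mean(err)
  }, numeric(1))
  expect_lt(errs[2], 0.02)
  expect_lt(errs[3], errs[1])            # error decreases with SNR
})

test_that("a window containing only noise is gated invalid", {
  cfg <- generator_config(n_patients = 2, noise_sd = 1,
                          baseline_params = c(0),
                          water_artifact = list(amplitude = 0, center = 4.75,
                                                fwhm = 0.2), seed = 1)
  cfg$tsp$area <- 0
  sp <- generate_spectrum(c(Alanine = 0), cfg, seed = 11)
  tpl <- signal_templates()
  fit <- fit_signal(sp, tpl[tpl$metabolite == "Alanine", ])
  expect_false(fit$valid)
})

test_that("valid fits never exceed the goodness-of-fit threshold", {
  cfg <- generator_config(n_patients = 2, noise_sd = 0.5, seed = 3)
  tpl <- signal_templates()
  co <- generate_cohort(generator_config(n_patients = 6, seed = 8))
  for (k in 1:6) {
    sp <- generate_spectrum(co$concentrations[k, ], cfg, seed = 50 + k)
    q <- quantify_panel(sp, gof_threshold = 0.05)
    expect_true(all(q$gof[q$valid] <= 0.05))
  }
})

test_that("overlapping glucose/glucuronate signals are fitted jointly", {
  cfg <- quiet_config()
  cfg$tsp$area <- 0
  height <- 0.5 * (2 / (pi * 0.003)) + 0.5 * 2 * sqrt(log(2) / pi) / 0.003
  # weakest multiplet component (glucuronate, area 0.6 over 2 peaks) must
  # still see SNR >= 100
  cfg$noise_sd <- 0.3 * height / 100
  sp <- generate_spectrum(c(Glucose = 1.4, Glucuronate = 0.6), cfg, seed = 21)
  q <- quantify_panel(sp)
  g <- q[q$metabolite == "Glucose", ]
  u <- q[q$metabolite == "Glucuronate", ]
  expect_true(g$valid && u$valid)
  expect_lt(abs(g$area - 1.4) / 1.4, 0.01)
  expect_lt(abs(u$area - 0.6) / 0.6, 0.01)

  # glucose present, glucuronate absent: absent signal never fakes an area
  sp2 <- generate_spectrum(c(Glucose = 1.4, Glucuronate = 0), cfg, seed = 22)
  q2 <- quantify_panel(sp2)
  u2 <- q2[q2$metabolite == "Glucuronate", ]
  expect_true(!u2$valid || u2$area < 0.05)
  expect_lt(abs(q2$area[q2$metabolite == "Glucose"] - 1.4) / 1.4, 0.01)
})

test_that("the full panel is recovered within 2% at high SNR", {
  cfg <- generator_config(n_patients = 2, noise_sd = 0.3,
                          baseline_params = c(2, 0.5),
                          water_artifact = list(amplitude = 100, center = 4.75,
                                                fwhm = 0.2), seed = 5)
  co <- generate_cohort(generator_config(n_patients = 3, seed = 14))
  conc <- co$concentrations[1, ]
  sp <- correct_baseline(reference_to_tsp(generate_spectrum(conc, cfg, seed = 31)))
  q <- quantify_panel(sp)
  expect_true(all(q$valid))
  expect_lt(max(abs(q$area - conc[q$metabolite]) / conc[q$metabolite]), 0.02)
})

test_that("creatinine failure makes the sample unusable downstream", {
  cfg <- quiet_config()
  cfg$noise_sd <- 0.5
  conc <- exp(default_metabolite_means()$control)
  conc["Creatinine"] <- 0
  sp <- generate_spectrum(conc, cfg, seed = 12)
  q <- quantify_panel(sp)
  pf <- process_features(q)
  expect_true(sp$sample_id %in% pf$unusable)
  expect_true(all(is.na(pf$features[sp$sample_id, ])))
})

test_that("features are invariant to global spectrum dilution", {
  quants <- data.frame(sample_id = rep(c("a", "b"), each = 3),
                       metabolite = rep(c("Lactate", "Citrate", "Creatinine"), 2),
                       area = c(2, 4, 1, 6, 2, 2), valid = TRUE)
  scaled <- quants
  scaled$area <- scaled$area * 17.3
  f1 <- process_features(quants)
  f2 <- process_features(scaled)
  expect_equal(f1$features, f2$features, tolerance = 1e-12)
})

test_that("a valid quantification with non-positive area is a contract violation", {
  q <- data.frame(sample_id = "a", metabolite = c("Lactate", "Creatinine"),
                  area = c(-1, 2), valid = TRUE)
  expect_error(process_features(q), "internal error")
})

test_that("feature standardization reproduces generator log-scale correlations", {
  co <- generate_cohort(generator_config(n_patients = 200,
                                         rejection_prevalence = 0,
                                         patient_sd = 0, seed = 31))
  conc <- co$concentrations
  quants <- data.frame(
    sample_id = rep(rownames(conc), times = ncol(conc)),
    metabolite = rep(colnames(conc), each = nrow(conc)),
    area = as.vector(conc), valid = TRUE)
  pf <- process_features(quants)
  # independent log-normals with common creatinine denominator, all sds
  # equal: corr(log(x/cr), log(y/cr)) = sd^2 / (2 sd^2) = 0.5
  cm <- cor(pf$features[, c("Lactate", "Citrate", "Alanine")])
  off <- cm[upper.tri(cm)]
  expect_true(all(abs(off - 0.5) < 3 / sqrt(nrow(conc))))
})
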