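# Synthetic-data module: urine NMR spectra and transplant cohorts with the
# statistical structure the downstream analysis assumes.  Defaults emulate
# the study conditions (180 patients, ~10 samples each, biopsy-confirmed
# rejection episodes, class shifts with the signs of the final model:
# citrate/alanine down, lactate/urea up in rejection).

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Default class-conditional log-concentration means
#'
#' Control-class log-means for the eleven panel metabolites and the
#' case-class shifts (alanine and citrate down, lactate and urea up,
#' proportional to the published coefficients).  These are the package's
#' fixed simulation conditions, not estimates of any real population.
#'
#' @return List with named numeric vectors `control` and `case`.
#' @export
default_metabolite_means <- function() {
  control <- c(Alanine = 0.0, Citrate = 1.0, DMA = -0.7, Glucose = 0.5,
               Glucuronate = -0.3, Hippurate = 1.2, Lactate = 0.3,
               PAQ = 0.0, Trigonelline = -0.5, Urea = 2.0, Creatinine = 1.5)
  # class shifts in log units = (published coefficient sign/size) * sd 0.4
  shift <- c(Alanine = -0.10, Citrate = -0.33, Lactate = 0.38, Urea = 0.10)
  case <- control
  case[names(shift)] <- case[names(shift)] + shift
  list(control = control, case = case)
}

#' Configuration of the synthetic-data generator
#'
#' All knobs of the simulator in one validated object.  The defaults are
#' the package's fixed study conditions: 180 patients with 8--12 urine
#' samples each, per-patient rejection prevalence 0.15, biopsy probability
#' 0.9 given a rejection episode and 0.1 otherwise, log-normal metabolite
#' concentrations (log-sd 0.4) whose case/control mean shifts carry the
#' signs of the published model (alanine and citrate lower, lactate and
#' urea higher under rejection).
#'
#' @param n_patients Number of patients.
#' @param samples_per_patient Integer range `c(min, max)` of samples per patient.
#' @param rejection_prevalence Per-patient probability of a rejection
#'   episode, in \[0, 1\].
#' @param biopsy_policy List: `p_biopsy_rejection`, `p_biopsy_control`,
#'   `p_extra_negative` (probability a rejecting patient also has an
#'   unrelated negative biopsy).
#' @param metabolite_means List with named numeric vectors `control` and
#'   `case`: per-metabolite log-concentration means.
#' @param metabolite_sds Named per-metabolite log-scale sd (all > 0).
#' @param patient_sd Log-scale sd of the per-patient, per-metabolite
#'   random effect (0 disables it).
#' @param noise_sd Spectral noise sd, intensity units.
#' @param baseline_params Polynomial baseline coefficients, ascending
#'   powers of ppm.
#' @param water_artifact List: `amplitude` (peak height), `center` (ppm),
#'   `fwhm` (ppm) of the residual-water Lorentzian.
#' @param tsp List: `area`, `fwhm`, `eta` of the TSP reference singlet.
#' @param peak List: shared `fwhm` and `eta` of metabolite peaks.
#' @param grid List: `ppm_min`, `ppm_max`, `ppm_step` of the spectral grid.
#' @param seed Integer; fully determines all generator output.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_patients = 180,
                             samples_per_patient = c(8L, 12L),
                             rejection_prevalence = 0.15,
                             biopsy_policy = list(p_biopsy_rejection = 0.9,
                                                  p_biopsy_control = 0.1,
                                                  p_extra_negative = 0.2),
                             metabolite_means = default_metabolite_means(),
                             metabolite_sds = NULL,
                             patient_sd = 0.15,
                             noise_sd = 1.0,
                             baseline_params = c(0, 0, 0),
                             water_artifact = list(amplitude = 150, center = 4.75,
                                                   fwhm = 0.2),
                             tsp = list(area = 1.0, fwhm = 0.003, eta = 0.3),
                             peak = list(fwhm = 0.003, eta = 0.5),
                             grid = list(ppm_min = -0.5, ppm_max = 10.0,
                                         ppm_step = 5e-4),
                             seed = 1L) {
  mets <- names(metabolite_means$control)
  if (is.null(metabolite_sds))
    metabolite_sds <- setNames(rep(0.4, length(mets)), mets)
  cfg <- list(n_patients = as.integer(n_patients),
              samples_per_patient = as.integer(samples_per_patient),
              rejection_prevalence = rejection_prevalence,
              biopsy_policy = biopsy_policy,
              metabolite_means = metabolite_means,
              metabolite_sds = metabolite_sds,
              patient_sd = patient_sd,
              noise_sd = noise_sd,
              baseline_params = baseline_params,
              water_artifact = water_artifact,
              tsp = tsp, peak = peak, grid = grid,
              seed = as.integer(seed))
  if (cfg$n_patients < 1)
    stop("configuration error: n_patients must be >= 1")
  if (length(cfg$samples_per_patient) != 2L ||
      any(cfg$samples_per_patient < 1L) ||
      diff(cfg$samples_per_patient) < 0)
    stop("configuration error: samples_per_patient must be a valid range")
  if (!is.numeric(rejection_prevalence) || rejection_prevalence < 0 ||
      rejection_prevalence > 1)
    stop("configuration error: rejection_prevalence outside [0, 1]")
  if (any(cfg$metabolite_sds <= 0) || cfg$patient_sd < 0 || cfg$noise_sd < 0)
    stop("configuration error: sds must be positive")
  if (!setequal(names(cfg$metabolite_means$case), mets) ||
      !setequal(names(cfg$metabolite_sds), mets))
    stop("configuration error: metabolite name mismatch")
  class(cfg) <- "generator_config"
  cfg
}

#' Simulate a transplant cohort
#'
#' Draws patients with transplant dates, repeated urine-sampling dates,
#' biopsy events graded BANFF 1 (no rejection) or BANFF 4 (acute cellular
#' rejection), and per-sample true metabolite concentrations.  A rejecting
#' patient carries a rejection episode on a random day; samples within
#' +/- 7 days of that day draw their concentrations from the case
#' distribution, all other samples from the control distribution.  Two
#' sampling days in the week before the episode are always present so
#' biopsy-linked case samples exist.  Concentrations are log-normal with
#' class-dependent means, a per-patient random effect, and the configured
#' log-sd.
#'
#' @param config A [generator_config()].
#' @return A list of class `nmr_cohort`:
#'   \describe{
#'     \item{samples}{data.frame: `sample_id, patient_id, tx_date,
#'       sample_date, days_post_tx`}
#'     \item{biopsies}{data.frame: `patient_id, biopsy_date, banff`
#'       (comma-separated BANFF categories per biopsy)}
#'     \item{concentrations}{samples x metabolites matrix of true
#'       concentrations (not log)}
#'     \item{truth}{data.frame: `sample_id, rejection_patient,
#'       rejection_active` (the true per-sample label)}
#'   }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  mets <- names(config$metabolite_means$control)
  with_seed(config$seed, {
    origin <- as.Date("2008-01-01")
    samples <- list(); biopsies <- list(); truth <- list(); conc <- list()
    for (i in seq_len(config$n_patients)) {
      pid <- sprintf("P%03d", i)
      tx_date <- origin + sample.int(731, 1) - 1L
      rejection <- runif(1) < config$rejection_prevalence
      n_s <- sample(seq(config$samples_per_patient[1],
                        config$samples_per_patient[2]), 1)
      days <- sort(sample(5:365, n_s))
      rej_day <- NA_integer_
      if (rejection) {
        rej_day <- sample(40:300, 1)
        days <- sort(unique(c(days, rej_day, rej_day - 3L)))
        if (runif(1) < config$biopsy_policy$p_biopsy_rejection)
          biopsies[[length(biopsies) + 1L]] <-
            data.frame(patient_id = pid, biopsy_date = tx_date + rej_day,
                       banff = "4")
        if (runif(1) < config$biopsy_policy$p_extra_negative) {
          far <- days[abs(days - rej_day) > 21]
          if (length(far) > 0)
            biopsies[[length(biopsies) + 1L]] <-
              data.frame(patient_id = pid,
                         biopsy_date = tx_date + far[sample.int(length(far), 1)],
                         banff = "1")
        }
      } else if (runif(1) < config$biopsy_policy$p_biopsy_control) {
        biopsies[[length(biopsies) + 1L]] <-
          data.frame(patient_id = pid,
                     biopsy_date = tx_date + days[sample.int(length(days), 1)],
                     banff = "1")
      }
      active <- rejection & !is.na(rej_day) & abs(days - rej_day) <= 7
      pat_eff <- rnorm(length(mets), 0, config$patient_sd)
      logc <- vapply(seq_along(days), function(k) {
        mu <- if (active[k]) config$metabolite_means$case
              else config$metabolite_means$control
        mu[mets] + pat_eff + rnorm(length(mets), 0, config$metabolite_sds[mets])
      }, numeric(length(mets)))
      sid <- sprintf("%s_S%02d", pid, seq_along(days))
      samples[[i]] <- data.frame(sample_id = sid, patient_id = pid,
                                 tx_date = tx_date,
                                 sample_date = tx_date + days,
                                 days_post_tx = days)
      truth[[i]] <- data.frame(sample_id = sid, patient_id = pid,
                               rejection_patient = rejection,
                               rejection_active = active)
      cm <- t(exp(logc)); rownames(cm) <- sid; colnames(cm) <- mets
      conc[[i]] <- cm
    }
    out <- list(samples = do.call(rbind, samples),
                biopsies = if (length(biopsies))
                  do.call(rbind, biopsies)
                else data.frame(patient_id = character(),
                                biopsy_date = as.Date(character()),
                                banff = character()),
                concentrations = do.call(rbind, conc),
                truth = do.call(rbind, truth))
    rownames(out$samples) <- rownames(out$truth) <- NULL
    class(out) <- "nmr_cohort"
    out
  })
}

#' @export
print.nmr_cohort <- function(x, ...) {
  cat(sprintf("<nmr_cohort> %d samples / %d patients, %d biopsies (%d BANFF-4)\n",
              nrow(x$samples), length(unique(x$samples$patient_id)),
              nrow(x$biopsies), sum(grepl("4", x$biopsies$banff))))
  invisible(x)
}

# evaluate the configured polynomial baseline at ppm
poly_baseline <- function(ppm, coefs) {
  y <- numeric(length(ppm))
  for (k in seq_along(coefs)) y <- y + coefs[k] * ppm^(k - 1)
  y
}

#' Simulate one urine NMR spectrum
#'
#' The spectrum is the sum of the metabolite multiplets (pseudo-Voigt
#' components with total area proportional to concentration), the TSP
#' reference singlet at 0.0 ppm, a smooth polynomial baseline, a broad
#' residual-water Lorentzian near 4.75 ppm, and i.i.d. Gaussian noise.
#'
#' @param concentrations Named non-negative vector; names must be panel
#'   metabolites (creatinine included).  Missing metabolites are absent
#'   from the spectrum.
#' @param config A [generator_config()].
#' @param sample_id Identifier stamped on the spectrum.
#' @param seed Optional seed for the noise draw; `NULL` uses the current
#'   RNG stream.
#' @return An [nmr_spectrum()].
#' @export
generate_spectrum <- function(concentrations, config, sample_id = "synthetic",
                              seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (any(concentrations < 0))
    stop("input error: negative concentration")
  tpl <- signal_templates()
  unknown <- setdiff(names(concentrations), tpl$metabolite)
  if (length(unknown))
    stop("no signal template for: ", paste(unknown, collapse = ", "))
  build <- function() {
    ppm <- seq(config$grid$ppm_min, config$grid$ppm_max, by = config$grid$ppm_step)
    y <- poly_baseline(ppm, config$baseline_params)
    wa <- config$water_artifact
    if (!is.null(wa) && wa$amplitude != 0)
      y <- y + wa$amplitude / (1 + 4 * ((ppm - wa$center) / wa$fwhm)^2)
    for (m in names(concentrations)) {
      if (concentrations[[m]] == 0) next
      r <- which(tpl$metabolite == m)
      y <- y + multiplet(ppm, tpl$center[r], tpl$offsets[[r]], tpl$weights[[r]],
                         concentrations[[m]], config$peak$fwhm, config$peak$eta)
    }
    r <- which(tpl$metabolite == "TSP")
    y <- y + multiplet(ppm, tpl$center[r], tpl$offsets[[r]], tpl$weights[[r]],
                       config$tsp$area, config$tsp$fwhm, config$tsp$eta)
    if (config$noise_sd > 0)
      y <- y + rnorm(length(ppm), 0, config$noise_sd)
    nmr_spectrum(ppm[1], config$grid$ppm_step, y, sample_id = sample_id)
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Simulate the spectra of a whole cohort
#'
#' One spectrum per cohort sample, with per-sample seeds derived from the
#' config seed so the result is reproducible regardless of call order.
#'
#' @param cohort A [generate_cohort()] result.
#' @param config The same [generator_config()].
#' @return Named list of [nmr_spectrum()] objects (names = sample ids).
#' @export
generate_cohort_spectra <- function(cohort, config) {
  stopifnot(inherits(cohort, "nmr_cohort"))
  ids <- rownames(cohort$concentrations)
  out <- lapply(seq_along(ids), function(k)
    generate_spectrum(cohort$concentrations[k, ], config, sample_id = ids[k],
                      seed = (config$seed + 7L * k) %% .Machine$integer.max))
  names(out) <- ids
  out
}

#' Simulate a standardized feature table from the published model
#'
#' Draws the four model features i.i.d. standard normal and labels each
#' row Bernoulli(Score/100) under the published score formula.  This is
#' the parameter-recovery harness: fitting logistic regression to enough
#' of these rows must recover the published coefficients.
#'
#' @param n Number of rows (>= 1).
#' @param model A [final_model()].
#' @param seed Integer seed.
#' @return List: `features` (n x 4 data.frame in model feature order),
#'   `labels` (integer 0/1), `omega` (true linear predictor).
#' @export
generate_feature_table <- function(n, model = final_model(), seed = 1L) {
  if (n < 1) stop("input error: n must be >= 1")
  stopifnot(inherits(model, "final_model"))
  with_seed(seed, {
    p <- length(model$feature_order)
    X <- matrix(rnorm(n * p), nrow = n,
                dimnames = list(NULL, model$feature_order))
    omega <- as.numeric(model$intercept + X %*% model$coefficients)
    labels <- rbinom(n, 1L, plogis(omega))
    list(features = as.data.frame(X), labels = labels, omega = omega)
  })
}

#' Write a synthetic cohort to plain-text files
#'
#' `samples.csv`, `biopsies.csv`, `concentrations.csv` and a
#' `truth.json` sidecar carrying the true labels for test oracles.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "nmr_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cohort$samples, file.path(dir, "samples.csv"), row.names = FALSE)
  write.csv(cohort$biopsies, file.path(dir, "biopsies.csv"), row.names = FALSE)
  write.csv(data.frame(sample_id = rownames(cohort$concentrations),
                       cohort$concentrations, check.names = FALSE),
            file.path(dir, "concentrations.csv"), row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
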