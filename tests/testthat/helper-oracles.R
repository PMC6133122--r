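# Independent oracles used across the suite.  These deliberately share no
# code with the package internals they check.

# AUC by brute force over all case-control pairs, half credit for ties
auc_pairwise <- function(scores, labels) {
  cases <- scores[labels == 1]
  ctrls <- scores[labels == 0]
  tot <- 0
  for (a in cases) for (b in ctrls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(ctrls))
}

# Labeling rule evaluator coded directly from the case/control definition,
# structured differently from the package implementation.
oracle_label <- function(sample_date, tx_date, biopsy_dates, banff_strings,
                         mode, setting = NULL) {
  if (as.numeric(sample_date - tx_date) < 0) stop("sample before transplant")
  # biopsies eligible: sample within 7 days before biopsy, inclusive both ends
  cand <- c()
  for (j in seq_along(biopsy_dates)) {
    gap <- as.numeric(biopsy_dates[j] - sample_date)
    if (!is.na(gap) && gap >= 0 && gap <= 7) cand <- c(cand, j)
  }
  lab_of <- function(b) {
    cats <- as.integer(strsplit(b, ",")[[1]])
    if (any(cats == 4)) return("case")
    if (all(cats == 1)) return("control")
    "excluded"
  }
  if (length(cand) > 0) {
    gaps <- as.numeric(biopsy_dates[cand] - sample_date)
    nearest <- cand[gaps == min(gaps)]
    pick <- nearest[length(nearest)]   # tie: later biopsy = later index here
    return(lab_of(banff_strings[pick]))
  }
  if (mode == "training") {
    if (length(biopsy_dates) == 0) return("control")
    all_neg <- TRUE
    for (b in banff_strings) if (lab_of(b) != "control") all_neg <- FALSE
    return(if (all_neg) "control" else "excluded")
  }
  if (identical(setting, "extended")) "control" else "excluded"
}

# random toy cohort for labeling tests: a handful of patients, biopsies
# with assorted BANFF strings, samples scattered around biopsy dates
random_toy_cohort <- function() {
  origin <- as.Date("2015-06-01")
  n_pat <- sample(2:5, 1)
  samples <- list(); biopsies <- list()
  banff_pool <- c("1", "2", "3", "4", "5", "2,4", "3,4", "1")
  for (p in seq_len(n_pat)) {
    pid <- paste0("T", p)
    tx <- origin + sample(0:100, 1)
    n_b <- sample(0:3, 1)
    if (n_b > 0) {
      bdays <- sample(20:200, n_b)
      biopsies[[pid]] <- data.frame(
        patient_id = pid, biopsy_date = tx + bdays,
        banff = sample(banff_pool, n_b, replace = TRUE))
    }
    n_s <- sample(1:8, 1)
    sdays <- sample(0:210, n_s)
    # bias some samples to sit near biopsies to exercise the 7-day window
    if (n_b > 0 && n_s > 2) {
      near <- sample(bdays, 1) - sample(c(-2, 0, 3, 7, 8, 10), 1)
      sdays[1] <- max(near, 0)
    }
    samples[[pid]] <- data.frame(
      sample_id = paste0(pid, "_", seq_len(n_s)), patient_id = pid,
      tx_date = tx, sample_date = tx + sdays)
  }
  list(samples = do.call(rbind, samples),
       biopsies = if (length(biopsies)) do.call(rbind, biopsies)
                  else data.frame(patient_id = character(),
                                  biopsy_date = as.Date(character()),
                                  banff = character()))
}

# compact generator config for spectrum-level tests
quiet_config <- function(..., seed = 1) {
  generator_config(
    n_patients = 2, noise_sd = 0, baseline_params = c(0),
    water_artifact = list(amplitude = 0, center = 4.75, fwhm = 0.2),
    seed = seed, ...)
}
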