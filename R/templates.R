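#' Metabolite signal templates
#'
#' The panel of NMR signals quantified by the pipeline: the ten candidate
#' metabolites (alanine, citrate, DMA, glucose, glucuronate, hippurate,
#' lactate, PAQ, trigonelline, urea), creatinine for urine-concentration
#' normalization, and the TSP chemical-shift reference.  Chemical shifts
#' and multiplet splittings are literature-standard values at 600 MHz;
#' they are project constants shipped with the package, not measured
#' quantities.
#'
#' @param file Path to a template CSV. Defaults to the file shipped in
#'   `inst/extdata/signal_templates.csv`.
#' @return A data.frame with one row per signal and columns
#'   \describe{
#'     \item{metabolite}{signal name}
#'     \item{role}{`"panel"` or `"reference"`}
#'     \item{center}{multiplet center, ppm}
#'     \item{offsets}{numeric list column: component offsets from center, ppm}
#'     \item{weights}{numeric list column: relative component intensities}
#'     \item{fit_lo, fit_hi}{fit window, ppm}
#'     \item{group}{signals sharing a group are fitted jointly in one window}
#'   }
#' @export
#' @examples
#' tpl <- signal_templates()
#' tpl[tpl$metabolite == "Lactate", c("center", "fit_lo", "fit_hi")]
signal_templates <- function(file = system.file("extdata", "signal_templates.csv",
                                                package = "nephroNMR")) {
  tpl <- read.csv(file, stringsAsFactors = FALSE)
  tpl$offsets <- lapply(strsplit(tpl$offsets, ";"), as.numeric)
  tpl$weights <- lapply(strsplit(tpl$weights, ";"), as.numeric)
  bad <- vapply(seq_len(nrow(tpl)), function(i) {
    any(tpl$center[i] + tpl$offsets[[i]] < tpl$fit_lo[i]) ||
      any(tpl$center[i] + tpl$offsets[[i]] > tpl$fit_hi[i]) ||
      length(tpl$offsets[[i]]) != length(tpl$weights[[i]])
  }, logical(1))
  if (any(bad))
    stop("malformed template row(s): ", paste(tpl$metabolite[bad], collapse = ", "))
  tpl
}

#' Names of the ten candidate metabolites (excluding creatinine)
#' @return Character vector of the ten model-candidate metabolites.
#' @export
panel_metabolites <- function() {
  tpl <- signal_templates()
  setdiff(tpl$metabolite[tpl$role == "panel"], "Creatinine")
}

#' The published final rejection-score model
#'
#' Loads the four-metabolite logistic model
#' \deqn{\omega = -3.0048615 - 0.2527461 I_{alanine} - 0.8224731 I_{citrate}
#'       + 0.9502339 I_{lactate} + 0.2529190 I_{urea}}
#' where each \eqn{I_x} is the creatinine-normalized, log-transformed,
#' centered and scaled signal intensity of metabolite \eqn{x}.
#'
#' The standardization constants behind \eqn{I_x} belong to the training
#' run that produced the features and were never published; a model file
#' may carry its own (`standardization` entry) or leave them `NULL`, in
#' which case features must already be standardized.
#'
#' @param file Path to a model JSON file; defaults to the shipped
#'   published model.
#' @return An object of class `final_model`: list with `intercept`,
#'   `coefficients` (named numeric), `feature_order`, `standardization`.
#' @export
#' @examples
#' m <- final_model()
#' m$coefficients["Citrate"]
final_model <- function(file = system.file("extdata", "final_model.json",
                                           package = "nephroNMR")) {
  raw <- jsonlite::read_json(file, simplifyVector = TRUE)
  m <- list(intercept = raw$intercept,
            coefficients = unlist(raw$coefficients),
            feature_order = raw$feature_order,
            standardization = raw$standardization,
            version = raw$version)
  if (!setequal(names(m$coefficients), m$feature_order))
    stop("model file inconsistent: coefficients vs feature_order")
  m$coefficients <- m$coefficients[m$feature_order]
  class(m) <- "final_model"
  m
}

#' @export
print.final_model <- function(x, ...) {
  cat("Rejection-score model (version ", x$version, ")\n", sep = "")
  cat(sprintf("  omega = %.7f", x$intercept))
  for (f in x$feature_order)
    cat(sprintf(" %+.7f*I_%s", x$coefficients[[f]], tolower(f)))
  cat("\n  Score = 100 / (1 + exp(-omega))\n")
  invisible(x)
}
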