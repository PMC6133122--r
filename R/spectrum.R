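#' Construct a 1D NMR spectrum
#'
#' A spectrum is stored on a uniform ppm grid: `ppm_start`, `ppm_step` and
#' the intensity vector.  `sample_id` and `batch_id` travel with the
#' spectrum through preprocessing.
#'
#' @param ppm_start First grid point (ppm).
#' @param ppm_step Grid spacing (ppm, > 0).
#' @param intensities Numeric vector of intensities (length >= 2, finite).
#' @param sample_id,batch_id Identifiers.
#' @return An object of class `nmr_spectrum`.
#' @export
nmr_spectrum <- function(ppm_start, ppm_step, intensities,
                         sample_id = "sample", batch_id = "batch") {
  stopifnot(is.numeric(ppm_start), length(ppm_start) == 1L,
            is.numeric(ppm_step), length(ppm_step) == 1L, ppm_step > 0,
            is.numeric(intensities), length(intensities) >= 2L)
  if (!all(is.finite(intensities)))
    stop("non-finite intensities in spectrum '", sample_id, "'")
  structure(list(ppm_start = as.numeric(ppm_start),
                 ppm_step = as.numeric(ppm_step),
                 intensities = as.numeric(intensities),
                 sample_id = as.character(sample_id),
                 batch_id = as.character(batch_id)),
            class = "nmr_spectrum")
}

#' Grid of ppm values of a spectrum
#' @param spectrum An `nmr_spectrum`.
#' @return Numeric vector, same length as the intensities.
#' @export
ppm_grid <- function(spectrum) {
  spectrum$ppm_start + spectrum$ppm_step * (seq_along(spectrum$intensities) - 1L)
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum '%s'> %d points, %.4f..%.4f ppm (step %.5f)\n",
              x$sample_id, length(x$intensities), x$ppm_start,
              x$ppm_start + x$ppm_step * (length(x$intensities) - 1L),
              x$ppm_step))
  invisible(x)
}

# intensities within a ppm interval (closed)
spectrum_window <- function(spectrum, lo, hi) {
  ppm <- ppm_grid(spectrum)
  keep <- ppm >= lo & ppm <= hi
  list(ppm = ppm[keep], y = spectrum$intensities[keep])
}

#' Read / write two-column spectrum CSV
#'
#' The primary plain-text interchange format: a CSV with columns
#' `ppm, intensity` on a uniform grid (ascending or descending ppm;
#' stored ascending).
#'
#' @param file Path.
#' @param sample_id,batch_id Metadata attached on read.
#' @return `read_spectrum_csv()`: an `nmr_spectrum`.
#' @export
read_spectrum_csv <- function(file, sample_id = basename(file), batch_id = "batch") {
  d <- read.csv(file)
  if (!all(c("ppm", "intensity") %in% names(d)))
    stop("spectrum CSV must have columns 'ppm' and 'intensity': ", file)
  o <- order(d$ppm)
  ppm <- d$ppm[o]; y <- d$intensity[o]
  steps <- diff(ppm)
  if (max(steps) - min(steps) > 1e-6 * mean(steps))
    stop("non-uniform ppm grid in ", file)
  nmr_spectrum(ppm[1], mean(steps), y, sample_id = sample_id, batch_id = batch_id)
}

#' @rdname read_spectrum_csv
#' @param spectrum An `nmr_spectrum` to write.
#' @param digits Significant digits for intensities.
#' @export
write_spectrum_csv <- function(spectrum, file, digits = 8) {
  d <- data.frame(ppm = ppm_grid(spectrum),
                  intensity = signif(spectrum$intensities, digits))
  write.csv(d, file, row.names = FALSE)
  invisible(file)
}

#' Minimal JCAMP-DX spectrum reader / writer
#'
#' Supports only the `(XY..XY)` AFFN point-pair form of `##XYDATA` /
#' `##PEAK TABLE`-style blocks, which is sufficient for round-tripping
#' the spectra this package generates.  Compressed (DIFDUP/SQZ) encodings
#' are not supported.
#'
#' @param file Path.
#' @return `read_spectrum_jdx()`: an `nmr_spectrum`.
#' @export
read_spectrum_jdx <- function(file) {
  lines <- readLines(file, warn = FALSE)
  title <- sub("^##TITLE=\\s*", "", grep("^##TITLE=", lines, value = TRUE)[1])
  if (is.na(title)) title <- basename(file)
  start <- grep("^##XYDATA=\\s*\\(XY\\.\\.XY\\)", lines)
  if (length(start) == 0L)
    stop("only ##XYDATA=(XY..XY) JCAMP-DX blocks are supported: ", file)
  end <- grep("^##END=", lines)
  end <- end[end > start[1]][1]
  body <- lines[(start[1] + 1L):(end - 1L)]
  body <- body[!grepl("^##", body)]
  pairs <- strsplit(trimws(body), "[,;[:space:]]+")
  xy <- do.call(rbind, lapply(pairs, function(p) as.numeric(p[1:2])))
  o <- order(xy[, 1])
  ppm <- xy[o, 1]; y <- xy[o, 2]
  nmr_spectrum(ppm[1], mean(diff(ppm)), y, sample_id = title)
}

#' @rdname read_spectrum_jdx
#' @param spectrum An `nmr_spectrum` to write.
#' @export
write_spectrum_jdx <- function(spectrum, file) {
  ppm <- ppm_grid(spectrum)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("##TITLE=", spectrum$sample_id),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=NMR SPECTRUM",
    "##XUNITS=PPM",
    "##YUNITS=ARBITRARY",
    sprintf("##FIRSTX=%.8g", ppm[1]),
    sprintf("##LASTX=%.8g", ppm[length(ppm)]),
    sprintf("##NPOINTS=%d", length(ppm)),
    "##XYDATA=(XY..XY)"), con)
  writeLines(sprintf("%.8g, %.8g", ppm, spectrum$intensities), con)
  writeLines("##END=", con)
  invisible(file)
}
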