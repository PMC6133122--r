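#' Pseudo-Voigt line shape
#'
#' The convex Gaussian/Lorentzian mixture used for all peak modelling:
#' \deqn{pV(x) = A\,[\eta L(x) + (1-\eta) G(x)]}
#' where \eqn{L} and \eqn{G} are unit-area Lorentzian and Gaussian
#' profiles sharing one full width at half maximum.
#'
#' @param x Positions (ppm).
#' @param center Peak center (ppm).
#' @param area Integrated peak area (intensity * ppm), >= 0.
#' @param fwhm Full width at half maximum (ppm), > 0.
#' @param eta Lorentzian mixing fraction in \[0, 1\].
#' @return Intensities at `x`.
#' @export
#' @examples
#' # value at center, pure Gaussian: area * 2*sqrt(log(2)/pi)/fwhm
#' pseudo_voigt(0, 0, area = 1, fwhm = 0.01, eta = 0)
pseudo_voigt <- function(x, center, area, fwhm, eta) {
  stopifnot(area >= 0, fwhm > 0, eta >= 0, eta <= 1)
  u <- (x - center) / fwhm
  lor <- (2 / (pi * fwhm)) / (1 + 4 * u^2)
  gau <- (2 / fwhm) * sqrt(log(2) / pi) * exp(-4 * log(2) * u^2)
  area * (eta * lor + (1 - eta) * gau)
}

# a multiplet: pseudo-Voigt components at center + offsets, total area
# split across components in proportion to weights; shared fwhm and eta
multiplet <- function(x, center, offsets, weights, area, fwhm, eta) {
  w <- weights / sum(weights)
  y <- numeric(length(x))
  for (j in seq_along(offsets))
    y <- y + pseudo_voigt(x, center + offsets[j], area * w[j], fwhm, eta)
  y
}
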