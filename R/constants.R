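#' Nuclear constants used across the package
#'
#' Gyromagnetic-ratio magnitudes relative to 1H, used to convert a
#' spectrometer 1H frequency (MHz) into the Larmor frequency of 15N or
#' 13C, e.g. for the rotational-correlation-time estimate and for
#' turning ppm shift differences into rad/s in dispersion models.
#'
#' @format Named numeric vector with elements `gammaN_over_gammaH`
#'   (0.101329) and `gammaC_over_gammaH` (0.251450).
#' @export
nmr_constants <- c(
  gammaN_over_gammaH = 0.101329,
  gammaC_over_gammaH = 0.251450
)

#' Larmor frequency of a nucleus at a given spectrometer field
#'
#' @param field_mhz 1H spectrometer frequency in MHz (e.g. 600, 850).
#' @param nucleus one of `"H"`, `"N"`, `"C"`.
#' @return frequency in Hz.
#' @export
larmor_hz <- function(field_mhz, nucleus = c("H", "N", "C")) {
  nucleus <- match.arg(nucleus)
  fac <- switch(nucleus,
    H = 1,
    N = nmr_constants[["gammaN_over_gammaH"]],
    C = nmr_constants[["gammaC_over_gammaH"]]
  )
  field_mhz * 1e6 * fac
}

#' Convert a chemical-shift difference in ppm to rad/s
#'
#' @param dw_ppm shift difference in ppm.
#' @param field_mhz 1H spectrometer frequency in MHz.
#' @param nucleus nucleus the shift belongs to.
#' @return angular frequency difference in rad/s.
#' @export
ppm_to_rad <- function(dw_ppm, field_mhz, nucleus = c("H", "N", "C")) {
  2 * pi * dw_ppm * larmor_hz(field_mhz, match.arg(nucleus)) * 1e-6
}
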