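# Parametric endmember spectra. Analytic curves, not library lookups, so the
# simulator carries no data files: a logistic red edge plus Gaussian green
# peak for vegetation, a gentle linear ramp for soil.

#' Parametric green-vegetation endmember
#'
#' Builds a smooth vegetation reflectance spectrum: low red reflectance with a
#' Gaussian green peak near 550 nm, a logistic red edge rising to a flat NIR
#' plateau. The red absorption trough level is tied to the green peak
#' (`green_peak / 3`) so that an all-zero parameterisation yields an all-dark
#' spectrum.
#'
#' @param wavelengths wavelength grid in nm (default native grid).
#' @param nir_plateau NIR plateau reflectance in \[0, 1\].
#' @param green_peak green-peak (550 nm) reflectance in \[0, 1\].
#' @param red_edge red-edge inflection position in nm, within \[680, 760\].
#' @param red_edge_width logistic width in nm.
#' @return Reflectance vector in \[0, 1\] on `wavelengths`.
#' @export
make_vegetation_endmember <- function(wavelengths = native_grid(),
                                      nir_plateau = 0.45,
                                      green_peak = 0.12,
                                      red_edge = 715,
                                      red_edge_width = 15) {
  stop_if_not_scalar_in(nir_plateau, 0, 1, "nir_plateau")
  stop_if_not_scalar_in(green_peak, 0, 1, "green_peak")
  stop_if_not_scalar_in(red_edge, 680, 760, "red_edge")
  stopifnot(red_edge_width > 0)
  red_trough <- green_peak / 3
  vis <- red_trough + (green_peak - red_trough) * exp(-((wavelengths - 550) / 40)^2)
  edge <- plogis((wavelengths - red_edge) / red_edge_width)
  r <- vis * (1 - edge) + nir_plateau * edge
  pmin(pmax(r, 0), 1)
}

#' Parametric bare-soil endmember
#'
#' A gentle, nearly linear brightness ramp rising with wavelength, typical of
#' dry soil background.
#'
#' @param wavelengths wavelength grid in nm.
#' @param level_340,level_1022 reflectance at the grid endpoints, in \[0, 1\].
#' @return Reflectance vector in \[0, 1\] on `wavelengths`.
#' @export
make_soil_endmember <- function(wavelengths = native_grid(),
                                level_340 = 0.08, level_1022 = 0.28) {
  stop_if_not_scalar_in(level_340, 0, 1, "level_340")
  stop_if_not_scalar_in(level_1022, 0, 1, "level_1022")
  w <- (wavelengths - 340) / (1022 - 340)
  pmin(pmax(level_340 + (level_1022 - level_340) * w, 0), 1)
}
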