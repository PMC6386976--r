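# Instrument model: native wavelength grid, fibres, integration times, noise.

#' Native spectrometer wavelength grid
#'
#' The instrument samples 340-1022 nm with a 1.33 nm full-width-half-maximum
#' optical resolution; the grid is idealised as exactly uniform: 513 samples
#' starting at 340 nm with 1.33 nm spacing (last sample 1020.96 nm).
#'
#' @return Numeric vector of 513 wavelengths in nm.
#' @export
native_grid <- function() seq(340, by = 1.33, length.out = 513L)

#' Analysis wavelength grid
#'
#' The 400-900 nm, 5 nm grid (101 bands) on which all statistical modelling
#' operates.
#'
#' @return Numeric vector of 101 wavelengths in nm.
#' @export
analysis_grid <- function() seq(400, 900, by = 5)

#' Spectrometer sensor model
#'
#' Describes the dual field-of-view instrument: one spectrometer fed by two
#' fibres — a bare upwelling fibre (400 um, 25 deg view) looking at the canopy
#' and a cosine-corrected downwelling fibre (600 um) looking at the sky.
#' Counts scale with irradiance x integration time x fibre cross-sectional
#' area x `gain`. Dark current adds `dark_level` counts (sd `dark_sd`);
#' photon shot noise is Poisson when `shot_noise` is TRUE.
#'
#' @param fiber_diameter_up,fiber_diameter_down fibre diameters in um.
#' @param it_up_range,it_down_range integration-time draw ranges in ms for the
#'   upwelling and downwelling channels.
#' @param dark_level mean dark-current counts.
#' @param dark_sd standard deviation of dark-current counts.
#' @param full_well saturation level in counts.
#' @param gain counts per (relative irradiance unit x ms x fibre-area unit),
#'   where fibre area is (diameter/100)^2.
#' @param shot_noise logical; draw target counts as Poisson.
#' @return An object of class `sensor_model`.
#' @export
sensor_model <- function(fiber_diameter_up = 400, fiber_diameter_down = 600,
                         it_up_range = c(13, 15), it_down_range = c(4, 6),
                         dark_level = 150, dark_sd = 5,
                         full_well = 65535, gain = 200, shot_noise = TRUE) {
  stopifnot(fiber_diameter_up > 0, fiber_diameter_down > 0,
            length(it_up_range) == 2L, length(it_down_range) == 2L,
            all(it_up_range > 0), all(it_down_range > 0),
            diff(it_up_range) >= 0, diff(it_down_range) >= 0,
            dark_level >= 0, dark_sd >= 0, gain > 0)
  if (dark_level >= full_well)
    stop("`dark_level` must be below `full_well`", call. = FALSE)
  structure(list(
    wavelengths = native_grid(),
    fiber_diameter_up = fiber_diameter_up,
    fiber_diameter_down = fiber_diameter_down,
    it_up_range = it_up_range, it_down_range = it_down_range,
    dark_level = dark_level, dark_sd = dark_sd,
    full_well = full_well, gain = gain,
    shot_noise = isTRUE(shot_noise)
  ), class = "sensor_model")
}

# Fibre cross-sectional area in the gain's area unit.
fiber_area <- function(diameter_um) (diameter_um / 100)^2

#' Raw spectrometer frame
#'
#' One readout: counts on the native grid for one channel, target or dark.
#'
#' @param channel `"up"` (radiance fibre) or `"down"` (irradiance fibre).
#' @param is_dark logical; shutter-closed dark frame.
#' @param integration_time integration time in ms (> 0).
#' @param wavelengths native wavelength grid (nm).
#' @param counts nonnegative counts, same length as `wavelengths`.
#' @param saturated logical saturation flag.
#' @return An object of class `raw_frame`.
#' @export
raw_frame <- function(channel, is_dark, integration_time, wavelengths, counts,
                      saturated = FALSE) {
  channel <- match.arg(channel, c("up", "down"))
  if (!is.numeric(integration_time) || length(integration_time) != 1L ||
      integration_time <= 0)
    stop("`integration_time` must be a positive scalar (ms)", call. = FALSE)
  if (length(counts) != length(wavelengths))
    stop("`counts` and `wavelengths` lengths differ", call. = FALSE)
  if (any(counts < 0))
    stop("`counts` must be nonnegative", call. = FALSE)
  structure(list(channel = channel, is_dark = isTRUE(is_dark),
                 integration_time = integration_time,
                 wavelengths = wavelengths, counts = counts,
                 saturated = isTRUE(saturated)),
            class = "raw_frame")
}

#' Footprint radius of the upwelling fibre on the ground
#'
#' A bare fibre with full view angle `fov_deg` held `height_m` above the
#' canopy sees a disc of radius `height_m * tan(fov_deg / 2)`.
#'
#' @param height_m fibre height above ground in m.
#' @param fov_deg full view angle in degrees.
#' @return Footprint radius in m.
#' @examples
#' fov_footprint_radius(0.60, 25)  # ~0.13 m
#' @export
fov_footprint_radius <- function(height_m = 0.60, fov_deg = 25) {
  stopifnot(height_m > 0, fov_deg > 0, fov_deg < 180)
  height_m * tan(fov_deg / 2 * pi / 180)
}

#' Spectral samples collected along one plot row
#'
#' At ground speed `speed_m_s` a row of length `row_length_m` takes
#' `row_length_m / speed_m_s` seconds to traverse; one full four-frame
#' measurement sequence every `sample_period_s` seconds yields
#' `floor(traverse time / period)` samples.
#'
#' @param row_length_m plot row length in m.
#' @param speed_m_s platform ground speed in m/s.
#' @param sample_period_s time between starts of successive sequences in s.
#' @return Integer number of samples per row.
#' @examples
#' samples_per_row(7.6, 0.22, 2.6)  # 13
#' @export
samples_per_row <- function(row_length_m = 7.6, speed_m_s = 0.22,
                            sample_period_s = 2.6) {
  stopifnot(row_length_m > 0, speed_m_s > 0, sample_period_s > 0)
  as.integer(floor((row_length_m / speed_m_s) / sample_period_s))
}
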