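# Downwelling illumination: solar-like spectral shape, with sky condition
# controlling magnitude (large) and, optionally, NIR spectral shape (mild).

#' Solar-like relative irradiance spectrum
#'
#' Blackbody spectral shape at `temperature` K, normalised to peak 1 on the
#' supplied grid. Units are relative energy; the processing chain only ever
#' uses ratios, so absolute calibration is irrelevant.
#'
#' @param wavelengths wavelength grid in nm.
#' @param temperature blackbody temperature in K.
#' @return Positive numeric vector, max 1.
#' @export
solar_irradiance <- function(wavelengths = native_grid(), temperature = 5800) {
  stopifnot(temperature > 0)
  lam <- wavelengths * 1e-9
  hc_k <- 0.0143877688  # h*c/k_B, m K
  e <- lam^-5 / expm1(hc_k / (lam * temperature))
  e / max(e)
}

#' Multiplicative NIR shape perturbation
#'
#' Smooth spectral multiplier near 1 that up-weights wavelengths beyond
#' ~750 nm by up to `boost`, emulating the mild spectral-shape divergence of
#' overcast vs. clear-sky illumination in the near infrared. Off (boost 0)
#' by default in [illumination_model()].
#'
#' @param boost maximum fractional up-weighting (e.g. 0.03 for 3 percent).
#' @return A function of wavelengths returning the multiplier.
#' @export
nir_shape_perturbation <- function(boost = 0.03) {
  stop_if_not_scalar_in(boost, 0, 0.5, "boost")
  function(wavelengths) 1 + boost * plogis((wavelengths - 750) / 30)
}

#' Sky illumination model
#'
#' Sunny and cloudy skies share the solar-like base spectral shape; the sky
#' condition drives a large magnitude difference and per-sequence temporal
#' variability. Sunny: magnitude 1 with <= 1 percent jitter. Cloudy: magnitude
#' drawn per sequence from `scale_range` (default \[0.1, 0.5\], scattered to
#' full cloud cover) with 5 percent jitter. An optional smooth
#' `shape_perturbation` multiplier models mild spectral-shape differences;
#' identity by default.
#'
#' @param condition `"sunny"` or `"cloudy"`.
#' @param scale_range range the per-sequence magnitude scale is drawn from.
#' @param temporal_jitter_sd sd of per-sequence lognormal magnitude jitter.
#' @param base_irradiance function of wavelengths giving the positive base
#'   spectrum.
#' @param shape_perturbation optional function of wavelengths giving a smooth
#'   multiplier near 1 (see [nir_shape_perturbation()]).
#' @return An object of class `illumination_model`.
#' @export
illumination_model <- function(condition = c("sunny", "cloudy"),
                               scale_range = NULL,
                               temporal_jitter_sd = NULL,
                               base_irradiance = solar_irradiance,
                               shape_perturbation = NULL) {
  condition <- match.arg(condition)
  scale_range <- scale_range %||%
    if (condition == "sunny") c(1, 1) else c(0.1, 0.5)
  temporal_jitter_sd <- temporal_jitter_sd %||%
    if (condition == "sunny") 0.01 else 0.05
  stopifnot(length(scale_range) == 2L, all(scale_range > 0),
            diff(scale_range) >= 0, temporal_jitter_sd >= 0,
            is.function(base_irradiance))
  structure(list(condition = condition,
                 scale_range = scale_range,
                 magnitude_scale = mean(scale_range),
                 temporal_jitter_sd = temporal_jitter_sd,
                 base_irradiance = base_irradiance,
                 shape_perturbation = shape_perturbation),
            class = "illumination_model")
}

# Evaluate the illumination spectrum for one sequence, given a drawn scale.
illumination_spectrum <- function(illum, wavelengths, scale) {
  e <- illum$base_irradiance(wavelengths) * scale
  if (!is.null(illum$shape_perturbation))
    e <- e * illum$shape_perturbation(wavelengths)
  if (any(e < 0) || all(e == 0))
    stop("degenerate illumination: irradiance must be positive somewhere",
         call. = FALSE)
  e
}
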