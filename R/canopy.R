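# Canopy model: soil-vegetation linear mixture with fractional cover that
# saturates in plant population (foliage overlap at later stages).

#' Canopy mixture model
#'
#' Holds the vegetation and soil endmembers, the per-stage cover coefficients
#' of the saturating cover law, and the variability knobs used by the trial
#' generator. Fractional ground cover follows
#' `f = 1 - exp(-(c_stage * population)^overlap_exponent)` with population in
#' plants x 10^4 per hectare: near-linear at small `c * p` (small seedlings),
#' saturating towards 1 as foliage overlaps.
#'
#' Stage-dependent variability emulates field reality at a 0.13 m-radius
#' footprint: early-stage seedlings are small relative to the footprint, so
#' both plot-level plant-size variation (`size_jitter_cv`) and within-plot
#' sequence-to-sequence cover variation (`within_plot_cover_cv`) shrink with
#' development stage.
#'
#' @param veg,soil endmember reflectance vectors on the native grid, in
#'   \[0, 1\].
#' @param cover_coefficient named per-stage cover coefficients in
#'   (plants x 10^4 / ha)^-1.
#' @param overlap_exponent exponent `k` of the cover law (> 0).
#' @param size_jitter_cv named per-stage lognormal CV of the plot-level
#'   effective cover coefficient (plant-size variation).
#' @param within_plot_cover_cv named per-stage lognormal CV of
#'   sequence-level cover around the plot mean.
#' @param soil_brightness_cv lognormal CV of per-plot soil brightness.
#' @param soil_shape_sd sd of the per-plot smooth multiplicative soil shape
#'   perturbation (moisture/residue patterning).
#' @param tillage_brightness named soil-brightness multipliers per tillage.
#' @param spacing_cover named cover multipliers per row spacing (the
#'   row-centred footprint sees denser rows under wide spacing).
#' @param cultivar_nir named NIR-plateau multipliers per cultivar.
#' @return An object of class `canopy_model`.
#' @export
canopy_model <- function(veg = make_vegetation_endmember(),
                         soil = make_soil_endmember(),
                         cover_coefficient = c(VC = 0.008, V1 = 0.012,
                                               V2 = 0.025, V3 = 0.040),
                         overlap_exponent = 1,
                         size_jitter_cv = c(VC = 0.18, V1 = 0.15,
                                            V2 = 0.10, V3 = 0.08),
                         within_plot_cover_cv = c(VC = 0.50, V1 = 0.40,
                                                  V2 = 0.25, V3 = 0.15),
                         soil_brightness_cv = 0.06,
                         soil_shape_sd = 0.04,
                         tillage_brightness = c(CT = 1.10, NT = 0.88),
                         spacing_cover = c("0.38" = 0.95, "0.76" = 1.05),
                         cultivar_nir = c(C1 = 1.00, C2 = 1.03)) {
  if (length(veg) != length(soil))
    stop("`veg` and `soil` must share a grid", call. = FALSE)
  if (any(veg < 0 | veg > 1) || any(soil < 0 | soil > 1))
    stop("endmember reflectances must lie in [0, 1]", call. = FALSE)
  stopifnot(all(cover_coefficient > 0), overlap_exponent > 0,
            all(size_jitter_cv >= 0), all(within_plot_cover_cv >= 0),
            soil_brightness_cv >= 0, soil_shape_sd >= 0,
            all(tillage_brightness > 0), all(spacing_cover > 0),
            all(cultivar_nir > 0))
  structure(list(veg = veg, soil = soil,
                 cover_coefficient = cover_coefficient,
                 overlap_exponent = overlap_exponent,
                 size_jitter_cv = size_jitter_cv,
                 within_plot_cover_cv = within_plot_cover_cv,
                 soil_brightness_cv = soil_brightness_cv,
                 soil_shape_sd = soil_shape_sd,
                 tillage_brightness = tillage_brightness,
                 spacing_cover = spacing_cover,
                 cultivar_nir = cultivar_nir),
            class = "canopy_model")
}

#' Fractional ground cover from plant population
#'
#' `f = 1 - exp(-(c_stage * population)^k)`. Monotone nondecreasing in
#' population, `f(0) = 0`, approaching 1 as population grows (foliage
#' overlap); strictly concave for `k = 1`.
#'
#' @param population plant population, plants x 10^4 per hectare (>= 0);
#'   vectorised.
#' @param stage development stage label matching
#'   `names(canopy$cover_coefficient)`.
#' @param canopy a [canopy_model()].
#' @return Fractional cover in \[0, 1\], same length as `population`.
#' @export
fractional_cover <- function(population, stage, canopy = canopy_model()) {
  if (any(!is.finite(population)) || any(population < 0))
    stop("`population` must be finite and nonnegative", call. = FALSE)
  cc <- canopy$cover_coefficient
  if (!stage %in% names(cc))
    stop(sprintf("unknown stage '%s'", stage), call. = FALSE)
  1 - exp(-(cc[[stage]] * population)^canopy$overlap_exponent)
}

#' Canopy reflectance as a soil-vegetation linear mixture
#'
#' `R = f * veg + (1 - f) * soil`, bandwise; the result lies in the convex
#' hull of the two endmembers.
#'
#' @param cover fractional cover in \[0, 1\].
#' @param canopy a [canopy_model()].
#' @param veg,soil optional endmember overrides (e.g. per-plot perturbed
#'   soil).
#' @return Reflectance vector on the endmember grid.
#' @export
canopy_reflectance <- function(cover, canopy = canopy_model(),
                               veg = canopy$veg, soil = canopy$soil) {
  stop_if_not_scalar_in(cover, 0, 1, "cover")
  cover * veg + (1 - cover) * soil
}
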