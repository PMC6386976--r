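# Shared fixtures. The default trial is expensive, so it is generated once
# per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# Default-condition trial (seed 101), processed to plot-mean analysis spectra.
default_processed <- function() {
  if (is.null(.fixture_cache$proc)) {
    trial <- generate_trial(trial_design(seed = 101))
    .fixture_cache$proc <- process_trial(trial)
  }
  .fixture_cache$proc
}

noise_free_sensor <- function(...) sensor_model(shot_noise = FALSE, dark_sd = 0, ...)

# Canopy with every stochastic and treatment effect switched off.
neutral_canopy <- function(...) {
  z4 <- c(VC = 0, V1 = 0, V2 = 0, V3 = 0)
  canopy_model(size_jitter_cv = z4, within_plot_cover_cv = z4,
               soil_brightness_cv = 0, soil_shape_sd = 0,
               tillage_brightness = c(CT = 1, NT = 1),
               spacing_cover = c("0.38" = 1, "0.76" = 1),
               cultivar_nir = c(C1 = 1, C2 = 1), ...)
}

fixed_illum <- function(condition, scale)
  illumination_model(condition, scale_range = c(scale, scale),
                     temporal_jitter_sd = 0)

# Smooth random reflectance in (0, 1) on the native grid.
random_reflectance <- function(seed) {
  wl <- native_grid()
  centers <- seq(350, 1010, length.out = 8)
  amp <- local_seed_draw(seed, rnorm(8, 0, 0.12))
  base <- 0.3 + drop(exp(-(outer(wl, centers, "-") / 90)^2) %*% amp)
  pmin(pmax(base, 0.02), 0.95)
}

local_seed_draw <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Two-band raw frame shortcut for radiometry unit tests.
mini_frame <- function(channel, is_dark, it, counts, wl = c(500, 600),
                       saturated = FALSE)
  raw_frame(channel, is_dark, it, wl, counts, saturated)

mini_sequence <- function(up_net, down_net, it_up = 15, it_down = 5,
                          up_dark = c(0, 0), down_dark = c(0, 0),
                          wl = c(500, 600)) {
  measurement_sequence(list(
    up_dark = mini_frame("up", TRUE, it_up, up_dark, wl),
    up_target = mini_frame("up", FALSE, it_up, up_net + up_dark, wl),
    down_target = mini_frame("down", FALSE, it_down, down_net + down_dark, wl),
    down_dark = mini_frame("down", TRUE, it_down, down_dark, wl)),
    sequence_id = "t1", plot_id = "p1")
}
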