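# Synthetic trial generator: dual field-of-view count data with the
# statistical structure the analysis assumes, so every downstream stage is
# testable without any field data.

#' Four-frame measurement sequence
#'
#' One spectral sample: upwelling dark, upwelling target, downwelling target,
#' downwelling dark (the acquisition order), plus provenance.
#'
#' @param frames named list with elements `up_dark`, `up_target`,
#'   `down_target`, `down_dark`, each a [raw_frame()].
#' @param sequence_id,plot_id,row_index,condition provenance fields.
#' @param seed seed the sequence was generated from (NA for real data).
#' @return An object of class `measurement_sequence`.
#' @export
measurement_sequence <- function(frames, sequence_id = NA_character_,
                                 plot_id = NA_character_,
                                 row_index = NA_integer_,
                                 condition = NA_character_, seed = NA) {
  needed <- c("up_dark", "up_target", "down_target", "down_dark")
  if (!all(needed %in% names(frames)))
    stop("sequence incomplete: frames must contain ",
         paste(needed, collapse = ", "), call. = FALSE)
  ok <- vapply(frames[needed], inherits, logical(1), what = "raw_frame")
  if (!all(ok)) stop("all frames must be raw_frame objects", call. = FALSE)
  structure(list(frames = frames[needed], sequence_id = sequence_id,
                 plot_id = plot_id, row_index = row_index,
                 condition = condition, seed = seed),
            class = "measurement_sequence")
}

#' Simulate one four-frame measurement sequence
#'
#' Expected dark-subtracted target counts follow the instrument forward
#' model: upwelling `irradiance x reflectance x t_up x area(fiber_up) x gain`,
#' downwelling `irradiance x t_down x area(fiber_down) x gain`. Integration
#' times are drawn from the sensor ranges; if the predicted signal would
#' saturate, the integration time is re-drawn once and the frame flagged
#' saturated if counts still reach the full well. With `shot_noise` off and
#' `dark_sd` 0 the sequence round-trips exactly through
#' [relative_reflectance()].
#'
#' @param reflectance target reflectance on the sensor's native grid, in
#'   \[0, 1\].
#' @param illum an [illumination_model()].
#' @param sensor a [sensor_model()].
#' @param seed integer seed; identical seeds give identical frames.
#' @param sequence_id,plot_id,row_index,condition provenance carried on the
#'   result.
#' @return A [measurement_sequence()].
#' @export
simulate_sequence <- function(reflectance, illum, sensor = sensor_model(),
                              seed = 1,
                              sequence_id = NA_character_,
                              plot_id = NA_character_,
                              row_index = NA_integer_,
                              condition = illum$condition) {
  wl <- sensor$wavelengths
  if (length(reflectance) != length(wl))
    stop("`reflectance` must be on the sensor's native grid", call. = FALSE)
  if (any(!is.finite(reflectance)) || any(reflectance < 0 | reflectance > 1))
    stop("`reflectance` values must lie in [0, 1]", call. = FALSE)
  a_up <- fiber_area(sensor$fiber_diameter_up)
  a_down <- fiber_area(sensor$fiber_diameter_down)

  local_seed(seed, {
    scale <- runif(1, illum$scale_range[1], illum$scale_range[2])
    if (illum$temporal_jitter_sd > 0)
      scale <- scale * exp(rnorm(1, 0, illum$temporal_jitter_sd))
    e <- illumination_spectrum(illum, wl, scale)

    mu_up <- function(it) e * reflectance * it * a_up * sensor$gain
    mu_down <- function(it) e * it * a_down * sensor$gain
    would_sat <- function(mu)
      max(mu) + sensor$dark_level + 5 * sqrt(max(mu)) > sensor$full_well

    it_up <- runif(1, sensor$it_up_range[1], sensor$it_up_range[2])
    it_down <- runif(1, sensor$it_down_range[1], sensor$it_down_range[2])
    if (would_sat(mu_up(it_up)))      # one re-draw, then live with it
      it_up <- runif(1, sensor$it_up_range[1], sensor$it_up_range[2])
    if (would_sat(mu_down(it_down)))
      it_down <- runif(1, sensor$it_down_range[1], sensor$it_down_range[2])

    draw_dark_noise <- function()
      if (sensor$dark_sd > 0) rnorm(length(wl), 0, sensor$dark_sd)
      else numeric(length(wl))
    clamp <- function(x) pmin(pmax(x, 0), sensor$full_well)
    draw_target <- function(mu) {
      sig <- if (sensor$shot_noise) rpois(length(mu), mu) else mu
      clamp(sig + sensor$dark_level + draw_dark_noise())
    }
    draw_dark <- function() clamp(sensor$dark_level + draw_dark_noise())

    up_dark_counts <- draw_dark()
    up_counts <- draw_target(mu_up(it_up))
    down_counts <- draw_target(mu_down(it_down))
    down_dark_counts <- draw_dark()
    sat_up <- any(up_counts >= sensor$full_well)
    sat_down <- any(down_counts >= sensor$full_well)

    frames <- list(
      up_dark = raw_frame("up", TRUE, it_up, wl, up_dark_counts),
      up_target = raw_frame("up", FALSE, it_up, wl, up_counts, sat_up),
      down_target = raw_frame("down", FALSE, it_down, wl, down_counts, sat_down),
      down_dark = raw_frame("down", TRUE, it_down, wl, down_dark_counts))
    measurement_sequence(frames, sequence_id = sequence_id, plot_id = plot_id,
                         row_index = row_index, condition = condition,
                         seed = seed)
  })
}

default_condition_schedule <- function(replicates, stages) {
  sched <- expand.grid(replicate = seq_len(replicates), stage = stages,
                       stringsAsFactors = FALSE)
  sched$condition <- "cloudy"
  sched$condition[sched$replicate == 1 & sched$stage == "V1"] <- "sunny"
  sched$condition[sched$replicate == 2 & sched$stage == "V3"] <- "sunny"
  sched
}

#' Field-trial design
#'
#' The canonical design: 2 replicates x 4 vegetative stages (VC, V1, V2, V3)
#' x 2 row spacings (0.38, 0.76 m) x 2 tillages (NT, CT) x 2 cultivars x 14
#' seeding rates spanning 3.7-51.8 seeds x 10^4 per hectare, with 13 spectral
#' samples per plot row and 2 rows sampled per plot. The condition schedule
#' maps each (replicate, stage) to a sky condition; by default replicate 1 was
#' measured sunny at V1 and replicate 2 sunny at V3, all other dates cloudy.
#'
#' Emergence (fraction of seeds producing a counted plant) is drawn per
#' physical plot from `N(emergence_mean, emergence_sd)` truncated to (0, 1];
#' the defaults are simulator conventions, not field-derived values.
#'
#' @param replicates number of replicates.
#' @param stages development-stage labels.
#' @param row_spacings row spacings in m.
#' @param tillages tillage labels.
#' @param cultivars cultivar labels.
#' @param seeding_rates 14 strictly increasing rates, seeds x 10^4 / ha.
#' @param emergence_mean,emergence_sd emergence fraction distribution.
#' @param condition_schedule data.frame (replicate, stage, condition)
#'   covering every (replicate, stage); defaults as described above.
#' @param samples_per_row sequences per plot row.
#' @param rows_per_plot rows sampled per plot.
#' @param seed master seed for the whole trial.
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(replicates = 2L,
                         stages = c("VC", "V1", "V2", "V3"),
                         row_spacings = c(0.38, 0.76),
                         tillages = c("NT", "CT"),
                         cultivars = c("C1", "C2"),
                         seeding_rates = 3.7 * (1:14),
                         emergence_mean = 0.85, emergence_sd = 0.08,
                         condition_schedule = NULL,
                         samples_per_row = 13L, rows_per_plot = 2L,
                         seed = 1L) {
  if (length(seeding_rates) != 14L || any(diff(seeding_rates) <= 0))
    stop("`seeding_rates` must be 14 strictly increasing values", call. = FALSE)
  stop_if_not_scalar_in(emergence_mean, 1e-6, 1, "emergence_mean")
  stopifnot(emergence_sd >= 0, replicates >= 1, samples_per_row >= 1,
            rows_per_plot >= 1, length(stages) >= 1)
  condition_schedule <- condition_schedule %||%
    default_condition_schedule(replicates, stages)
  need <- expand.grid(replicate = seq_len(replicates), stage = stages,
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$replicate, d$stage)
  if (!all(key(need) %in% key(condition_schedule)))
    stop("`condition_schedule` must cover every (replicate, stage)",
         call. = FALSE)
  if (!all(condition_schedule$condition %in% c("sunny", "cloudy")))
    stop("conditions must be 'sunny' or 'cloudy'", call. = FALSE)
  structure(list(replicates = as.integer(replicates), stages = stages,
                 row_spacings = row_spacings, tillages = tillages,
                 cultivars = cultivars, seeding_rates = seeding_rates,
                 emergence_mean = emergence_mean, emergence_sd = emergence_sd,
                 condition_schedule = condition_schedule,
                 samples_per_row = as.integer(samples_per_row),
                 rows_per_plot = as.integer(rows_per_plot),
                 seed = seed),
            class = "trial_design")
}

#' Generate a full synthetic trial
#'
#' Produces one plot record per (replicate, stage, row spacing, tillage,
#' cultivar, seeding rate) combination — 224 per stage, 896 in total for the
#' default design — and `rows_per_plot x samples_per_row` (26) simulated
#' measurement sequences per plot record. Measured population is seeding rate
#' times a truncated-normal emergence draw shared across the stages of the
#' same physical plot. Ground-truth fractional cover and plot reflectance are
#' stored for testing. Deterministic in `design$seed`.
#'
#' @param design a [trial_design()].
#' @param canopy a [canopy_model()].
#' @param sensor a [sensor_model()].
#' @param illum_by_condition named list of [illumination_model()]s for
#'   `"sunny"` and `"cloudy"`.
#' @return An object of class `sim_trial`: list with `plots` (plot records
#'   incl. `measured_population`, `condition`, `cover_truth`), `truth`
#'   (plots x native-grid matrix of noise-free plot reflectance),
#'   `sequences` (list of [measurement_sequence()]), and the models used.
#' @export
generate_trial <- function(design = trial_design(), canopy = canopy_model(),
                           sensor = sensor_model(),
                           illum_by_condition = list(
                             sunny = illumination_model("sunny"),
                             cloudy = illumination_model("cloudy"))) {
  stopifnot(inherits(design, "trial_design"), inherits(canopy, "canopy_model"),
            inherits(sensor, "sensor_model"))
  conds <- unique(design$condition_schedule$condition)
  if (!all(conds %in% names(illum_by_condition)))
    stop("`illum_by_condition` must cover the scheduled conditions",
         call. = FALSE)
  if (!all(design$stages %in% names(canopy$cover_coefficient)))
    stop("canopy cover coefficients missing for some stages", call. = FALSE)
  wl <- sensor$wavelengths

  field <- expand.grid(seeding_rate = design$seeding_rates,
                       cultivar = design$cultivars,
                       tillage = design$tillages,
                       row_spacing = design$row_spacings,
                       replicate = seq_len(design$replicates),
                       stringsAsFactors = FALSE)
  field$field_plot <- sprintf("P%03d", seq_len(nrow(field)))

  nf <- nrow(field)
  plots <- field[rep(seq_len(nf), times = length(design$stages)), ,
                 drop = FALSE]
  plots$stage <- rep(design$stages, each = nf)
  rownames(plots) <- NULL
  plots$plot_id <- paste0(plots$field_plot, "_", plots$stage)
  sched_key <- paste(design$condition_schedule$replicate,
                     design$condition_schedule$stage)
  plots$condition <- design$condition_schedule$condition[
    match(paste(plots$replicate, plots$stage), sched_key)]

  n <- nrow(plots)
  nseq_per_plot <- design$rows_per_plot * design$samples_per_row
  truth <- matrix(NA_real_, n, length(wl),
                  dimnames = list(plots$plot_id, NULL))
  cover <- numeric(n)
  seq_list <- vector("list", n * nseq_per_plot)

  # smooth random soil-shape basis: 6 broad Gaussian bumps
  bump_centers <- seq(360, 1000, length.out = 6)
  bumps <- exp(-(outer(wl, bump_centers, "-") / 80)^2)

  local_seed(design$seed, {
    em <- rnorm(nf, design$emergence_mean, design$emergence_sd)
    em <- pmin(pmax(em, 1e-3), 1)
    pop_field <- field$seeding_rate * em
    plots$measured_population <- rep(pop_field, times = length(design$stages))

    seq_counter <- 0L
    for (i in seq_len(n)) {
      st <- plots$stage[i]
      sp_key <- as.character(plots$row_spacing[i])
      sp_fac <- if (sp_key %in% names(canopy$spacing_cover))
        canopy$spacing_cover[[sp_key]] else 1
      c_eff <- canopy$cover_coefficient[[st]] * sp_fac
      if (canopy$size_jitter_cv[[st]] > 0)
        c_eff <- c_eff * exp(rnorm(1, 0, canopy$size_jitter_cv[[st]]))
      f <- 1 - exp(-(c_eff * plots$measured_population[i])^canopy$overlap_exponent)

      tb <- if (plots$tillage[i] %in% names(canopy$tillage_brightness))
        canopy$tillage_brightness[[plots$tillage[i]]] else 1
      sb <- tb
      if (canopy$soil_brightness_cv > 0)
        sb <- sb * exp(rnorm(1, 0, canopy$soil_brightness_cv))
      shape <- if (canopy$soil_shape_sd > 0)
        1 + drop(bumps %*% rnorm(6, 0, canopy$soil_shape_sd)) else 1
      soil_i <- pmin(pmax(canopy$soil * sb * shape, 0), 1)
      cn <- if (plots$cultivar[i] %in% names(canopy$cultivar_nir))
        canopy$cultivar_nir[[plots$cultivar[i]]] else 1
      veg_i <- pmin(canopy$veg * (1 + (cn - 1) * plogis((wl - 720) / 20)), 1)

      truth[i, ] <- f * veg_i + (1 - f) * soil_i
      cover[i] <- f
      illum <- illum_by_condition[[plots$condition[i]]]
      wcv <- canopy$within_plot_cover_cv[[st]]

      for (row in seq_len(design$rows_per_plot)) {
        for (s in seq_len(design$samples_per_row)) {
          seq_counter <- seq_counter + 1L
          f_seq <- if (wcv > 0)
            min(1, f * exp(rnorm(1, 0, wcv) - wcv^2 / 2)) else f
          refl <- f_seq * veg_i + (1 - f_seq) * soil_i
          seq_list[[seq_counter]] <- simulate_sequence(
            refl, illum, sensor,
            seed = derive_seed(design$seed, seq_counter),
            sequence_id = sprintf("%s_r%d_s%02d", plots$plot_id[i], row, s),
            plot_id = plots$plot_id[i], row_index = row,
            condition = plots$condition[i])
        }
      }
    }
  })

  plots$cover_truth <- cover
  structure(list(plots = plots, truth = truth, sequences = seq_list,
                 design = design, canopy = canopy, sensor = sensor,
                 illum_by_condition = illum_by_condition),
            class = "sim_trial")
}

#' Write measurement sequences to long-format CSV
#'
#' Columns: sequence_id, plot_id, row_index, frame (up_dark, up_target,
#' down_target, down_dark), integration_time_ms, wavelength_nm, counts.
#'
#' @param sequences list of [measurement_sequence()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sequences_csv <- function(sequences, path) {
  rows <- lapply(sequences, function(sq) {
    do.call(rbind, lapply(names(sq$frames), function(fn) {
      fr <- sq$frames[[fn]]
      data.frame(sequence_id = sq$sequence_id, plot_id = sq$plot_id,
                 row_index = sq$row_index, frame = fn,
                 integration_time_ms = fr$integration_time,
                 wavelength_nm = fr$wavelengths, counts = fr$counts)
    }))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read measurement sequences from long-format CSV
#'
#' Inverse of [write_sequences_csv()].
#'
#' @param path CSV path.
#' @return List of [measurement_sequence()] in file order.
#' @export
read_sequences_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sequence_id", "plot_id", "row_index", "frame",
            "integration_time_ms", "wavelength_nm", "counts")
  if (!all(need %in% names(d)))
    stop("sequence CSV missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  ids <- unique(d$sequence_id)
  lapply(ids, function(id) {
    di <- d[d$sequence_id == id, , drop = FALSE]
    frames <- lapply(split(di, di$frame), function(df) {
      df <- df[order(df$wavelength_nm), , drop = FALSE]
      raw_frame(channel = if (grepl("^up", df$frame[1])) "up" else "down",
                is_dark = grepl("dark", df$frame[1]),
                integration_time = df$integration_time_ms[1],
                wavelengths = df$wavelength_nm, counts = df$counts)
    })
    measurement_sequence(frames, sequence_id = id, plot_id = di$plot_id[1],
                         row_index = di$row_index[1])
  })
}

#' Write / read the plot-record table
#'
#' One row per plot record: design factors, measured population, condition,
#' stage, replicate (and ground-truth cover for synthetic trials).
#'
#' @param plots plot-record data.frame.
#' @param path CSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_plots_csv <- function(plots, path) {
  write.csv(plots, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plots_csv
#' @export
read_plots_csv <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Write a whole simulated trial to a directory
#'
#' Emits `sequences.csv` and `plots.csv` in the package's CSV dialects.
#'
#' @param trial a `sim_trial` from [generate_trial()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_trial_csv <- function(trial, dir) {
  stopifnot(inherits(trial, "sim_trial"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_sequences_csv(trial$sequences, file.path(dir, "sequences.csv"))
  write_plots_csv(trial$plots, file.path(dir, "plots.csv"))
  invisible(dir)
}
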