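# Radiometric correction: four-frame sequences -> relative reflectance,
# normalising for dark current, integration time and fibre throughput.
#
# Committed reflectance equation (the instrument reference equation is not
# reproduced in the accompanying description; this interpretation is the
# package's contract, with K as the escape hatch for any unquantified
# field-of-view geometry factor):
#
#   R(lambda) = K * [ (C_up - C_up,dark) / (t_up  * g_up ) ] /
#                   [ (C_dn - C_dn,dark) / (t_dn * g_dn) ]
#
# with g proportional to fibre cross-sectional area (diameter^2). Relative
# reflectance needs only consistency, not absolute calibration, so K = 1 by
# default.

#' Fibre throughput model
#'
#' Effective channel throughputs proportional to fibre cross-sectional area:
#' `g_down / g_up = (d_down / d_up)^2` unless overridden. `K` is a single
#' dimensionless system constant absorbing any field-of-view geometry factor
#' (cosine fore optic vs. bare fibre) that area alone does not capture.
#'
#' @param fiber_diameter_up,fiber_diameter_down fibre diameters in um.
#' @param throughput_ratio_override optional `g_down / g_up` replacing the
#'   area ratio.
#' @param K dimensionless system constant (default 1).
#' @return An object of class `throughput_model`.
#' @export
throughput_model <- function(fiber_diameter_up = 400,
                             fiber_diameter_down = 600,
                             throughput_ratio_override = NULL, K = 1) {
  stopifnot(fiber_diameter_up > 0, fiber_diameter_down > 0, K > 0)
  ratio <- throughput_ratio_override %||%
    (fiber_diameter_down / fiber_diameter_up)^2
  stopifnot(ratio > 0)
  structure(list(fiber_diameter_up = fiber_diameter_up,
                 fiber_diameter_down = fiber_diameter_down,
                 g_up = 1, g_down = ratio, K = K),
            class = "throughput_model")
}

#' Dark-current subtraction
#'
#' Elementwise `target - dark` for a matched pair of frames (same channel,
#' grid and integration time). Negative net counts are preserved — clamping
#' would bias low-signal bands — and bands more than 3 estimated dark sds
#' below zero are flagged.
#'
#' @param target,dark [raw_frame()]s; `dark` must be a dark frame.
#' @return Numeric net-counts vector with attribute `negative_flags`
#'   (indices of strongly negative bands).
#' @export
dark_subtract <- function(target, dark) {
  stopifnot(inherits(target, "raw_frame"), inherits(dark, "raw_frame"))
  if (!dark$is_dark || target$is_dark)
    stop("`target` must be a target frame and `dark` a dark frame",
         call. = FALSE)
  if (target$channel != dark$channel)
    stop("frame pairing error: channels differ", call. = FALSE)
  if (length(target$wavelengths) != length(dark$wavelengths) ||
      any(target$wavelengths != dark$wavelengths))
    stop("frame pairing error: wavelength grids differ", call. = FALSE)
  if (target$integration_time != dark$integration_time)
    stop("frame pairing error: integration times differ", call. = FALSE)
  net <- target$counts - dark$counts
  dark_sd_est <- mad(dark$counts)
  flags <- which(net < -3 * max(dark_sd_est, .Machine$double.eps))
  attr(net, "negative_flags") <- flags
  net
}

#' Relative reflectance of one measurement sequence
#'
#' Applies the committed reflectance equation (see [throughput_model()]):
#' dark-subtract each channel, normalise by integration time and fibre
#' throughput, ratio the channels, scale by `K`. The ratio cancels any joint
#' illumination change, which is the core of the dual field-of-view design.
#' Bands whose net downwelling signal is at or below `min_irradiance` counts
#' are set to `NA` and flagged `low_irradiance`; bands outside 400-900 nm are
#' flagged `edge` (noisy detector edges, trimmed later in preprocessing).
#'
#' @param seq a [measurement_sequence()]; all four frames required, none
#'   saturated.
#' @param tm a [throughput_model()].
#' @param min_irradiance net downwelling counts at or below which a band is
#'   treated as missing.
#' @return A `reflectance_spectrum`: list with `wavelengths`, `values`
#'   (NA where missing), provenance fields and `band_flags`.
#' @export
relative_reflectance <- function(seq, tm = throughput_model(),
                                 min_irradiance = 1) {
  stopifnot(inherits(seq, "measurement_sequence"),
            inherits(tm, "throughput_model"))
  fr <- seq$frames
  if (any(vapply(fr, function(f) isTRUE(f$saturated), logical(1))))
    stop("saturated frame: sequence cannot be reduced to reflectance",
         call. = FALSE)
  up_net <- dark_subtract(fr$up_target, fr$up_dark)
  down_net <- dark_subtract(fr$down_target, fr$down_dark)
  wl <- fr$up_target$wavelengths

  up_norm <- up_net / (fr$up_target$integration_time * tm$g_up)
  down_norm <- down_net / (fr$down_target$integration_time * tm$g_down)
  bad <- down_net <= min_irradiance
  if (all(bad))
    stop("degenerate sequence: no usable downwelling signal on any band",
         call. = FALSE)
  values <- as.vector(tm$K * up_norm / down_norm)
  values[bad] <- NA_real_

  structure(list(
    wavelengths = wl, values = values,
    sequence_id = seq$sequence_id, plot_id = seq$plot_id,
    condition = seq$condition,
    band_flags = list(
      low_irradiance = which(bad),
      negative_net_up = attr(up_net, "negative_flags"),
      negative_net_down = attr(down_net, "negative_flags"),
      edge = which(wl < 400 | wl > 900))
  ), class = "reflectance_spectrum")
}

#' Quality-control limits for sequence screening
#'
#' @param it_up_range,it_down_range acceptable integration-time ranges (ms).
#' @param max_median_reflectance median relative reflectance above which the
#'   up/down pairing is implausible (operator error).
#' @param max_negative_frac maximum tolerated fraction of bands with negative
#'   net downwelling signal.
#' @return A list of limits.
#' @export
qc_limits <- function(it_up_range = c(13, 15), it_down_range = c(4, 6),
                      max_median_reflectance = 2,
                      max_negative_frac = 0.10) {
  list(it_up_range = it_up_range, it_down_range = it_down_range,
       max_median_reflectance = max_median_reflectance,
       max_negative_frac = max_negative_frac)
}

#' Screen one measurement sequence
#'
#' Deterministic pass/fail with flags: fails on any saturated frame
#' (`"saturated"`), on negative net irradiance over more than
#' `max_negative_frac` of bands (`"negative_irradiance"`), on integration
#' times outside the configured ranges (`"integration_time"`), and on a
#' median relative reflectance above `max_median_reflectance`
#' (`"implausible_ratio"`, e.g. the upwelling frame duplicated as
#' downwelling).
#'
#' @param seq a [measurement_sequence()].
#' @param tm a [throughput_model()] (for the plausibility ratio).
#' @param limits a [qc_limits()].
#' @return List with `pass` (logical) and `flags` (character).
#' @export
sequence_qc <- function(seq, tm = throughput_model(), limits = qc_limits()) {
  stopifnot(inherits(seq, "measurement_sequence"))
  flags <- character()
  fr <- seq$frames
  if (any(vapply(fr, function(f) isTRUE(f$saturated), logical(1))))
    flags <- c(flags, "saturated")
  in_range <- function(x, r) x >= r[1] & x <= r[2]
  if (!in_range(fr$up_target$integration_time, limits$it_up_range) ||
      !in_range(fr$down_target$integration_time, limits$it_down_range))
    flags <- c(flags, "integration_time")
  if (!"saturated" %in% flags) {
    down_net <- fr$down_target$counts - fr$down_dark$counts
    if (mean(down_net < 0) > limits$max_negative_frac)
      flags <- c(flags, "negative_irradiance")
    r <- tryCatch(relative_reflectance(seq, tm), error = function(e) NULL)
    if (is.null(r)) {
      flags <- c(flags, "degenerate")
    } else if (median(r$values, na.rm = TRUE) > limits$max_median_reflectance) {
      flags <- c(flags, "implausible_ratio")
    }
  }
  list(pass = length(flags) == 0L, flags = flags)
}

#' Reduce many sequences to a reflectance matrix
#'
#' Runs [sequence_qc()] and [relative_reflectance()] over a list of
#' sequences, returning a sequences x bands matrix on the native grid plus
#' per-sequence metadata. QC-failing sequences keep their metadata but carry
#' `NA` spectra and `qc_pass = FALSE`.
#'
#' @param sequences list of [measurement_sequence()].
#' @param tm a [throughput_model()].
#' @param min_irradiance see [relative_reflectance()].
#' @param limits see [sequence_qc()].
#' @return List with `values` (matrix, rows = sequences), `wavelengths`, and
#'   `meta` (data.frame: sequence_id, plot_id, row_index, condition, qc_pass,
#'   qc_flags).
#' @export
process_sequences <- function(sequences, tm = throughput_model(),
                              min_irradiance = 1, limits = qc_limits()) {
  stopifnot(length(sequences) >= 1L)
  wl <- sequences[[1L]]$frames$up_target$wavelengths
  n <- length(sequences)
  values <- matrix(NA_real_, n, length(wl))
  meta <- data.frame(sequence_id = character(n), plot_id = character(n),
                     row_index = integer(n), condition = character(n),
                     qc_pass = logical(n), qc_flags = character(n),
                     stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    sq <- sequences[[i]]
    qc <- sequence_qc(sq, tm, limits)
    meta$sequence_id[i] <- sq$sequence_id
    meta$plot_id[i] <- sq$plot_id
    meta$row_index[i] <- sq$row_index
    meta$condition[i] <- sq$condition
    meta$qc_pass[i] <- qc$pass
    meta$qc_flags[i] <- paste(qc$flags, collapse = ";")
    if (qc$pass)
      values[i, ] <- relative_reflectance(sq, tm, min_irradiance)$values
  }
  list(values = values, wavelengths = wl, meta = meta)
}
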