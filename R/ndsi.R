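# Normalized difference spectral index (NDSI) screening: exhaustive two-band
# search against measured plant population, with ranking and a single-pair
# prediction model. "Quality of correlation" is committed as the r-squared of
# an ordinary least squares fit of population on NDSI; ranking by |r| would
# order pairs identically.

#' NDSI value for one band pair
#'
#' `(R_i - R_j) / (R_i + R_j)`. Antisymmetric under band swap; in \[-1, 1\]
#' whenever both reflectances are nonnegative. Missing when the denominator
#' is at or below `eps`.
#'
#' @param values spectrum values on the analysis grid, or a plots x bands
#'   matrix.
#' @param wavelengths analysis-grid wavelengths matching the columns.
#' @param band_i,band_j band wavelengths in nm (must be on the grid and
#'   distinct).
#' @param eps denominator threshold below which the value is missing.
#' @return NDSI value(s); `NA` where the denominator is degenerate.
#' @export
ndsi_value <- function(values, wavelengths, band_i, band_j, eps = 1e-6) {
  if (band_i == band_j)
    stop("`band_i` and `band_j` must differ", call. = FALSE)
  ii <- match(band_i, wavelengths)
  jj <- match(band_j, wavelengths)
  if (is.na(ii) || is.na(jj))
    stop("band off the analysis grid", call. = FALSE)
  if (is.matrix(values)) {
    ri <- values[, ii]; rj <- values[, jj]
  } else {
    ri <- values[ii]; rj <- values[jj]
  }
  den <- ri + rj
  out <- unname((ri - rj) / den)
  out[!is.finite(den) | abs(den) <= eps] <- NA_real_
  out
}

# Masked per-column simple OLS of y on each column of N (NAs allowed in N).
ols_columns <- function(N, y) {
  ok <- !is.na(N) & is.finite(y)
  N0 <- N; N0[!ok] <- 0
  y0 <- ifelse(is.finite(y), y, 0)
  nk <- colSums(ok)
  xm <- colSums(N0) / nk
  ym <- colSums(ok * y0) / nk
  sxx <- colSums(N0^2) - nk * xm^2
  sxy <- colSums(N0 * y0) - nk * xm * ym
  syy <- colSums(ok * y0^2) - nk * ym^2
  degenerate <- !(sxx > 1e-12 * pmax(1, abs(xm))^2) | syy <= 0
  slope <- ifelse(degenerate, NA_real_, sxy / sxx)
  r2 <- ifelse(degenerate, 0, sxy^2 / (sxx * syy))
  rss <- pmax(0, syy - ifelse(degenerate, 0, sxy^2 / sxx))
  list(slope = slope, intercept = ym - slope * xm,
       r_squared = pmin(pmax(r2, 0), 1),
       rmse = sqrt(rss / nk), n_used = nk, degenerate = degenerate)
}

#' Exhaustive NDSI band-pair screen
#'
#' Evaluates every canonical pair (band_i < band_j) on the 101-band analysis
#' grid — 5050 pairs — regressing measured population on the pair's NDSI by
#' ordinary least squares. Results are sorted by r-squared (descending), ties
#' broken by smaller band_i then smaller band_j, and ranked densely. Pairs
#' with a constant NDSI get r-squared 0 and a `degenerate` flag; pairs with
#' more than `max_missing` of plots missing are excluded from ranking
#' (rank `NA`).
#'
#' @param spectra plots x bands matrix with analysis wavelengths as column
#'   names (or supply `wavelengths`).
#' @param populations measured plant population per plot, plants x 10^4 / ha.
#' @param wavelengths band wavelengths (default from column names).
#' @param max_missing maximum tolerated missing fraction per pair.
#' @param eps NDSI denominator threshold.
#' @return data.frame sorted by rank: band_i, band_j, r_squared, slope,
#'   intercept, rmse, n_used, missing_frac, degenerate, rank.
#' @export
scan_ndsi <- function(spectra, populations,
                      wavelengths = as.numeric(colnames(spectra)),
                      max_missing = 0.2, eps = 1e-6) {
  spectra <- as.matrix(spectra)
  n <- nrow(spectra)
  if (n < 3L)
    stop("need at least 3 plots for the NDSI screen", call. = FALSE)
  if (length(populations) != n)
    stop("`populations` must match the spectra rows", call. = FALSE)
  if (any(!is.finite(populations)))
    stop("`populations` must be finite", call. = FALSE)
  if (anyNA(wavelengths))
    stop("band wavelengths unavailable: set column names or `wavelengths`",
         call. = FALSE)

  pr <- combn(length(wavelengths), 2L)
  Ri <- spectra[, pr[1L, ], drop = FALSE]
  Rj <- spectra[, pr[2L, ], drop = FALSE]
  den <- Ri + Rj
  N <- (Ri - Rj) / den
  N[!is.finite(den) | abs(den) <= eps] <- NA_real_

  fit <- ols_columns(N, populations)
  res <- data.frame(band_i = wavelengths[pr[1L, ]],
                    band_j = wavelengths[pr[2L, ]],
                    r_squared = fit$r_squared, slope = fit$slope,
                    intercept = fit$intercept, rmse = fit$rmse,
                    n_used = fit$n_used,
                    missing_frac = 1 - fit$n_used / n,
                    degenerate = fit$degenerate)
  res <- res[order(-res$r_squared, res$band_i, res$band_j), , drop = FALSE]
  rownames(res) <- NULL
  eligible <- res$missing_frac <= max_missing
  res$rank <- NA_integer_
  res$rank[eligible] <- seq_len(sum(eligible))
  res
}

#' Rank of a band pair in a scan
#'
#' @param scan result of [scan_ndsi()].
#' @param pair length-2 wavelengths; order-insensitive.
#' @return The pair's rank (NA if excluded or absent).
#' @export
pair_rank <- function(scan, pair) {
  pair <- sort(pair)
  hit <- scan$band_i == pair[1] & scan$band_j == pair[2]
  if (!any(hit)) return(NA_integer_)
  scan$rank[hit][1L]
}

#' Top-k membership frequency of a band pair across datasets
#'
#' Counts in how many scanned datasets the pair ranks within the top `k`.
#'
#' @param scans nonempty list of [scan_ndsi()] results.
#' @param pair length-2 band wavelengths (order-insensitive).
#' @param k top-list size.
#' @return List with `count` and the per-dataset `ranks`.
#' @export
top_pair_frequency <- function(scans, pair = c(565, 710), k = 10L) {
  if (length(scans) < 1L)
    stop("need at least one scanned dataset", call. = FALSE)
  ranks <- vapply(scans, pair_rank, integer(1), pair = pair)
  list(count = sum(!is.na(ranks) & ranks <= k), ranks = ranks, k = k)
}

#' Single-pair NDSI prediction model
#'
#' Ordinary least squares of population on the pair's NDSI. Predict with
#' [predict.ndsi_model()]; evaluate held-out predictions with
#' [regression_metrics()].
#'
#' @param spectra training plots x bands matrix (analysis grid).
#' @param populations training populations.
#' @param pair length-2 band wavelengths.
#' @param wavelengths band wavelengths (default from column names).
#' @param eps NDSI denominator threshold.
#' @return An object of class `ndsi_model` with `slope`, `intercept`,
#'   `pair`, and training `r_squared`/`rmse`.
#' @export
fit_ndsi_model <- function(spectra, populations,
                           pair = c(565, 710),
                           wavelengths = as.numeric(colnames(spectra)),
                           eps = 1e-6) {
  spectra <- as.matrix(spectra)
  x <- ndsi_value(spectra, wavelengths, pair[1], pair[2], eps)
  ok <- !is.na(x) & is.finite(populations)
  if (sum(ok) < 3L)
    stop("need at least 3 usable training plots", call. = FALSE)
  fit <- ols_columns(matrix(x[ok], ncol = 1L), populations[ok])
  if (fit$degenerate)
    stop("degenerate NDSI: constant across training plots", call. = FALSE)
  structure(list(pair = pair, slope = fit$slope, intercept = fit$intercept,
                 r_squared = fit$r_squared, rmse = fit$rmse,
                 wavelengths = wavelengths, eps = eps),
            class = "ndsi_model")
}

#' @describeIn fit_ndsi_model Predict population for new spectra.
#' @param object an `ndsi_model`.
#' @param newdata plots x bands matrix on the same analysis grid.
#' @param ... unused.
#' @export
predict.ndsi_model <- function(object, newdata, ...) {
  x <- ndsi_value(as.matrix(newdata), object$wavelengths,
                  object$pair[1], object$pair[2], object$eps)
  object$intercept + object$slope * x
}
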