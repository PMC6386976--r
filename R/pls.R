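# PLS1 regression (NIPALS). Latent directions maximise covariance between
# X-scores and y; with as many components as the centred X has rank, the
# predictions coincide with ordinary least squares.

#' Fit a partial least squares regression (single response)
#'
#' NIPALS PLS1: components are extracted by deflation, each weight vector
#' proportional to the covariance of the current X residual with the y
#' residual. Coefficient vectors for every truncation 1..`ncomp` are kept, so
#' one fit serves all candidate model sizes during component selection. If
#' the residual signal is exhausted before `ncomp` components (rank
#' deficiency), the model is truncated with a warning.
#'
#' @param X n x p predictor matrix (reflectance spectra).
#' @param y length-n response (plant population).
#' @param ncomp number of latent components requested.
#' @param tol relative tolerance declaring the residual exhausted.
#' @return An object of class `pls_model`: `ncomp` (components actually
#'   fitted), `x_mean`, `y_mean`, `weights` (W), `loadings` (P), `q`
#'   (y-loadings), `coef` (p x ncomp matrix; column a = coefficients of the
#'   a-component model).
#' @export
fit_pls <- function(X, y, ncomp, tol = 1e-12) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("`X` rows and `y` length differ", call. = FALSE)
  if (anyNA(X) || anyNA(y))
    stop("missing values: impute before fitting", call. = FALSE)
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L) stop("`ncomp` must be >= 1", call. = FALSE)
  a_max <- min(ncomp, n - 1L, p)
  if (a_max < 1L) stop("not enough samples to fit any component", call. = FALSE)

  xm <- colMeans(X); ym <- mean(y)
  Xr <- sweep(X, 2L, xm)
  yr <- y - ym
  y_scale <- sqrt(sum(yr^2))
  W <- P <- matrix(0, p, a_max)
  Q <- numeric(a_max)
  a_used <- 0L
  for (a in seq_len(a_max)) {
    w <- crossprod(Xr, yr)[, 1L]
    nw <- sqrt(sum(w^2))
    if (nw <= tol * max(1, y_scale)) break
    w <- w / nw
    t_a <- Xr %*% w
    tt <- sum(t_a^2)
    if (tt <= tol) break
    p_a <- crossprod(Xr, t_a)[, 1L] / tt
    q_a <- sum(yr * t_a) / tt
    Xr <- Xr - tcrossprod(t_a, p_a)
    yr <- yr - q_a * t_a
    W[, a] <- w; P[, a] <- p_a; Q[a] <- q_a
    a_used <- a
  }
  if (a_used < 1L)
    stop("no usable signal: y is constant or X has no variance", call. = FALSE)
  if (a_used < ncomp)
    warning(sprintf("rank deficiency: fitted %d of %d requested components",
                    a_used, ncomp), call. = FALSE)
  W <- W[, seq_len(a_used), drop = FALSE]
  P <- P[, seq_len(a_used), drop = FALSE]
  Q <- Q[seq_len(a_used)]
  Rw <- W %*% solve(crossprod(P, W))        # X-space rotation
  coef <- vapply(seq_len(a_used),
                 function(a) drop(Rw[, seq_len(a), drop = FALSE] %*%
                                    Q[seq_len(a)]),
                 numeric(p))
  coef <- matrix(coef, nrow = p)
  structure(list(ncomp = a_used, x_mean = xm, y_mean = ym,
                 weights = W, loadings = P, q = Q, coef = coef),
            class = "pls_model")
}

#' Predict from a PLS model
#'
#' @param object a `pls_model`.
#' @param newdata m x p matrix on the training band grid.
#' @param ncomp number of components to use (default: all fitted).
#' @param ... unused.
#' @return Length-m vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, ncomp = object$ncomp, ...) {
  newdata <- rbind(as.matrix(newdata))
  if (ncol(newdata) != length(object$x_mean))
    stop("`newdata` band count differs from the training matrix", call. = FALSE)
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L || ncomp > object$ncomp)
    stop("`ncomp` outside the fitted range", call. = FALSE)
  drop(sweep(newdata, 2L, object$x_mean) %*% object$coef[, ncomp]) +
    object$y_mean
}

#' Select the number of PLS components on a held-out split
#'
#' Fits up to `max_components` on the calibration split and picks the
#' component count minimising RMSE on the cross-validation split; ties break
#' to the smallest count (`which.min`), so a noise-free one-component signal
#' selects one component. Deterministic.
#'
#' @param X_cal,y_cal calibration split.
#' @param X_cv,y_cv cross-validation split.
#' @param max_components largest candidate count.
#' @return Integer component count, with the per-candidate RMSE curve as
#'   attribute `cv_rmse`.
#' @export
select_ncomp <- function(X_cal, y_cal, X_cv, y_cv, max_components = 15L) {
  if (max_components < 1L)
    stop("`max_components` must be >= 1", call. = FALSE)
  X_cv <- rbind(as.matrix(X_cv))
  if (nrow(X_cv) < 1L || length(y_cal) < 2L)
    stop("both splits must be nonempty", call. = FALSE)
  fit <- suppressWarnings(fit_pls(X_cal, y_cal, max_components))
  pred <- sweep(X_cv, 2L, fit$x_mean) %*% fit$coef + fit$y_mean
  rmse <- sqrt(colMeans((pred - y_cv)^2))
  # smallest count whose RMSE is within numerical noise of the minimum
  tol <- 1e-8 * max(rmse[1L], 1e-8)
  sel <- which(rmse <= min(rmse) + tol)[1L]
  structure(as.integer(sel), cv_rmse = rmse)
}

# Column-mean imputation learned on a training fold and applied elsewhere.
impute_fit <- function(X) {
  mns <- colMeans(X, na.rm = TRUE)
  mns[!is.finite(mns)] <- 0
  mns
}
impute_apply <- function(X, means) {
  X <- as.matrix(X)
  nas <- which(is.na(X), arr.ind = TRUE)
  if (nrow(nas)) X[nas] <- means[nas[, 2L]]
  X
}
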