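# Resampled PLSR ensemble: per iteration, a random 75/25 split into a
# calibration+cross-validation pool and a validation hold-out; within the
# pool a further 75/25 cal/cv split drives component selection; the model is
# refit on the full pool at the selected size and predicts the hold-out.
# Per-sample predictions are averaged over the iterations in which the
# sample was held out, and the averaged estimates are regressed against the
# measured values for the reported R2/RMSE.

#' R-squared and RMSE of predictions against measurements
#'
#' `r_squared` is the squared Pearson correlation of the ordinary
#' least-squares fit of predicted on measured (estimated and measured values
#' "regressed" against each other); `rmse` is
#' `sqrt(mean((predicted - measured)^2))` in population units
#' (plants x 10^4 / ha). A constant offset therefore leaves r-squared at 1
#' while inflating RMSE.
#'
#' @param measured,predicted equal-length finite vectors (length >= 2).
#' @return List with `r_squared` (NA with a warning if either vector has
#'   zero variance) and `rmse`.
#' @export
regression_metrics <- function(measured, predicted) {
  if (length(measured) != length(predicted))
    stop("`measured` and `predicted` lengths differ", call. = FALSE)
  ok <- is.finite(measured) & is.finite(predicted)
  measured <- measured[ok]; predicted <- predicted[ok]
  if (length(measured) < 2L)
    stop("need at least 2 finite pairs", call. = FALSE)
  r2 <- if (sd(measured) == 0 || sd(predicted) == 0) {
    warning("zero variance: r_squared undefined", call. = FALSE)
    NA_real_
  } else cor(measured, predicted)^2
  list(r_squared = r2, rmse = sqrt(mean((predicted - measured)^2)))
}

# Accumulate role-wise prediction sums for aggregated metrics.
acc_new <- function(n) list(sum = numeric(n), sumsq = numeric(n),
                            count = integer(n))
acc_add <- function(acc, idx, pred) {
  acc$sum[idx] <- acc$sum[idx] + pred
  acc$sumsq[idx] <- acc$sumsq[idx] + pred^2
  acc$count[idx] <- acc$count[idx] + 1L
  acc
}
acc_metrics <- function(acc, y) {
  has <- acc$count > 0L
  if (sum(has) < 2L) return(list(r_squared = NA_real_, rmse = NA_real_))
  regression_metrics(y[has], acc$sum[has] / acc$count[has])
}

#' Resampled calibration / cross-validation / validation ensemble
#'
#' Runs `iterations` PLSR fits under the resampling topology described above
#' (`topology = "per-iteration"`); `topology = "fixed-validation"` instead
#' draws the 25 percent validation set once and only reshuffles the cal/cv
#' split. `refit = "pool"` refits the selected model on the full cal+cv pool
#' before predicting validation samples; `refit = "cal"` predicts straight
#' from the calibration fit. Per-iteration seeds derive from `seed` by a
#' counter, so any single iteration is reproducible in isolation. Missing
#' predictor entries are mean-imputed within each training fold.
#'
#' @param X n x p spectra matrix (rownames used as plot ids if `ids` absent).
#' @param y measured populations, length n.
#' @param iterations number of resampling iterations.
#' @param holdout_fraction validation fraction per iteration.
#' @param cal_fraction calibration share of the cal+cv pool.
#' @param seed master seed.
#' @param ids optional plot identifiers.
#' @param topology `"per-iteration"` or `"fixed-validation"`.
#' @param refit `"pool"` or `"cal"`.
#' @param max_components component-selection cap.
#' @return An object of class `ensemble_result`: `per_sample` (plot_id,
#'   measured, mean_predicted, sd_predicted, n_times_held_out), `metrics`
#'   (`calibration` / `cross_validation` / `validation`, each r_squared +
#'   rmse from aggregated per-sample means), `per_iteration` (n_components
#'   and per-split metrics per iteration), and the run descriptors.
#' @export
run_ensemble <- function(X, y, iterations = 100L, holdout_fraction = 0.25,
                         cal_fraction = 0.75, seed = 1L, ids = NULL,
                         topology = c("per-iteration", "fixed-validation"),
                         refit = c("pool", "cal"), max_components = 15L) {
  topology <- match.arg(topology)
  refit <- match.arg(refit)
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stop("`X` rows and `y` length differ", call. = FALSE)
  if (n < 12L)
    stop("need at least 12 samples for the three-way split", call. = FALSE)
  if (iterations < 1L) stop("`iterations` must be >= 1", call. = FALSE)
  ids <- ids %||% rownames(X) %||% as.character(seq_len(n))

  n_val <- max(1L, round(n * holdout_fraction))
  val_acc <- acc_new(n); cal_acc <- acc_new(n); cv_acc <- acc_new(n)
  fixed_val <- if (topology == "fixed-validation")
    local_seed(derive_seed(seed, 0L), sort(sample.int(n, n_val)))
  per_iter <- vector("list", iterations)

  for (t in seq_len(iterations)) {
    st <- local_seed(derive_seed(seed, t), {
      val <- if (topology == "per-iteration") sort(sample.int(n, n_val))
             else fixed_val
      pool <- setdiff(seq_len(n), val)
      n_cv <- max(1L, round(length(pool) * (1 - cal_fraction)))
      cv <- sort(sample(pool, n_cv))
      list(val = val, pool = pool, cv = cv, cal = setdiff(pool, cv))
    })
    mns <- impute_fit(X[st$cal, , drop = FALSE])
    Xc <- impute_apply(X[st$cal, , drop = FALSE], mns)
    Xv <- impute_apply(X[st$cv, , drop = FALSE], mns)
    a <- select_ncomp(Xc, y[st$cal], Xv, y[st$cv],
                      min(max_components, length(st$cal) - 1L, ncol(X)))
    cal_fit <- suppressWarnings(fit_pls(Xc, y[st$cal], a))
    a_cal <- min(a, cal_fit$ncomp)
    model <- if (refit == "pool") {
      mns_p <- impute_fit(X[st$pool, , drop = FALSE])
      Xp <- impute_apply(X[st$pool, , drop = FALSE], mns_p)
      fitp <- suppressWarnings(fit_pls(Xp, y[st$pool], a))
      mns <- mns_p
      fitp
    } else cal_fit
    a_use <- min(a, model$ncomp)

    pred_val <- predict(model, impute_apply(X[st$val, , drop = FALSE], mns),
                        ncomp = a_use)
    pred_cal <- predict(cal_fit,
                        impute_apply(X[st$cal, , drop = FALSE],
                                     impute_fit(X[st$cal, , drop = FALSE])),
                        ncomp = a_cal)
    pred_cv <- predict(cal_fit, Xv, ncomp = a_cal)

    val_acc <- acc_add(val_acc, st$val, pred_val)
    cal_acc <- acc_add(cal_acc, st$cal, pred_cal)
    cv_acc <- acc_add(cv_acc, st$cv, pred_cv)
    mi <- function(idx, pred) unlist(regression_metrics(y[idx], pred))
    per_iter[[t]] <- c(iteration = t, n_components = a_use,
                       cal = mi(st$cal, pred_cal), cv = mi(st$cv, pred_cv),
                       val = mi(st$val, pred_val))
  }

  never <- val_acc$count == 0L
  if (any(never))
    warning(sprintf("%d sample(s) never held out; reported as missing",
                    sum(never)), call. = FALSE)
  mean_pred <- ifelse(never, NA_real_, val_acc$sum / pmax(val_acc$count, 1L))
  var_pred <- pmax(0, val_acc$sumsq / pmax(val_acc$count, 1L) - mean_pred^2)
  sd_pred <- ifelse(val_acc$count > 1L,
                    sqrt(var_pred * val_acc$count / (val_acc$count - 1L)),
                    0)
  sd_pred[never] <- NA_real_

  structure(list(
    per_sample = data.frame(plot_id = ids, measured = y,
                            mean_predicted = mean_pred,
                            sd_predicted = sd_pred,
                            n_times_held_out = val_acc$count,
                            stringsAsFactors = FALSE),
    metrics = list(calibration = acc_metrics(cal_acc, y),
                   cross_validation = acc_metrics(cv_acc, y),
                   validation = acc_metrics(val_acc, y)),
    per_iteration = as.data.frame(do.call(rbind, per_iter)),
    n_iterations = as.integer(iterations), seed = seed,
    topology = topology, refit = refit,
    holdout_fraction = holdout_fraction, cal_fraction = cal_fraction
  ), class = "ensemble_result")
}

#' Cross-condition validation
#'
#' Trains the resampling ensemble wholly on one plot set (internal 75/25
#' cal/cv reshuffles drive component selection; the model is refit on all
#' training plots) and predicts every plot of a disjoint test set each
#' iteration — e.g. calibrate under sunny skies, validate under cloudy, and
#' vice versa.
#'
#' @param X_train,y_train training spectra and populations.
#' @param X_test,y_test test spectra and populations.
#' @param train_ids,test_ids plot identifiers; must be disjoint.
#' @param iterations,seed,cal_fraction,max_components as in
#'   [run_ensemble()].
#' @return List with `metrics` (aggregated test r_squared/rmse),
#'   `per_sample` (test-set mean/sd predictions), `n_components` used per
#'   iteration.
#' @export
cross_condition_validate <- function(X_train, y_train, X_test, y_test,
                                     train_ids = rownames(X_train),
                                     test_ids = rownames(X_test),
                                     iterations = 100L, seed = 1L,
                                     cal_fraction = 0.75,
                                     max_components = 15L) {
  X_train <- as.matrix(X_train); X_test <- as.matrix(X_test)
  if (is.null(train_ids) || is.null(test_ids))
    stop("plot identifiers required to verify disjointness", call. = FALSE)
  if (length(intersect(train_ids, test_ids)) > 0L)
    stop("train and test plot sets overlap", call. = FALSE)
  n <- nrow(X_train)
  if (n < 8L) stop("training set too small", call. = FALSE)
  m <- nrow(X_test)
  acc <- acc_new(m)
  ncomps <- integer(iterations)
  for (t in seq_len(iterations)) {
    cv <- local_seed(derive_seed(seed, t),
                     sort(sample.int(n, max(1L, round(n * (1 - cal_fraction))))))
    cal <- setdiff(seq_len(n), cv)
    mns <- impute_fit(X_train[cal, , drop = FALSE])
    a <- select_ncomp(impute_apply(X_train[cal, , drop = FALSE], mns),
                      y_train[cal],
                      impute_apply(X_train[cv, , drop = FALSE], mns),
                      y_train[cv],
                      min(max_components, length(cal) - 1L, ncol(X_train)))
    mns_all <- impute_fit(X_train)
    model <- suppressWarnings(fit_pls(impute_apply(X_train, mns_all),
                                      y_train, a))
    ncomps[t] <- min(a, model$ncomp)
    acc <- acc_add(acc, seq_len(m),
                   predict(model, impute_apply(X_test, mns_all),
                           ncomp = ncomps[t]))
  }
  mean_pred <- acc$sum / acc$count
  list(metrics = regression_metrics(y_test, mean_pred),
       per_sample = data.frame(plot_id = test_ids, measured = y_test,
                               mean_predicted = mean_pred,
                               stringsAsFactors = FALSE),
       n_components = ncomps, seed = seed)
}
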