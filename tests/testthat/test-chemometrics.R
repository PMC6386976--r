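# PLS1 core, component selection, the resampling ensemble, metrics.

ols_predict <- function(X, y, Xnew) {
  A <- cbind(1, X)
  drop(cbind(1, Xnew) %*% solve(crossprod(A), crossprod(A, y)))
}

test_that("one component captures a single-direction signal exactly", {
  set.seed(1)
  scores <- rnorm(30)
  X <- outer(scores, rnorm(6))       # rank-one spectra
  y <- 3 + 2 * X[, 4]
  fit <- fit_pls(X, y, 1)
  expect_equal(unname(predict(fit, X)), y, tolerance = 1e-8)
  expect_equal(regression_metrics(y, predict(fit, X))$r_squared, 1,
               tolerance = 1e-10)
})

test_that("full-rank PLS reproduces OLS predictions (normal-equations oracle)", {
  for (i in 1:10) {
    set.seed(100 + i)
    X <- matrix(rnorm(30 * 8), 30)
    y <- rnorm(30)
    fit <- fit_pls(X, y, 8)
    expect_lt(max(abs(predict(fit, X) - ols_predict(X, y, X))), 1e-8)
  }
})

test_that("PLS predictions agree with an independent implementation", {
  set.seed(7)
  X <- matrix(rnorm(40 * 12), 40, dimnames = list(NULL, paste0("b", 1:12)))
  y <- rnorm(40)
  fit <- fit_pls(X, y, 5)
  m <- suppressMessages(mixOmics::pls(X, y, ncomp = 5, mode = "regression",
                                      scale = FALSE))
  for (a in 1:5)
    expect_equal(unname(predict(fit, X, ncomp = a)),
                 unname(predict(m, X)$predict[, 1, a]), tolerance = 1e-10)
})

test_that("sample order does not affect the fit", {
  set.seed(2)
  X <- matrix(rnorm(25 * 7), 25)
  y <- rnorm(25)
  perm <- sample(25)
  f1 <- fit_pls(X, y, 4)
  f2 <- fit_pls(X[perm, ], y[perm], 4)
  expect_equal(f1$coef, f2$coef, tolerance = 1e-12)
  expect_equal(f1$y_mean, f2$y_mean, tolerance = 1e-12)
})

test_that("duplicated bands split coefficients without changing predictions", {
  set.seed(3)
  X <- matrix(rnorm(30 * 5), 30)
  y <- 1 + X %*% rnorm(5) + rnorm(30, 0, 0.1)
  Xdup <- cbind(X, X[, 2])
  f <- suppressWarnings(fit_pls(Xdup, y, 6))
  expect_equal(unname(predict(f, Xdup)),
               ols_predict(X, y, X), tolerance = 1e-6)
})

test_that("rank deficiency truncates the model with a warning", {
  set.seed(4)
  X <- matrix(rnorm(10 * 3), 10)
  X <- cbind(X, X)  # rank 3 at most
  y <- rnorm(10)
  expect_warning(fit <- fit_pls(X, y, 6), "rank")
  expect_lte(fit$ncomp, 3L)
})

test_that("a noise-free single-direction signal selects one component", {
  set.seed(5)
  # centred orthonormal predictors: the signal lives in exactly one direction
  Q <- qr.Q(qr(scale(matrix(rnorm(40 * 10), 40), scale = FALSE)))
  y <- 2 * Q[, 1]
  a <- select_ncomp(Q, y, Q[1:10, ], y[1:10], max_components = 8)
  expect_equal(as.integer(a), 1L)
  expect_lt(min(attr(a, "cv_rmse")), 1e-10)
})

test_that("a planted multi-component signal is selected near its true size", {
  hits <- 0L
  for (s in 1:10) {
    set.seed(400 + s)
    n <- 150
    scores <- matrix(rnorm(n * 3), n)
    load <- matrix(rnorm(3 * 20), 3)
    X <- scores %*% load + matrix(rnorm(n * 20, 0, 0.3), n)
    y <- scores %*% c(3, -2, 1) + rnorm(n, 0, 0.5)
    cal <- 1:110
    a <- select_ncomp(X[cal, ], y[cal], X[-cal, ], y[-cal], 10)
    if (abs(as.integer(a) - 3L) <= 1L) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("pure-noise responses keep the model small", {
  set.seed(6)
  X <- matrix(rnorm(60 * 15), 60)
  y <- rnorm(60)
  a <- select_ncomp(X[1:45, ], y[1:45], X[46:60, ], y[46:60], 10)
  expect_lte(as.integer(a), 3L)
})

test_that("metrics distinguish correlation from error magnitude", {
  expect_equal(regression_metrics(1:10, 1:10),
               list(r_squared = 1, rmse = 0))
  off <- regression_metrics(1:10, 1:10 + 2)
  expect_equal(off$r_squared, 1)
  expect_equal(off$rmse, 2)
  hand <- regression_metrics(c(10, 20, 30), c(12, 18, 33))
  expect_equal(hand$rmse, sqrt((4 + 4 + 9) / 3), tolerance = 1e-12)
  expect_warning(z <- regression_metrics(c(1, 1, 1), c(1, 2, 3)),
                 "zero variance")
  expect_true(is.na(z$r_squared))
})

test_that("a noise-free linear response gives a perfect ensemble", {
  set.seed(8)
  X <- matrix(rnorm(60 * 8), 60)
  y <- drop(5 + X %*% c(1, -2, 0.5, 0, 0, 1, 0, 0))
  ens <- run_ensemble(X, y, iterations = 20, seed = 3)
  expect_equal(ens$metrics$validation$r_squared, 1, tolerance = 1e-6)
  expect_lt(ens$metrics$validation$rmse, 1e-6)
  expect_lt(max(ens$per_sample$sd_predicted, na.rm = TRUE), 1e-6)
})

test_that("the ensemble is seed-deterministic and stable across seeds", {
  set.seed(9)
  n <- 224
  X <- matrix(rnorm(n * 12), n)
  y <- drop(X %*% rnorm(12)) + rnorm(n, 0, 1.5)
  e1 <- run_ensemble(X, y, iterations = 40, seed = 77)
  e2 <- run_ensemble(X, y, iterations = 40, seed = 77)
  expect_identical(e1, e2)
  e3 <- run_ensemble(X, y, iterations = 40, seed = 78)
  expect_lt(abs(e1$metrics$validation$r_squared -
                  e3$metrics$validation$r_squared), 0.05)
})

test_that("hold-out counts match the binomial expectation", {
  set.seed(10)
  n <- 224
  X <- matrix(rnorm(n * 6), n)
  y <- drop(X %*% rnorm(6)) + rnorm(n)
  ens <- run_ensemble(X, y, iterations = 100, seed = 5)
  counts <- ens$per_sample$n_times_held_out
  expect_equal(sum(counts), 100L * round(0.25 * n))
  expect_gte(mean(counts), 22)
  expect_lte(mean(counts), 28)
})

test_that("the fixed-validation topology holds out one constant set", {
  set.seed(11)
  X <- matrix(rnorm(40 * 5), 40)
  y <- drop(X %*% rnorm(5)) + rnorm(40, 0, 0.2)
  # pool samples are never held out under this topology; the ensemble
  # reports them as missing, which is the designed behaviour
  expect_warning(
    ens <- run_ensemble(X, y, iterations = 15, seed = 2,
                        topology = "fixed-validation"),
    "never held out")
  counts <- ens$per_sample$n_times_held_out
  expect_true(all(counts %in% c(0L, 15L)))
  expect_equal(sum(counts == 15L), 10L)  # round(0.25 * 40)
})

test_that("cross-condition validation rejects overlapping plot sets", {
  X <- matrix(rnorm(40 * 5), 40, dimnames = list(paste0("p", 1:40), NULL))
  y <- rnorm(40)
  expect_error(
    cross_condition_validate(X[1:20, ], y[1:20], X[15:40, ], y[15:40]),
    "overlap")
})

test_that("ensemble preconditions are enforced", {
  X <- matrix(rnorm(10 * 4), 10)
  expect_error(run_ensemble(X, rnorm(10)), "at least 12")
  expect_error(select_ncomp(X, rnorm(10), X, rnorm(10), 0), "max_components")
})
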