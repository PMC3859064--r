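test_that("single-band PLS reduces to simple least squares", {
  set.seed(21)
  x <- runif(15, 0.2, 0.8)
  y <- 3 + 5 * x + rnorm(15, 0, 0.1)
  fit <- fit_plsr(matrix(x, ncol = 1), y, n_lv = 1)
  ols <- lm(y ~ x)
  expect_equal(fit$beta, unname(coef(ols)[2]), tolerance = 1e-10)
  expect_equal(fit$intercept, unname(coef(ols)[1]), tolerance = 1e-10)
})

test_that("full-component PLS equals the pseudo-inverse solution", {
  set.seed(22)
  X <- matrix(rnorm(40), 10, 4)
  y <- X %*% c(1, -2, 0.5, 3) + rnorm(10, 0, 0.2)
  fit <- fit_plsr(X, y, n_lv = 4)
  Xc <- cbind(1, X)
  beta_ols <- MASS::ginv(Xc) %*% y
  expect_equal(predict(fit, X), as.vector(Xc %*% beta_ols), tolerance = 1e-8)
})

test_that("noiseless rank-1 structure is recovered with one component", {
  set.seed(23)
  d <- runif(6)                                  # single latent direction
  t_ <- rnorm(12)
  X <- outer(t_, d)
  y <- 2 + 3 * t_
  fit <- fit_plsr(X, y, n_lv = 1)
  expect_lt(max(abs(predict(fit, X) - y)), 1e-8)
})

test_that("prediction is affine and matches the score-space route", {
  set.seed(24)
  X <- matrix(rnorm(60, 5, 2), 15, 4)
  y <- X %*% c(1, 0, -1, 2) + rnorm(15, 0, 0.3)
  fit <- fit_plsr(X, y, n_lv = 3)
  expect_equal(predict(fit, X), as.vector(X %*% fit$beta) + fit$intercept)
  expect_equal(predict(fit, rep(0, 4)), fit$intercept)
  Xnew <- matrix(rnorm(20, 5, 2), 5, 4)
  for (a in 1:3)
    expect_equal(predict(fit, Xnew, n_lv = a),
                 hsimoist:::.predict_via_scores(fit, Xnew, n_lv = a),
                 tolerance = 1e-10)
  expect_error(predict(fit, Xnew[, 1:3]), "band count")
})

test_that("partial-component predictions match an independent PLS implementation", {
  set.seed(25)
  X <- matrix(rnorm(80), 20, 4)
  colnames(X) <- paste0("b", 1:4)
  y <- matrix(X %*% c(2, -1, 0.5, 1) + rnorm(20, 0, 0.3), ncol = 1)
  fit <- fit_plsr(X, as.vector(y), n_lv = 2)
  ext <- mixOmics::pls(X, y, ncomp = 2, scale = FALSE, mode = "regression")
  Xn <- matrix(rnorm(12), 3, 4, dimnames = list(NULL, colnames(X)))
  pext <- predict(ext, Xn)$predict[, 1, 2]
  expect_equal(predict(fit, Xn, n_lv = 2), unname(pext), tolerance = 1e-8)
})

test_that("scores are orthogonal and calibration error shrinks with components", {
  set.seed(26)
  X <- matrix(rnorm(200), 20, 10)
  y <- X %*% rnorm(10) + rnorm(20, 0, 0.5)
  fit <- fit_plsr(X, y, n_lv = 8)
  G <- crossprod(fit$scores)
  off <- max(abs(G[upper.tri(G)]))
  expect_lt(off, 1e-8 * max(diag(G)))
  rmse <- vapply(1:8, function(a) sqrt(mean((y - predict(fit, X, n_lv = a))^2)), 0)
  expect_true(all(diff(rmse) <= 1e-10))
  expect_error(fit_plsr(X, y, n_lv = 25), "n_lv")
  expect_error(fit_plsr(X, rep(1, 20), n_lv = 2), "zero variance")
})

test_that("leave-one-out CV equals a naive per-fold refit", {
  tx <- toy_spectra(n = 12, seed = 27)
  max_lv <- 6
  for (m in c("raw", "snv", "msc")) {
    cv <- loo_cv(tx$X, tx$y, max_lv, method = m, wavelengths = tx$wl)
    naive <- matrix(NA_real_, 12, max_lv)
    for (i in 1:12) {
      pf <- preprocess_fit(tx$X[-i, ], m, tx$wl)
      xte <- preprocess_apply(pf$state, tx$X[i, , drop = FALSE])
      for (a in 1:max_lv) {
        f <- fit_plsr(pf$X, tx$y[-i], n_lv = a)
        naive[i, a] <- predict(f, xte, n_lv = min(a, f$n_lv))
      }
    }
    expect_equal(cv$predictions, naive, tolerance = 1e-12, info = m)
    expect_equal(cv$rmse_by_lv, sqrt(colMeans((tx$y - naive)^2)),
                 tolerance = 1e-12, info = m)
    expect_equal(cv$chosen_lv, which.min(cv$rmse_by_lv))
  }
})

test_that("three-sample leave-one-out matches the closed-form one-component fit", {
  X <- matrix(c(0.2, 0.5, 0.9,
                0.4, 0.3, 0.7), 3, 2)
  y <- c(66, 69, 72)
  cv <- loo_cv(X, y, max_lv = 1, method = "raw")
  want <- vapply(1:3, function(i) pls1_one_lv(X[-i, ], y[-i], X[i, ]), 0)
  expect_equal(as.vector(cv$predictions), want, tolerance = 1e-10)
  expect_equal(cv$rmse_by_lv, sqrt(mean((y - want)^2)), tolerance = 1e-10)
})

test_that("CV on a noiseless linear response selects one component", {
  set.seed(28)
  t_ <- runif(12)
  X <- outer(t_, runif(5))
  y <- 60 + 10 * t_
  cv <- loo_cv(X, y, max_lv = 3, method = "raw")
  expect_lt(cv$rmse_by_lv[1], 1e-6)
  expect_equal(cv$chosen_lv, 1L)
  expect_error(loo_cv(X, y, max_lv = 11), "max_lv")
})

test_that("report metrics match their definitions", {
  tx <- toy_spectra(n = 20, seed = 29)
  cal <- 1:14; tst <- 15:20
  cv <- loo_cv(tx$X[cal, ], tx$y[cal], 3, "snv", tx$wl)
  pf <- preprocess_fit(tx$X[cal, ], "snv", tx$wl)
  fit <- fit_plsr(pf$X, tx$y[cal], cv$chosen_lv, preprocess_state = pf$state)
  rep_ <- evaluate_model(fit, tx$X[cal, ], tx$y[cal], cv,
                         tx$X[tst, ], tx$y[tst])
  yhat_c <- predict(fit, preprocess_apply(pf$state, tx$X[cal, ]))
  expect_equal(rep_$sec, sqrt(mean((tx$y[cal] - yhat_c)^2)))
  expect_equal(rep_$r2_c,
               1 - sum((tx$y[cal] - yhat_c)^2) /
                   sum((tx$y[cal] - mean(tx$y[cal]))^2))
  expect_equal(rep_$sev, cv$rmse_by_lv[fit$n_lv])
  expect_error(evaluate_model(fit, tx$X[cal, ], tx$y[cal], cv,
                              tx$X[0, , drop = FALSE], numeric(0)),
               "empty test set")
})

test_that("a perfect predictor scores R2 = 1 and a constant scores R2 = 0", {
  y <- c(66, 68, 70, 72)
  r2 <- function(y, yh) 1 - sum((y - yh)^2) / sum((y - mean(y))^2)
  expect_equal(r2(y, y), 1)
  expect_equal(r2(y, rep(mean(y), 4)), 0)
})

test_that("method comparison isolates failures and is seed-deterministic", {
  tx <- toy_spectra(n = 24, seed = 31)
  X <- tx$X
  X[, 3] <- 0.5                     # constant band; harmless for row methods
  sel1 <- select_model(X, tx$y, tx$wl, methods = c("raw", "snv", "msc"),
                       max_lv = 4, n_train = 18, seed = 5)
  expect_equal(nrow(sel1$report), 3)
  expect_true(all(is.finite(sel1$report$sev)))
  sel2 <- select_model(X, tx$y, tx$wl, methods = c("raw", "snv", "msc"),
                       max_lv = 4, n_train = 18, seed = 5)
  expect_identical(sel1$report, sel2$report)
  # a method that errors is flagged NA while others complete
  Xbad <- tx$X; Xbad[2, ] <- 0.5    # constant spectrum kills SNV
  expect_warning(
    sel3 <- select_model(Xbad, tx$y, tx$wl, methods = c("snv", "raw"),
                         max_lv = 4, n_train = 18, seed = 5),
    "snv")
  expect_true(is.na(sel3$report$sev[sel3$report$method == "snv"]))
  expect_true(is.finite(sel3$report$sev[sel3$report$method == "raw"]))
})

test_that("the split is reproducible and leaves the RNG state alone", {
  s1 <- split_samples(72, 52, 9)
  s2 <- split_samples(72, 52, 9)
  expect_identical(s1, s2)
  expect_equal(length(s1), 52)
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(split_samples(10, 5, 3)); b <- runif(1)
  expect_identical(a, b)
})

test_that("a saved model file restores an identical predictor", {
  tx <- toy_spectra(n = 16, seed = 32)
  pf <- preprocess_fit(tx$X, "msc", tx$wl)
  fit <- fit_plsr(pf$X, tx$y, n_lv = 3, preprocess_state = pf$state,
                  wavelengths = tx$wl)
  f <- file.path(tempdir(), "model.json")
  write_plsr_model(fit, f)
  back <- read_plsr_model(f)
  Xnew <- tx$X[1:4, ]
  expect_equal(predict(back, preprocess_apply(back$preprocess_state, Xnew)),
               predict(fit, preprocess_apply(fit$preprocess_state, Xnew)),
               tolerance = 1e-12)
  expect_equal(back$wavelengths, fit$wavelengths)
  expect_equal(back$preprocess_state$msc_reference,
               fit$preprocess_state$msc_reference, tolerance = 1e-12)
  writeLines("{\"format\": \"other\"}", f)
  expect_error(read_plsr_model(f), "not an hsimoist")
})
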