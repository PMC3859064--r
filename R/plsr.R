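#' NIPALS partial least squares regression (PLS1)
#'
#' Fits a univariate-response PLS regression by the NIPALS algorithm: the
#' centered spectral matrix X is decomposed into orthogonal score vectors T
#' and loadings P (X = T P' + E) while the centered response is regressed on
#' the scores (y = T q + f). Components ("latent variables") are extracted by
#' X-deflation; for a scalar response the weight vector of each component is
#' X'y normalized, which maximizes covariance between score and response.
#' Columns are mean-centered, not variance-scaled (set `scale = TRUE` to
#' autoscale).
#'
#' The model carries the regression vector for every component count
#' 1..`n_lv` (`beta_path`), so cross-validation can read predictions for all
#' component counts from one fit.
#'
#' @param X numeric matrix `[n x p]` of (already preprocessed) spectra.
#' @param y numeric response vector, length `n`.
#' @param n_lv number of latent variables, `1 <= n_lv <= min(n - 1, p)`.
#' @param scale logical; autoscale columns to unit variance (default FALSE).
#' @param preprocess_state optional `preprocess_state` recorded for later
#'   application to new spectra.
#' @param wavelengths optional band wavelengths (nm) recorded in the model.
#' @return An object of class `plsr_model` with weights `W`, X-loadings `P`,
#'   y-loadings `q`, scores `T` and `U`, centering terms, `beta`/`intercept`
#'   for `n_lv` components, and `beta_path`/`intercept_path` for 1..`n_lv`.
#' @export
fit_plsr <- function(X, y, n_lv, scale = FALSE,
                     preprocess_state = NULL, wavelengths = NULL) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) does not match nrow(X)")
  if (stats::var(y) == 0) stop("response has zero variance")
  n_lv <- as.integer(n_lv)
  if (n_lv < 1 || n_lv > min(n - 1, p))
    stop(sprintf("n_lv must be in [1, %d]", min(n - 1, p)))

  x_mean <- colMeans(X)
  x_scale <- if (scale) apply(X, 2, stats::sd) else rep(1, p)
  if (any(x_scale == 0)) stop("zero-variance column with scale = TRUE")
  y_mean <- mean(y)
  Xc <- sweep(sweep(X, 2, x_mean), 2, x_scale, "/")
  yc <- y - y_mean

  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv)
  Tm <- matrix(0, n, n_lv); U <- matrix(0, n, n_lv)
  q <- numeric(n_lv)
  used <- 0L
  tol <- 1e-12 * sqrt(sum((crossprod(Xc, yc))^2))
  for (a in seq_len(n_lv)) {
    w <- as.vector(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (!is.finite(nw) || nw <= tol) break       # X residual carries no covariance
    w <- w / nw
    t_ <- as.vector(Xc %*% w)
    tt <- sum(t_^2)
    if (tt <= .Machine$double.eps) break
    p_ <- as.vector(crossprod(Xc, t_)) / tt
    q[a] <- sum(yc * t_) / tt
    W[, a] <- w; P[, a] <- p_; Tm[, a] <- t_; U[, a] <- yc
    Xc <- Xc - tcrossprod(t_, p_)
    yc <- yc - q[a] * t_
    used <- a
  }
  if (used == 0L) stop("no extractable latent variable (X'y is zero)")

  # beta for each component count: B_a = W_a (P_a' W_a)^{-1} q_a
  beta_path <- matrix(0, p, n_lv)
  PW <- crossprod(P[, seq_len(used), drop = FALSE],
                  W[, seq_len(used), drop = FALSE])
  for (a in seq_len(used)) {
    b <- W[, seq_len(a), drop = FALSE] %*%
      solve(PW[seq_len(a), seq_len(a), drop = FALSE], q[seq_len(a)])
    beta_path[, a] <- as.vector(b) / x_scale
  }
  if (used < n_lv)                                # exhausted rank: later LVs add nothing
    beta_path[, (used + 1L):n_lv] <- beta_path[, used]
  intercept_path <- y_mean - as.vector(x_mean %*% beta_path)

  structure(list(
    n_lv = n_lv, n_lv_used = used,
    W = W[, seq_len(used), drop = FALSE], P = P[, seq_len(used), drop = FALSE],
    q = q[seq_len(used)],
    scores = Tm[, seq_len(used), drop = FALSE],
    u_scores = U[, seq_len(used), drop = FALSE],
    x_mean = x_mean, x_scale = x_scale, y_mean = y_mean,
    beta = beta_path[, n_lv], intercept = intercept_path[n_lv],
    beta_path = beta_path, intercept_path = intercept_path,
    preprocess_state = preprocess_state, wavelengths = wavelengths),
    class = "plsr_model")
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> %d latent variable(s), %d band(s)%s\n",
              x$n_lv, length(x$beta),
              if (!is.null(x$preprocess_state))
                paste0(", preprocess = ", x$preprocess_state$method) else ""))
  invisible(x)
}

#' Predict from a fitted PLS regression
#'
#' Affine prediction `X beta + intercept`. `newdata` must already carry the
#' model's preprocessing (see [preprocess_apply]); band count must match.
#'
#' @param object a `plsr_model`.
#' @param newdata matrix `[m x p]` (or a single spectrum vector).
#' @param n_lv component count to predict with (default: the fitted count).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.plsr_model <- function(object, newdata, n_lv = object$n_lv, ...) {
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$beta))
    stop(sprintf("band count (%d) does not match model (%d)",
                 ncol(newdata), length(object$beta)))
  n_lv <- as.integer(n_lv)
  if (n_lv < 1 || n_lv > object$n_lv) stop("invalid n_lv")
  as.vector(newdata %*% object$beta_path[, n_lv]) + object$intercept_path[n_lv]
}

# algebraically equivalent prediction through the score space:
# T_new = (X - x_mean) W (P'W)^{-1}, yhat = y_mean + T_new q
.predict_via_scores <- function(object, newdata, n_lv = object$n_lv) {
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1)
  a <- min(n_lv, object$n_lv_used)
  Xc <- sweep(sweep(as.matrix(newdata), 2, object$x_mean), 2, object$x_scale, "/")
  W <- object$W[, seq_len(a), drop = FALSE]
  P <- object$P[, seq_len(a), drop = FALSE]
  R <- W %*% solve(crossprod(P, W))
  Tn <- Xc %*% R
  object$y_mean + as.vector(Tn %*% object$q[seq_len(a)])
}

#' Leave-one-out cross-validation with latent-variable selection
#'
#' For each left-out sample the preprocessing state and the PLS model are
#' refit on the remaining n - 1 samples (the MSC reference is recomputed per
#' fold, so no information leaks from the held-out spectrum), and the sample
#' is predicted with every component count 1..`max_lv`. The root mean square
#' error over the n held-out predictions,
#' \deqn{RMSE_a = \sqrt{\frac{1}{n}\sum_i (y_i - \hat y_i^{(a)})^2},}
#' is reported per component count and the chosen count is the first
#' minimum (ties broken toward fewer components).
#'
#' @param X matrix `[n x p]` of raw (untransformed) spectra.
#' @param y response vector.
#' @param max_lv maximum component count, `<= n - 2`.
#' @param method preprocessing tag (see [PREPROCESS_METHODS]).
#' @param wavelengths band wavelengths (nm), for the derivative spacing.
#' @param sg_window,sg_polyorder Savitzky-Golay settings.
#' @return An object of class `cv_result`: `rmse_by_lv`, `chosen_lv`
#'   (lowest RMSE, ties toward fewer components), `chosen_lv_1se` (smallest
#'   count within one standard error of the minimum CV MSE), and the
#'   `[n x max_lv]` matrix of held-out `predictions`.
#' @export
loo_cv <- function(X, y, max_lv, method = "raw", wavelengths = NULL,
                   sg_window = 11L, sg_polyorder = 2L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3) stop("leave-one-out CV needs at least 3 samples")
  max_lv <- as.integer(max_lv)
  if (max_lv > n - 2) stop("max_lv must be <= n - 2")
  preds <- matrix(NA_real_, n, max_lv)
  for (i in seq_len(n)) {
    y_tr <- y[-i]
    if (stats::var(y_tr) == 0) stop("degenerate fold: constant response")
    pf <- preprocess_fit(X[-i, , drop = FALSE], method, wavelengths,
                         sg_window, sg_polyorder)
    x_te <- preprocess_apply(pf$state, X[i, , drop = FALSE])
    fit <- fit_plsr(pf$X, y_tr, n_lv = min(max_lv, min(n - 2, ncol(X))))
    for (a in seq_len(max_lv)) {
      aa <- min(a, fit$n_lv)
      preds[i, a] <- predict(fit, x_te, n_lv = aa)
    }
  }
  sqerr <- (y - preds)^2
  rmse <- sqrt(colMeans(sqerr))
  chosen <- which.min(rmse)
  # parsimonious alternative: smallest count whose CV MSE is within one
  # standard error of the minimum (used for pixel-wise mapping, where extra
  # components amplify per-pixel noise)
  mse <- colMeans(sqerr)
  se_min <- stats::sd(sqerr[, chosen]) / sqrt(n)
  chosen_1se <- which(mse <= mse[chosen] + se_min)[1]
  structure(list(rmse_by_lv = rmse, chosen_lv = chosen,
                 chosen_lv_1se = chosen_1se,
                 predictions = preds, method = method),
            class = "cv_result")
}

#' Calibration / validation / prediction metrics
#'
#' Computes the standard chemometric report: coefficient of determination
#' `R^2 = 1 - SS_res / SS_tot` and root-mean-square residual on the
#' calibration set (SEC), on the cross-validated predictions (SEV), and on
#' the independent test set (SEP). Spectra are passed untransformed; the
#' model's stored preprocessing is applied.
#'
#' @param model a `plsr_model` with a `preprocess_state`.
#' @param X_cal,y_cal calibration spectra and responses (raw spectra).
#' @param cv a `cv_result` from [loo_cv] on the calibration set.
#' @param X_test,y_test held-out test spectra and responses.
#' @return A one-row `data.frame`: method, n_lv, r2_c, sec, r2_v, sev,
#'   r2_p, sep.
#' @export
evaluate_model <- function(model, X_cal, y_cal, cv, X_test, y_test) {
  if (is.null(nrow(X_test)) || nrow(as.matrix(X_test)) == 0 ||
      length(y_test) == 0) stop("empty test set")
  st <- model$preprocess_state
  tr <- function(M) if (is.null(st)) as.matrix(M) else preprocess_apply(st, M)
  yhat_c <- predict(model, tr(X_cal))
  yhat_p <- predict(model, tr(X_test))
  yhat_v <- cv$predictions[, model$n_lv]
  r2 <- function(y, yh) 1 - sum((y - yh)^2) / sum((y - mean(y))^2)
  rms <- function(y, yh) sqrt(mean((y - yh)^2))
  data.frame(
    method = if (!is.null(st)) st$method else "raw",
    n_lv = model$n_lv,
    r2_c = r2(y_cal, yhat_c), sec = rms(y_cal, yhat_c),
    r2_v = r2(y_cal, yhat_v), sev = rms(y_cal, yhat_v),
    r2_p = r2(y_test, yhat_p), sep = rms(y_test, yhat_p),
    stringsAsFactors = FALSE)
}

#' Compare preprocessing methods and select the best model
#'
#' Runs the full protocol for each preprocessing tag: seeded random split
#' into calibration and test sets, leave-one-out CV on the calibration set to
#' choose the component count (lowest RMSE), refit at that count, and the
#' calibration/validation/prediction report. The winning model is the one
#' with the lowest SEV — a validation-set criterion, so the test set never
#' informs selection. A method that errors (e.g. SNV on a constant spectrum)
#' is flagged with an NA row; the others complete.
#'
#' @param X matrix `[n x p]` of raw mean sample spectra.
#' @param y response vector (moisture %).
#' @param wavelengths band wavelengths (nm).
#' @param methods preprocessing tags to compare.
#' @param max_lv maximum latent variables for CV.
#' @param n_train calibration-set size (remainder is the test set).
#' @param seed integer seed for the split.
#' @param sg_window,sg_polyorder Savitzky-Golay settings.
#' @return List: `report` (one row per method), `best_method`, `best_model`
#'   (a `plsr_model`), `models` and `cv` per method, and `split`
#'   (calibration indices).
#' @export
select_model <- function(X, y, wavelengths = NULL,
                         methods = PREPROCESS_METHODS, max_lv = 20L,
                         n_train = 52L, seed = 1L,
                         sg_window = 11L, sg_polyorder = 2L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n_train >= n) stop("n_train must leave a non-empty test set")
  idx <- split_samples(n, n_train, seed)
  X_cal <- X[idx, , drop = FALSE]; y_cal <- y[idx]
  X_test <- X[-idx, , drop = FALSE]; y_test <- y[-idx]
  max_lv <- min(as.integer(max_lv), n_train - 2L, ncol(X))
  rows <- list(); cvs <- list(); models <- list()
  for (m in methods) {
    res <- tryCatch({
      cv <- loo_cv(X_cal, y_cal, max_lv, m, wavelengths, sg_window, sg_polyorder)
      pf <- preprocess_fit(X_cal, m, wavelengths, sg_window, sg_polyorder)
      fit <- fit_plsr(pf$X, y_cal, n_lv = cv$chosen_lv,
                      preprocess_state = pf$state, wavelengths = wavelengths)
      list(cv = cv, fit = fit,
           row = evaluate_model(fit, X_cal, y_cal, cv, X_test, y_test))
    }, error = function(e) {
      warning(sprintf("method '%s' failed: %s", m, conditionMessage(e)))
      list(cv = NULL, fit = NULL,
           row = data.frame(method = m, n_lv = NA_integer_, r2_c = NA_real_,
                            sec = NA_real_, r2_v = NA_real_, sev = NA_real_,
                            r2_p = NA_real_, sep = NA_real_,
                            stringsAsFactors = FALSE))
    })
    rows[[m]] <- res$row; cvs[[m]] <- res$cv; models[[m]] <- res$fit
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  ok <- which(is.finite(report$sev))
  if (length(ok) == 0) stop("all preprocessing methods failed")
  best <- ok[which.min(report$sev[ok])]
  list(report = report, best_method = report$method[best],
       best_model = models[[report$method[best]]], models = models, cv = cvs,
       split = idx)
}

#' Seeded calibration/test split
#'
#' Draws `n_train` of `n` indices uniformly without replacement under a
#' local RNG seed; the caller's RNG state is untouched.
#'
#' @param n total sample count.
#' @param n_train calibration-set size.
#' @param seed integer seed.
#' @return Sorted calibration indices.
#' @export
split_samples <- function(n, n_train, seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sort(sample.int(n, n_train))
}
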