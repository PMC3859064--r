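#' Save a fitted PLS regression model to a self-describing file
#'
#' Serializes everything needed to predict on new spectra — regression
#' vector, intercept, centering terms, wavelengths, component count, and the
#' preprocessing state (including the MSC reference when present) — as a
#' single JSON document with full numeric precision.
#'
#' @param model a `plsr_model`.
#' @param path output file path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
write_plsr_model <- function(model, path) {
  stopifnot(inherits(model, "plsr_model"))
  st <- model$preprocess_state
  doc <- list(
    format = "hsimoist-plsr", format_version = 1L,
    package_version = as.character(utils::packageVersion("hsimoist")),
    n_lv = model$n_lv,
    beta = model$beta, intercept = model$intercept,
    x_mean = model$x_mean, x_scale = model$x_scale, y_mean = model$y_mean,
    wavelengths = model$wavelengths,
    preprocess = if (is.null(st)) NULL else list(
      method = st$method, msc_reference = st$msc_reference,
      sg_window = st$sg_window, sg_polyorder = st$sg_polyorder,
      sg_deriv = st$sg_deriv, delta = st$delta, n_bands = st$n_bands))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a PLS regression model saved by [write_plsr_model]
#'
#' The restored model predicts identically to the original (`beta` route);
#' score-space internals are not serialized.
#'
#' @param path file written by [write_plsr_model].
#' @return A `plsr_model`.
#' @export
read_plsr_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "hsimoist-plsr"))
    stop("not an hsimoist PLSR model file: ", path)
  st <- NULL
  if (!is.null(doc$preprocess)) {
    p <- doc$preprocess
    st <- structure(list(method = p$method,
                         msc_reference = p$msc_reference,
                         sg_window = as.integer(p$sg_window),
                         sg_polyorder = as.integer(p$sg_polyorder),
                         sg_deriv = as.integer(p$sg_deriv),
                         delta = p$delta, n_bands = as.integer(p$n_bands)),
                    class = "preprocess_state")
  }
  structure(list(
    n_lv = as.integer(doc$n_lv), n_lv_used = as.integer(doc$n_lv),
    x_mean = doc$x_mean, x_scale = doc$x_scale, y_mean = doc$y_mean,
    beta = doc$beta, intercept = doc$intercept,
    beta_path = matrix(doc$beta, ncol = 1)[, rep(1, doc$n_lv), drop = FALSE],
    intercept_path = rep(doc$intercept, doc$n_lv),
    preprocess_state = st, wavelengths = doc$wavelengths),
    class = "plsr_model")
}
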