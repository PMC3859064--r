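#' Oven-drying moisture content
#'
#' Moisture percentage from the three weighings of the oven-drying protocol:
#' \deqn{Moisture (\%) = 100 (W_2 - W_3) / (W_2 - W_1)}
#' with \eqn{W_1} the dry pan, \eqn{W_2} pan + wet sample, \eqn{W_3}
#' pan + dried sample. Vectorized over samples.
#'
#' @param w1,w2,w3 weights in grams; `w2 > w1` and `w1 <= w3 <= w2`.
#' @return Moisture percentage(s) in \[0, 100\].
#' @export
moisture_percent <- function(w1, w2, w3) {
  if (any(w2 <= w1)) stop("w2 must exceed w1 (no wet sample mass)")
  if (any(w3 < w1 - 1e-12) || any(w3 > w2 + 1e-12))
    stop("w3 must lie in [w1, w2]")
  100 * (w2 - w3) / (w2 - w1)
}

#' Load and validate a moisture reference table
#'
#' Reads the per-sample reference CSV
#' (`sample_id,breast_id,slice_location,temperature_C,w1_g,w2_g,w3_g[,moisture_pct]`),
#' validates each row's weights, computes moisture from the weights when the
#' column is absent, and cross-checks a supplied moisture column against the
#' weights to 0.01 percentage points.
#'
#' @param path CSV path.
#' @return A `data.frame` with a validated `moisture_pct` column.
#' @export
load_reference_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "breast_id", "slice_location", "temperature_C",
           "w1_g", "w2_g", "w3_g")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("reference table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (!all(df$slice_location %in% c("central", "peripheral")))
    stop("slice_location must be 'central' or 'peripheral'")
  if (!all(df$temperature_C %in% c(50, 60, 70)))
    stop("temperature_C must be one of 50, 60, 70")
  for (i in seq_len(nrow(df))) {
    ok <- tryCatch({
      moisture_percent(df$w1_g[i], df$w2_g[i], df$w3_g[i]); TRUE
    }, error = function(e) conditionMessage(e))
    if (!isTRUE(ok))
      stop(sprintf("row %d (sample %s): %s", i, df$sample_id[i], ok))
  }
  m <- moisture_percent(df$w1_g, df$w2_g, df$w3_g)
  if ("moisture_pct" %in% names(df)) {
    off <- which(abs(df$moisture_pct - m) > 0.01)
    if (length(off))
      stop(sprintf("moisture_pct inconsistent with weights (>0.01) at row(s): %s",
                   paste(off, collapse = ", ")))
  }
  df$moisture_pct <- m
  df
}
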