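#' Read an ENVI hypercube
#'
#' Parses an ENVI text header (`.hdr`) and reads the companion binary cube.
#' Supports BSQ/BIL/BIP interleaves, little/big endian, and data types
#' 4 (float32), 5 (float64), and 12 (uint16). The header must carry a
#' `wavelength` list; its length must equal `bands`.
#'
#' @param header_path path to the `.hdr` file. The binary file is the same
#'   path without the `.hdr` suffix, or with `.img`/`.dat`/`.raw` appended to
#'   the stem, whichever exists.
#' @param kind cube kind to record; defaults to `"reflectance"` for float
#'   payloads and `"raw"` for uint16.
#' @return A [hypercube].
#' @export
read_envi <- function(header_path, kind = NULL) {
  if (!file.exists(header_path)) stop("header not found: ", header_path)
  hdr <- .parse_envi_header(header_path)
  for (key in c("samples", "lines", "bands", "data type", "interleave"))
    if (is.null(hdr[[key]])) stop("ENVI header missing key: ", key)
  if (is.null(hdr[["wavelength"]]))
    stop("ENVI header missing key: wavelength")
  ns <- as.integer(hdr$samples); nl <- as.integer(hdr$lines)
  nb <- as.integer(hdr$bands)
  wl <- as.numeric(hdr$wavelength)
  if (length(wl) != nb)
    stop(sprintf("header wavelength list (%d) does not match bands (%d)",
                 length(wl), nb))
  interleave <- tolower(hdr$interleave)
  if (!interleave %in% c("bsq", "bil", "bip"))
    stop("unsupported interleave: ", interleave)
  dtype <- as.integer(hdr[["data type"]])
  endian <- if (!is.null(hdr[["byte order"]]) && as.integer(hdr[["byte order"]]) == 1)
    "big" else "little"
  bin_path <- .envi_data_path(header_path, must_exist = TRUE)
  n <- ns * nl * nb
  sz <- file.info(bin_path)$size
  bytes <- switch(as.character(dtype), "4" = 4L, "5" = 8L, "12" = 2L,
                  stop("unsupported ENVI data type: ", dtype))
  if (sz != n * bytes)
    stop(sprintf("binary size (%d bytes) does not match header shape %d x %d x %d (expected %d bytes)",
                 sz, nl, ns, nb, n * bytes))
  con <- file(bin_path, "rb"); on.exit(close(con))
  v <- switch(as.character(dtype),
    "4"  = readBin(con, "numeric", n = n, size = 4L, endian = endian),
    "5"  = readBin(con, "numeric", n = n, size = 8L, endian = endian),
    "12" = as.numeric(readBin(con, "integer", n = n, size = 2L,
                              signed = FALSE, endian = endian)))
  # file order -> [row, col, band]; sample (col) varies fastest within a line
  a <- switch(interleave,
    bsq = aperm(array(v, dim = c(ns, nl, nb)), c(2, 1, 3)),
    bil = aperm(array(v, dim = c(ns, nb, nl)), c(3, 1, 2)),
    bip = aperm(array(v, dim = c(nb, ns, nl)), c(3, 2, 1)))
  if (is.null(kind)) kind <- if (dtype == 12L) "raw" else "reflectance"
  hypercube(a, wl, kind = kind)
}

#' Write an ENVI hypercube
#'
#' Writes the binary cube and a matching ENVI text header recording
#' samples/lines/bands, interleave, data type, byte order, and the
#' wavelength list (nm).
#'
#' @param cube a [hypercube].
#' @param header_path output `.hdr` path; the binary goes to the same path
#'   without the `.hdr` suffix.
#' @param interleave `"bsq"`, `"bil"`, or `"bip"`.
#' @param dtype ENVI data type code: 4 (float32, default), 5 (float64),
#'   or 12 (uint16).
#' @return `header_path`, invisibly.
#' @export
write_envi <- function(cube, header_path, interleave = c("bsq", "bil", "bip"),
                       dtype = 4L) {
  stopifnot(inherits(cube, "hypercube"))
  interleave <- match.arg(interleave)
  dtype <- as.integer(dtype)
  if (!dtype %in% c(4L, 5L, 12L)) stop("unsupported ENVI data type: ", dtype)
  d <- dim(cube$data)
  v <- switch(interleave,
    bsq = as.vector(aperm(cube$data, c(2, 1, 3))),
    bil = as.vector(aperm(cube$data, c(2, 3, 1))),
    bip = as.vector(aperm(cube$data, c(3, 2, 1))))
  bin_path <- .envi_data_path(header_path, must_exist = FALSE)
  con <- tryCatch(file(bin_path, "wb"), error = function(e)
    stop("cannot open for writing: ", bin_path))
  on.exit(close(con), add = TRUE)
  if (dtype == 12L) {
    if (any(v < 0 | v > 65535)) stop("values outside uint16 range")
    writeBin(as.integer(round(v)), con, size = 2L, endian = "little")
  } else {
    writeBin(as.numeric(v), con, size = if (dtype == 4L) 4L else 8L,
             endian = "little")
  }
  hdr <- c(
    "ENVI",
    "description = { hsimoist hypercube }",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", dtype),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    paste0("wavelength = { ",
           paste(format(cube$wavelengths, trim = TRUE, digits = 15,
                        scientific = FALSE), collapse = ", "),
           " }"))
  writeLines(hdr, header_path)
  invisible(header_path)
}

.envi_data_path <- function(header_path, must_exist) {
  stem <- sub("\\.hdr$", "", header_path, ignore.case = TRUE)
  if (identical(stem, header_path)) stem <- paste0(header_path, ".img")
  if (!must_exist) return(stem)
  cand <- c(stem, paste0(stem, c(".img", ".dat", ".raw")))
  hit <- cand[file.exists(cand) & cand != header_path]
  if (length(hit) == 0) stop("ENVI binary not found for header: ", header_path)
  hit[1]
}

# minimal ENVI header parser: `key = value` lines, `{ ... }` lists possibly
# spanning lines; keys lowercased
.parse_envi_header <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  out <- list()
  pos <- gregexpr("([a-zA-Z][a-zA-Z0-9 _]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)", txt, perl = TRUE)[[1]]
  if (pos[1] == -1) return(out)
  m <- regmatches(txt, gregexpr("([a-zA-Z][a-zA-Z0-9 _]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)", txt, perl = TRUE))[[1]]
  for (entry in m) {
    key <- tolower(trimws(sub("=.*$", "", entry)))
    val <- trimws(sub("^[^=]*=", "", entry))
    if (startsWith(val, "{")) {
      inner <- gsub("[{}]", "", val)
      parts <- trimws(strsplit(inner, ",")[[1]])
      parts <- parts[nzchar(parts)]
      num <- suppressWarnings(as.numeric(parts))
      out[[key]] <- if (!anyNA(num)) num else parts
    } else {
      out[[key]] <- val
    }
  }
  out
}
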