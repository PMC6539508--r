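#' @include AllClasses.R
NULL

# ENVI raster format: a plain-text .hdr describing an accompanying
# headerless binary. Fields used here: samples (cols), lines (rows), bands,
# data type, interleave (bsq/bil/bip), byte order, wavelength { ... }.
# Data type 4 = 32-bit float, 5 = 64-bit float.

#' Read an ENVI-format hyperspectral cube
#'
#' Parses the ENVI text header and reads the binary payload in any of the
#' three standard interleaves (BSQ, BIL, BIP). The header must carry a
#' `wavelength` list whose length equals `bands`.
#'
#' @param headerPath path to the `.hdr` file; the binary is looked up by
#'   dropping the extension (or from the header's companion file with the
#'   same stem).
#' @param rangeTag camera-range tag to attach, `"VNIR"` or `"SWIR"`;
#'   defaults to the header's `range tag` entry when present.
#' @param isCalibrated whether the values are reflectances; defaults to the
#'   header's `calibrated` entry when present, else `FALSE`.
#' @return A [HyperCube-class].
#' @seealso [writeENVI()]
#' @export
readENVI <- function(headerPath, rangeTag = NULL, isCalibrated = NULL) {
  hdr <- .parseEnviHeader(headerPath)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("ENVI header missing field(s): ", paste(miss, collapse = ", "))
  if (is.null(hdr[["wavelength"]]))
    stop("ENVI header has no wavelength field")

  rows <- as.integer(hdr[["lines"]])
  cols <- as.integer(hdr[["samples"]])
  bands <- as.integer(hdr[["bands"]])
  wl <- as.numeric(strsplit(hdr[["wavelength"]], ",")[[1L]])
  if (length(wl) != bands)
    stop("wavelength count (", length(wl), ") != bands (", bands, ")")

  dtype <- as.integer(hdr[["data type"]])
  size <- switch(as.character(dtype), "4" = 4L, "5" = 8L,
                 stop("unsupported ENVI data type ", dtype))
  endian <- if (!is.null(hdr[["byte order"]]) &&
                as.integer(hdr[["byte order"]]) == 1L) "big" else "little"

  binPath <- sub("\\.hdr$", "", headerPath)
  if (!file.exists(binPath)) binPath <- paste0(binPath, ".dat")
  if (!file.exists(binPath))
    stop("binary payload not found for ", headerPath)

  con <- file(binPath, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = rows * cols * bands, size = size,
                  endian = endian)
  if (length(vals) != rows * cols * bands)
    stop("binary payload truncated")

  interleave <- tolower(hdr[["interleave"]])
  # ENVI stores row-major within each line: sample (col) varies fastest.
  cube <- switch(interleave,
    bsq = aperm(array(vals, dim = c(cols, rows, bands)), c(2L, 1L, 3L)),
    bil = aperm(array(vals, dim = c(cols, bands, rows)), c(3L, 1L, 2L)),
    bip = aperm(array(vals, dim = c(bands, cols, rows)), c(3L, 2L, 1L)),
    stop("unsupported interleave ", interleave))

  if (is.null(rangeTag))
    rangeTag <- if (!is.null(hdr[["range tag"]])) hdr[["range tag"]] else "VNIR"
  if (is.null(isCalibrated))
    isCalibrated <- !is.null(hdr[["calibrated"]]) &&
      tolower(hdr[["calibrated"]]) == "true"
  px <- if (!is.null(hdr[["pixel size mm"]]))
    as.numeric(hdr[["pixel size mm"]]) else NA_real_

  hyperCube(cube, wl, rangeTag = rangeTag, pixelSizeMm = px,
            isCalibrated = isCalibrated)
}

#' Write a cube in ENVI format
#'
#' Emits `path.hdr` (text header including the wavelength list and the
#' package's `range tag` / `calibrated` bookkeeping entries) plus the
#' headerless binary at `path`, 64-bit little-endian floats.
#'
#' @param cube a [HyperCube-class].
#' @param path output stem; `.hdr` is appended for the header.
#' @param interleave `"bsq"`, `"bil"` or `"bip"`.
#' @return `path`, invisibly.
#' @seealso [readENVI()]
#' @export
writeENVI <- function(cube, path, interleave = c("bsq", "bil", "bip")) {
  stopifnot(is(cube, "HyperCube"))
  interleave <- match.arg(interleave)
  d <- dim(cube@data)

  hdr <- c(
    "ENVI",
    "file type = ENVI Standard",
    sprintf("samples = %d", d[2L]),
    sprintf("lines = %d", d[1L]),
    sprintf("bands = %d", d[3L]),
    "header offset = 0",
    "data type = 5",
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("range tag = %s", cube@rangeTag),
    sprintf("calibrated = %s", tolower(as.character(cube@isCalibrated))),
    if (!is.na(cube@pixelSizeMm))
      sprintf("pixel size mm = %g", cube@pixelSizeMm),
    sprintf("wavelength = {\n %s }",
            paste(format(cube@wavelengths, trim = TRUE, digits = 15),
                  collapse = ",\n "))
  )
  writeLines(hdr, paste0(path, ".hdr"))

  vals <- switch(interleave,
    bsq = as.vector(aperm(cube@data, c(2L, 1L, 3L))),
    bil = as.vector(aperm(cube@data, c(2L, 3L, 1L))),
    bip = as.vector(aperm(cube@data, c(3L, 2L, 1L))))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(vals), con, size = 8L, endian = "little")
  invisible(path)
}

# Parse an ENVI header into a named list of strings; brace-delimited lists
# (possibly multi-line) are flattened to comma-separated strings.
.parseEnviHeader <- function(headerPath) {
  if (!file.exists(headerPath)) stop("header not found: ", headerPath)
  txt <- paste(readLines(headerPath, warn = FALSE), collapse = "\n")
  if (!grepl("^\\s*ENVI", txt))
    stop(headerPath, " is not an ENVI header")
  body <- sub("^\\s*ENVI\\s*\n", "", txt)

  out <- list()
  # brace-delimited entries first (may span lines)
  m <- gregexpr("([a-zA-Z ][a-zA-Z0-9 ]*?)\\s*=\\s*\\{([^}]*)\\}", body)
  for (hit in regmatches(body, m)[[1L]]) {
    key <- tolower(trimws(sub("=.*$", "", hit)))
    val <- sub("^[^{]*\\{", "", hit)
    val <- sub("\\}\\s*$", "", val)
    out[[key]] <- gsub("\\s+", "", val)
  }
  body <- gsub("([a-zA-Z ][a-zA-Z0-9 ]*?)\\s*=\\s*\\{[^}]*\\}", "", body)
  for (line in strsplit(body, "\n")[[1L]]) {
    if (!grepl("=", line)) next
    key <- tolower(trimws(sub("=.*$", "", line)))
    val <- trimws(sub("^[^=]*=", "", line))
    if (nzchar(key)) out[[key]] <- val
  }
  out
}
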