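#' Write a hypercube as an ENVI raster + header pair
#'
#' Writes the binary raster to `path` and a text header to `paste0(path,
#' ".hdr")` with the fields `samples, lines, bands, data type, interleave,
#' byte order` and the wavelength list in nm.
#'
#' @param cube a [hypercube()].
#' @param path output path for the binary raster (header gets `.hdr`).
#' @param interleave one of `"bil"`, `"bip"`, `"bsq"`.
#' @param data_type ENVI data-type code: 4 (float32, default) or
#'   5 (float64).
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path, interleave = c("bil", "bip", "bsq"),
                       data_type = 4L) {
  interleave <- match.arg(interleave)
  if (!data_type %in% c(4L, 5L))
    stop("only data types 4 (float32) and 5 (float64) are written")
  d <- dim(cube$data)                      # lines, samples, bands
  perm <- switch(interleave,
                 bsq = c(2L, 1L, 3L),      # sample, line, band
                 bil = c(2L, 3L, 1L),      # sample, band, line
                 bip = c(3L, 2L, 1L))      # band, sample, line
  vals <- as.vector(aperm(cube$data, perm))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(vals, con, size = if (data_type == 4L) 4L else 8L,
           endian = "little")
  hdr <- c(
    "ENVI",
    "description = {synthetic leaf hypercube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", data_type),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("wavelength = {%s}",
            paste(format(cube$wavelengths, trim = TRUE, digits = 17),
                  collapse = ", ")))
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  fields <- list()
  # brace-delimited values may span lines; scalars end at the newline
  pat <- "([a-zA-Z ]+?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"
  m <- gregexpr(pat, txt, perl = TRUE)[[1]]
  starts <- as.vector(m); lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    piece <- substr(txt, starts[i], starts[i] + lens[i] - 1L)
    key <- tolower(trimws(sub("=.*", "", piece)))
    val <- trimws(sub("^[^=]*=", "", piece))
    fields[[key]] <- val
  }
  fields
}

#' Read an ENVI raster + header pair into a hypercube
#'
#' Supports BIL/BIP/BSQ interleaves, little/big endian, and data types
#' 1 (uint8), 2 (int16), 4 (float32), 5 (float64), 12 (uint16). The header
#' must carry a wavelength list whose length equals `bands`.
#'
#' @param path path to the binary raster; the header is looked up at
#'   `paste0(path, ".hdr")` (or `path` with its extension swapped).
#' @return a [hypercube()].
#' @export
read_envi <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path))
    hdr_path <- sub("\\.[^.]+$", ".hdr", path)
  if (!file.exists(hdr_path))
    stop(sprintf("ENVI header not found for '%s'", path))
  f <- parse_envi_header(hdr_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  for (k in need)
    if (is.null(f[[k]]))
      stop(sprintf("ENVI format error: header field '%s' missing", k))
  ns <- as.integer(f[["samples"]]); nl <- as.integer(f[["lines"]])
  nb <- as.integer(f[["bands"]]); dt <- as.integer(f[["data type"]])
  interleave <- tolower(trimws(f[["interleave"]]))
  if (!interleave %in% c("bil", "bip", "bsq"))
    stop(sprintf("ENVI format error: unsupported interleave '%s'", interleave))
  if (is.null(f[["wavelength"]]))
    stop("ENVI format error: header field 'wavelength' missing")
  wl <- as.numeric(strsplit(gsub("[{}\n]", "", f[["wavelength"]]), ",")[[1]])
  if (length(wl) != nb)
    stop(sprintf(
      "ENVI format error: field 'wavelength' has %d entries but bands = %d",
      length(wl), nb))
  endian <- if (!is.null(f[["byte order"]]) &&
                as.integer(f[["byte order"]]) == 1L) "big" else "little"
  spec <- switch(as.character(dt),
                 "1" = list(what = "integer", size = 1L, signed = FALSE),
                 "2" = list(what = "integer", size = 2L, signed = TRUE),
                 "4" = list(what = "numeric", size = 4L, signed = TRUE),
                 "5" = list(what = "numeric", size = 8L, signed = TRUE),
                 "12" = list(what = "integer", size = 2L, signed = FALSE),
                 stop(sprintf("ENVI format error: unsupported data type %d", dt)))
  n_vals <- ns * nl * nb
  offset <- if (!is.null(f[["header offset"]]))
    as.integer(f[["header offset"]]) else 0L
  con <- file(path, "rb")
  on.exit(close(con))
  if (offset > 0L) readBin(con, "raw", offset)
  vals <- readBin(con, spec$what, n = n_vals, size = spec$size,
                  signed = spec$signed, endian = endian)
  if (length(vals) != n_vals)
    stop(sprintf("ENVI format error: expected %d values, file holds %d",
                 n_vals, length(vals)))
  dims <- switch(interleave,
                 bsq = c(ns, nl, nb), bil = c(ns, nb, nl), bip = c(nb, ns, nl))
  inv <- switch(interleave,
                bsq = c(2L, 1L, 3L), bil = c(3L, 1L, 2L), bip = c(3L, 2L, 1L))
  arr <- aperm(array(as.numeric(vals), dims), inv)
  hypercube(arr, wl, meta = list(interleave = interleave, data_type = dt))
}

#' White/dark reference pair
#'
#' Container for the white-board and dark-current reference frames used by
#' [calibrate()]. References follow the push-broom convention: a matrix
#' with one row per spatial column (sample) and one column per band,
#' broadcast along scan lines. 3-D frames are averaged over lines.
#'
#' @param white white reference: `samples x bands` matrix or
#'   `lines x samples x bands` array.
#' @param dark matching dark reference.
#' @return object of class `reference_pair` with `white`/`dark` matrices.
#' @export
reference_pair <- function(white, dark) {
  squash <- function(x) {
    if (is.array(x) && length(dim(x)) == 3L)
      x <- apply(x, c(2, 3), mean)      # average scans over lines
    as.matrix(x)
  }
  white <- squash(white); dark <- squash(dark)
  if (!all(dim(white) == dim(dark)))
    stop("white and dark reference shapes differ")
  if (any(white <= dark)) {
    bad <- which(white <= dark, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "invalid reference pair: white <= dark at sample %d, band %d",
      bad[1], bad[2]))
  }
  structure(list(white = white, dark = dark), class = "reference_pair")
}

#' White/dark reflectance calibration
#'
#' Converts raw sensor counts to reflectance by the standard correction
#' `Ic = (Ir - Id) / (Iw - Id)`, elementwise, broadcasting the per-column
#' references along scan lines. Values outside `[0, 1.2]` (specular
#' outliers, noise under the dark level) are clipped and counted in
#' `meta$qc$clipped`.
#'
#' @param raw raw-count [hypercube()].
#' @param refs a [reference_pair()] with `samples x bands` frames matching
#'   the cube.
#' @param clip_range reflectance clipping range.
#' @return reflectance [hypercube()] (`meta$calibrated = TRUE`).
#' @export
calibrate <- function(raw, refs, clip_range = c(0, 1.2)) {
  stopifnot(inherits(raw, "hypercube"), inherits(refs, "reference_pair"))
  d <- dim(raw$data)
  if (!all(dim(refs$white) == c(d[2], d[3])))
    stop(sprintf(
      "reference shape (%d x %d) incompatible with cube (%d samples x %d bands)",
      nrow(refs$white), ncol(refs$white), d[2], d[3]))
  denom <- refs$white - refs$dark
  if (any(denom == 0)) {
    bad <- which(denom == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("calibration error: white = dark at sample %d, band %d",
                 bad[1], bad[2]))
  }
  out <- array(0, d)
  for (b in seq_len(d[3])) {
    dk <- matrix(refs$dark[, b], d[1], d[2], byrow = TRUE)
    dn <- matrix(denom[, b], d[1], d[2], byrow = TRUE)
    out[, , b] <- (raw$data[, , b] - dk) / dn
  }
  clipped <- sum(out < clip_range[1] | out > clip_range[2])
  out <- pmin(pmax(out, clip_range[1]), clip_range[2])
  hypercube(out, raw$wavelengths,
            meta = c(raw$meta[setdiff(names(raw$meta), "calibrated")],
                     list(calibrated = TRUE, qc = list(clipped = clipped))))
}
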