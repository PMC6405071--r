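#' Write a hyperspectral cube as ENVI header + binary
#'
#' Writes the standard ENVI pair: a little-endian binary data file and a
#' text `.hdr` describing it (samples, lines, bands, data type,
#' interleave, wavelengths). Float32 by default. No geospatial package
#' ships an ENVI codec in this stack, so the format is implemented here;
#' it is plain IEEE binary plus a text header and round-trips exactly.
#'
#' @param cube A [hyper_cube()].
#' @param path Data-file path (the header gets `.hdr` appended to the
#'   path without its extension).
#' @param interleave `"bsq"`, `"bil"` or `"bip"`.
#' @param data_type ENVI code: 4 = float32 (default), 5 = float64.
#' @return `path`, invisibly.
#' @export
write_envi_cube <- function(cube, path, interleave = c("bsq", "bil", "bip"),
                            data_type = 4L) {
  interleave <- match.arg(interleave)
  d <- dim(cube$values)
  nb <- d[1L]; nr <- d[2L]; nc <- d[3L]
  # values is [band, row, col]; ENVI orders sample (col) fastest
  v <- switch(interleave,
    bsq = aperm(cube$values, c(3L, 2L, 1L)),  # sample, line, band
    bil = aperm(cube$values, c(3L, 1L, 2L)),  # sample, band, line
    bip = aperm(cube$values, c(1L, 3L, 2L)))  # band, sample, line
  if (!data_type %in% c(3L, 4L, 5L)) {
    stop("write_envi_cube supports data types 3 (int32), 4 (float32), ",
         "5 (float64)")
  }
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  if (data_type == 3L) {
    writeBin(as.integer(round(as.vector(v))), con, size = 4L,
             endian = "little")
  } else {
    writeBin(as.vector(v), con,
             size = if (data_type == 4L) 4L else 8L, endian = "little")
  }
  hdr <- c(
    "ENVI",
    "description = {mdshape cube}",
    paste0("samples = ", nc),
    paste0("lines = ", nr),
    paste0("bands = ", nb),
    "header offset = 0",
    "file type = ENVI Standard",
    paste0("data type = ", data_type),
    paste0("interleave = ", interleave),
    "byte order = 0",
    paste0("band mask = {", paste(as.integer(cube$band_mask),
                                  collapse = ", "), "}"),
    paste0("wavelength units = nm"),
    paste0("wavelength = {", paste(format(cube$wavelengths,
                                          trim = TRUE, digits = 10),
                                   collapse = ", "), "}"))
  writeLines(hdr, .hdr_path(path))
  invisible(path)
}

.hdr_path <- function(path) paste0(tools::file_path_sans_ext(path), ".hdr")

# Parse an ENVI header into a named list; brace values may span lines.
.parse_envi_hdr <- function(hdr_file) {
  txt <- paste(readLines(hdr_file, warn = FALSE), collapse = "\n")
  out <- list()
  pat <- gregexpr("([a-zA-Z ][a-zA-Z 0-9]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)",
                  txt, perl = TRUE)[[1L]]
  starts <- as.vector(pat)
  lens <- attr(pat, "match.length")
  for (i in seq_along(starts)) {
    piece <- substr(txt, starts[i], starts[i] + lens[i] - 1L)
    eq <- regexpr("=", piece, fixed = TRUE)
    key <- tolower(trimws(substr(piece, 1L, eq - 1L)))
    val <- trimws(substr(piece, eq + 1L, nchar(piece)))
    out[[key]] <- val
  }
  out
}

.hdr_numeric_list <- function(v) {
  v <- gsub("[{}]", "", v)
  as.numeric(trimws(strsplit(v, ",")[[1L]]))
}

#' Read an ENVI cube
#'
#' Reads the header + binary pair back into a [hyper_cube()]. BSQ, BIL
#' and BIP interleaves and ENVI data types 1, 2, 3, 4, 5 and 12 are
#' supported. Wavelengths come from the header `wavelength` field or,
#' when absent, from a sidecar CSV with columns `band, wavelength_nm`.
#'
#' @param path Data-file path (header found by swapping the extension
#'   for `.hdr`, or at `path.hdr`).
#' @param wavelengths Optional explicit wavelengths or sidecar CSV path,
#'   overriding the header.
#' @param scale_factor Multiplier applied to the raw values (use e.g.
#'   1/10000 for integer reflectance products).
#' @return A [hyper_cube()].
#' @export
read_envi_cube <- function(path, wavelengths = NULL, scale_factor = 1) {
  hdr_file <- .hdr_path(path)
  if (!file.exists(hdr_file)) hdr_file <- paste0(path, ".hdr")
  if (!file.exists(hdr_file)) stop("no ENVI header found for ", path)
  h <- .parse_envi_hdr(hdr_file)
  nc <- as.integer(h[["samples"]]); nr <- as.integer(h[["lines"]])
  nb <- as.integer(h[["bands"]])
  dt <- as.integer(h[["data type"]])
  interleave <- tolower(h[["interleave"]] %||% "bsq")
  endian <- if (!is.null(h[["byte order"]]) &&
                as.integer(h[["byte order"]]) == 1L) "big" else "little"
  spec <- switch(as.character(dt),
    "1" = list(what = integer(), size = 1L, signed = FALSE),
    "2" = list(what = integer(), size = 2L, signed = TRUE),
    "3" = list(what = integer(), size = 4L, signed = TRUE),
    "4" = list(what = numeric(), size = 4L, signed = TRUE),
    "5" = list(what = numeric(), size = 8L, signed = TRUE),
    "12" = list(what = integer(), size = 2L, signed = FALSE),
    stop("unsupported ENVI data type ", dt))
  n <- nb * nr * nc
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  raw <- readBin(con, spec$what, n = n, size = spec$size,
                 signed = spec$signed, endian = endian)
  if (length(raw) != n) stop("ENVI file shorter than header promises")
  arr <- switch(interleave,
    bsq = aperm(array(raw, c(nc, nr, nb)), c(3L, 2L, 1L)),
    bil = aperm(array(raw, c(nc, nb, nr)), c(2L, 3L, 1L)),
    bip = aperm(array(raw, c(nb, nc, nr)), c(1L, 3L, 2L)),
    stop("unsupported interleave '", interleave, "'"))
  if (is.null(wavelengths)) {
    if (!is.null(h[["wavelength"]])) {
      wavelengths <- .hdr_numeric_list(h[["wavelength"]])
    } else {
      stop("header has no wavelengths; supply a sidecar CSV ",
           "(band, wavelength_nm) via the wavelengths argument")
    }
  } else if (is.character(wavelengths)) {
    wavelengths <- read_wavelengths(wavelengths)
  }
  if (length(wavelengths) != nb) {
    stop("wavelength count (", length(wavelengths),
         ") does not match band count (", nb, ")")
  }
  mask <- if (!is.null(h[["band mask"]])) {
    .hdr_numeric_list(h[["band mask"]]) > 0
  } else NULL
  hyper_cube(arr * scale_factor, wavelengths, band_mask = mask)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a wavelength sidecar CSV
#'
#' Two columns, `band` (1-based) and `wavelength_nm`; returns the
#' wavelengths ordered by band.
#' @param path CSV path.
#' @return Numeric vector.
#' @export
read_wavelengths <- function(path) {
  df <- utils::read.csv(path)
  need <- c("band", "wavelength_nm")
  if (!all(need %in% names(df))) {
    stop("wavelength sidecar must have columns: ",
         paste(need, collapse = ", "))
  }
  df$wavelength_nm[order(df$band)]
}

#' Read a band-mask file
#'
#' One 0/1 value per band (whitespace/newline separated); 1 = retained.
#' @param path Text file path.
#' @return Logical vector.
#' @export
read_band_mask <- function(path) scan(path, integer(), quiet = TRUE) > 0

#' Write a single-band raster
#'
#' Stores a `rows x cols` layer as a one-band ENVI float32 (or int32)
#' file, the package's raster exchange format. `NaN` values are stored
#' as IEEE NaN.
#'
#' @param layer Numeric or integer matrix.
#' @param path Output data-file path.
#' @param integer Store as int32 instead of float32.
#' @return `path`, invisibly.
#' @export
write_raster <- function(layer, path, integer = FALSE) {
  if (!is.matrix(layer)) stop("layer must be a matrix")
  cube <- hyper_cube(array(as.numeric(layer),
                           dim = c(1L, nrow(layer), ncol(layer))),
                     wavelengths = 0)
  write_envi_cube(cube, path, data_type = if (integer) 3L else 4L)
}

#' Read a single-band raster written by [write_raster()]
#' @param path Data-file path.
#' @return Numeric matrix.
#' @export
read_raster <- function(path) {
  cube <- read_envi_cube(path, wavelengths = 0)
  matrix(cube$values[1L, , ], dim(cube$values)[2L], dim(cube$values)[3L])
}
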