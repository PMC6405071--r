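#' Construct a hyperspectral cube
#'
#' In-memory container for a reflectance cube: a `bands x rows x cols`
#' numeric array with per-band wavelengths and an optional bad-band mask.
#' Masked (dropped) bands are excluded from every downstream computation
#' and the retained bands are re-indexed contiguously (0-based), so the
#' default moment-distance abscissa runs 0, 1, ... over retained bands.
#'
#' @param values Numeric array `bands x rows x cols`.
#' @param wavelengths Numeric vector of per-band wavelengths in nm,
#'   strictly increasing, length `bands`.
#' @param band_mask Logical vector, length `bands`: `TRUE` = retained.
#'   Default keeps every band.
#' @param meta Optional named list of pass-through metadata (map info,
#'   coordinate system strings, nodata value).
#' @return An object of class `hyper_cube`.
#' @export
hyper_cube <- function(values, wavelengths, band_mask = NULL, meta = list()) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("values must be a bands x rows x cols array")
  }
  storage.mode(values) <- "double"
  nb <- dim(values)[1L]
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != nb) {
    stop("wavelengths length (", length(wavelengths),
         ") must equal band count (", nb, ")")
  }
  if (nb > 1L && any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing")
  }
  if (is.null(band_mask)) band_mask <- rep(TRUE, nb)
  band_mask <- as.logical(band_mask)
  if (length(band_mask) != nb) {
    stop("band_mask length must equal band count")
  }
  if (!any(band_mask)) stop("band_mask retains no bands")
  structure(list(values = values, wavelengths = wavelengths,
                 band_mask = band_mask, meta = meta),
            class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$values)
  cat("<hyper_cube> ", d[1L], " bands (", sum(x$band_mask), " retained) x ",
      d[2L], " x ", d[3L], " pixels, ",
      min(x$wavelengths), "-", max(x$wavelengths), " nm\n", sep = "")
  invisible(x)
}

#' @export
dim.hyper_cube <- function(x) dim(x$values)

#' Cube helpers
#'
#' `cube_shape()` returns `c(rows, cols)`; `retained_bands()` the indices
#' of unmasked bands; `retained_matrix()` the retained reflectance as a
#' `bands x pixels` matrix (pixels in column-major row/col order);
#' `cube_abscissa()` the moment-distance abscissa of the retained bands.
#'
#' @param cube A [hyper_cube()].
#' @param abscissa `"index"` for the contiguous 0-based retained-band
#'   index (default) or `"wavelength"` for nm positions.
#' @name cube-helpers
NULL

#' @rdname cube-helpers
#' @export
cube_shape <- function(cube) dim(cube$values)[2:3]

#' @rdname cube-helpers
#' @export
retained_bands <- function(cube) which(cube$band_mask)

#' @rdname cube-helpers
#' @export
retained_matrix <- function(cube) {
  d <- dim(cube$values)
  m <- matrix(cube$values, nrow = d[1L])
  m[cube$band_mask, , drop = FALSE]
}

#' @rdname cube-helpers
#' @export
cube_abscissa <- function(cube, abscissa = c("index", "wavelength")) {
  abscissa <- match.arg(abscissa)
  if (abscissa == "index") {
    seq_len(sum(cube$band_mask)) - 1
  } else {
    cube$wavelengths[cube$band_mask]
  }
}

#' Extract one pixel's spectral curve
#'
#' @param cube A [hyper_cube()].
#' @param row,col 1-based pixel position.
#' @inheritParams cube-helpers
#' @return A [spectral_curve()] over the retained bands.
#' @export
cube_curve <- function(cube, row, col, abscissa = c("index", "wavelength")) {
  spectral_curve(cube$values[cube$band_mask, row, col],
                 cube_abscissa(cube, abscissa))
}

#' Moment-distance raster of a cube
#'
#' Applies the moment-distance metrics per pixel over the retained bands
#' and returns the chosen metric as a `rows x cols` raster. Pivot
#' positions are expressed on the cube abscissa (retained-band 0-based
#' index by default) and default to the first and last retained band,
#' i.e. the full spectrum.
#'
#' @param cube A [hyper_cube()].
#' @param pivots A [pivot_pair()] on the cube abscissa, or `NULL` for the
#'   full retained range.
#' @param metric One of `"MDI"`, `"MDIN"`, `"MDRLR"`, `"MDRRL"`,
#'   `"MD_LP"`, `"MD_RP"` (case-insensitive).
#' @inheritParams cube-helpers
#' @param na_skip Exclude NaN samples per pixel instead of erroring.
#' @param reflectance_scale Multiplier applied to reflectance before the
#'   hypotenuse sums (default 1). The moment-distance sums mix the
#'   reflectance ordinate with abscissa distances, so their relative
#'   magnitude is a unit choice: for cubes in \[0, 1\] reflectance with a
#'   band-index abscissa, percent scale (100) keeps the two axes
#'   comparable so that curve shape actually informs the sums.
#' @return A `rows x cols` numeric matrix.
#' @export
md_cube <- function(cube, pivots = NULL,
                    metric = c("MDI", "MDIN", "MDRLR", "MDRRL",
                               "MD_LP", "MD_RP"),
                    abscissa = c("index", "wavelength"),
                    na_skip = FALSE, reflectance_scale = 1) {
  metric <- match.arg(toupper(metric[1L]),
                      c("MDI", "MDIN", "MDRLR", "MDRRL", "MD_LP", "MD_RP"))
  x <- cube_abscissa(cube, abscissa)
  if (is.null(pivots)) pivots <- pivot_pair(x[1L], x[length(x)])
  tol <- 1e-8
  if (pivots$lp < x[1L] - tol || pivots$rp > x[length(x)] + tol ||
      min(abs(x - pivots$lp)) > tol || min(abs(x - pivots$rp)) > tol) {
    stop("pivots must fall on retained-band abscissa positions in [",
         x[1L], ", ", x[length(x)], "]")
  }
  win <- which(x >= pivots$lp - tol & x <= pivots$rp + tol)
  m <- retained_matrix(cube)[win, , drop = FALSE] * reflectance_scale
  if (anyNA(m) && !na_skip) {
    stop("cube contains NaN reflectance inside the pivot window; ",
         "set na_skip = TRUE to exclude missing samples per pixel")
  }
  xs <- x[win]
  legs_lp <- xs - pivots$lp
  legs_rp <- pivots$rp - xs
  md_lp <- colSums(sqrt(m^2 + legs_lp^2), na.rm = na_skip)
  md_rp <- colSums(sqrt(m^2 + legs_rp^2), na.rm = na_skip)
  vals <- switch(metric,
    MD_LP = md_lp,
    MD_RP = md_rp,
    MDI = md_rp - md_lp,
    MDIN = {
      s <- md_lp + md_rp
      ifelse(s > 0, (md_rp - md_lp) / s, NaN)
    },
    MDRLR = ifelse(md_rp > 0, md_lp / md_rp, NaN),
    MDRRL = ifelse(md_lp > 0, md_rp / md_lp, NaN))
  sh <- cube_shape(cube)
  matrix(vals, nrow = sh[1L], ncol = sh[2L])
}
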