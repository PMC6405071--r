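#' Broadband wavelength ranges
#'
#' The four broadband ranges used to average hyperspectral bands for the
#' comparison indices: NIR 750-850 nm, red 600-700 nm, green 500-600 nm,
#' blue 400-500 nm.
#'
#' @param nir,red,green,blue Length-2 numeric `c(lo, hi)` in nm.
#' @return Named list of ranges, class `band_ranges`.
#' @export
band_ranges <- function(nir = c(750, 850), red = c(600, 700),
                        green = c(500, 600), blue = c(400, 500)) {
  r <- list(nir = nir, red = red, green = green, blue = blue)
  for (nm in names(r)) {
    v <- as.numeric(r[[nm]])
    if (length(v) != 2L || v[1L] >= v[2L]) {
      stop("range '", nm, "' must be c(lo, hi) with lo < hi")
    }
    r[[nm]] <- v
  }
  structure(r, class = "band_ranges")
}

#' Broadband average of a cube
#'
#' Per-pixel unweighted mean of the retained bands whose wavelength falls
#' inside `range_nm` (inclusive).
#'
#' @param cube A [hyper_cube()].
#' @param range_nm Numeric `c(lo, hi)` in nm.
#' @return `rows x cols` matrix.
#' @export
broadband_average <- function(cube, range_nm) {
  wl <- cube$wavelengths
  sel <- cube$band_mask & wl >= range_nm[1L] & wl <= range_nm[2L]
  if (!any(sel)) {
    stop("no retained band in [", range_nm[1L], ", ", range_nm[2L],
         "] nm; available wavelengths: ",
         paste(signif(range(wl[cube$band_mask]), 6), collapse = " - "),
         " nm (", sum(cube$band_mask), " bands)")
  }
  d <- dim(cube$values)
  m <- matrix(cube$values, nrow = d[1L])[sel, , drop = FALSE]
  matrix(colMeans(m), nrow = d[2L], ncol = d[3L])
}

# Nearest retained band to a target wavelength; ties go to the shorter
# wavelength. Errors when the target lies outside the covered range.
.nearest_band <- function(cube, nm, context = "narrow band") {
  wl <- cube$wavelengths[cube$band_mask]
  if (nm < min(wl) || nm > max(wl)) {
    stop(context, ": cube wavelengths (", min(wl), "-", max(wl),
         " nm) do not cover ", nm, " nm")
  }
  d <- abs(wl - nm)
  which(d == min(d))[1L]  # first = shorter wavelength on ties
}

.narrow_band_image <- function(cube, nm, context) {
  b <- .nearest_band(cube, nm, context)
  ret <- retained_matrix(cube)
  sh <- cube_shape(cube)
  matrix(ret[b, ], nrow = sh[1L], ncol = sh[2L])
}

.nd_ratio <- function(a, b) {
  s <- a + b
  out <- (a - b) / s
  out[s == 0] <- NaN
  out
}

#' Names of the supported comparison indices
#' @return Character vector.
#' @export
index_names <- function() c("NDVI", "EVI", "NDII", "NRI", "PSRI", "PRI")

#' Compute a comparison spectral index
#'
#' The six conventional indices used alongside the moment-distance
#' metrics. Broadband indices use [broadband_average()] over the four
#' ranges; narrow-band indices use the retained band nearest the target
#' wavelength:
#' * `NDVI` = (Red - NIR)/(Red + NIR) by default — note the orientation,
#'   the reverse of the textbook form; set `standard_orientation = TRUE`
#'   for (NIR - Red)/(NIR + Red). Tree-based classifiers are invariant to
#'   this monotone sign flip.
#' * `EVI`  = 2.5 (NIR - Red) / (1 + NIR + 6 Red - 7.5 Blue)
#' * `NDII` = (R819 - R1649)/(R819 + R1649) (water sensitivity; needs SWIR)
#' * `NRI`  = (Green - Red)/(Green + Red)
#' * `PSRI` = (Red - Blue)/NIR
#' * `PRI`  = (R529 - R580)/(R529 + R580)
#'
#' Zero denominators yield `NaN`.
#'
#' @param cube A [hyper_cube()].
#' @param name One of [index_names()] (case-insensitive).
#' @param ranges A [band_ranges()].
#' @param standard_orientation Flip NDVI to its conventional sign.
#' @return `rows x cols` matrix of index values.
#' @export
compute_index <- function(cube, name, ranges = band_ranges(),
                          standard_orientation = FALSE) {
  name <- match.arg(toupper(name), index_names())
  bb <- function(which) broadband_average(cube, ranges[[which]])
  switch(name,
    NDVI = {
      red <- bb("red"); nir <- bb("nir")
      if (standard_orientation) .nd_ratio(nir, red) else .nd_ratio(red, nir)
    },
    EVI = {
      nir <- bb("nir"); red <- bb("red"); blue <- bb("blue")
      den <- 1 + nir + 6 * red - 7.5 * blue
      out <- 2.5 * (nir - red) / den
      out[den == 0] <- NaN
      out
    },
    NDII = .nd_ratio(.narrow_band_image(cube, 819, "NDII"),
                     .narrow_band_image(cube, 1649, "NDII")),
    NRI = .nd_ratio(bb("green"), bb("red")),
    PSRI = {
      nir <- bb("nir")
      out <- (bb("red") - bb("blue")) / nir
      out[nir == 0] <- NaN
      out
    },
    PRI = .nd_ratio(.narrow_band_image(cube, 529, "PRI"),
                    .narrow_band_image(cube, 580, "PRI")))
}

#' Stack of all six comparison indices
#'
#' @inheritParams compute_index
#' @param set Character vector of index names to compute (default all six).
#' @return A [feature_stack()] with one layer per index.
#' @export
spectral_index_stack <- function(cube, set = index_names(),
                                 ranges = band_ranges(),
                                 standard_orientation = FALSE) {
  set <- vapply(set, function(s) match.arg(toupper(s), index_names()),
                character(1))
  fs <- feature_stack()
  for (nm in set) {
    fs <- fs_add(fs, nm,
                 compute_index(cube, nm, ranges, standard_orientation),
                 paste0("compute_index(", nm, ")"))
  }
  fs
}

#' Stack of the four moment-distance rasters
#'
#' Convenience wrapper producing the MDI, MDIN, MDRLR and MDRRL layers of
#' a cube with shared pivots, named as used in the classification sets.
#'
#' @inheritParams md_cube
#' @return A [feature_stack()] with layers `MDI`, `MDIN`, `MDRLR`, `MDRRL`.
#' @export
md_stack <- function(cube, pivots = NULL,
                     abscissa = c("index", "wavelength"), na_skip = FALSE,
                     reflectance_scale = 1) {
  fs <- feature_stack()
  for (nm in c("MDI", "MDIN", "MDRLR", "MDRRL")) {
    fs <- fs_add(fs, nm,
                 md_cube(cube, pivots, nm, abscissa, na_skip,
                         reflectance_scale),
                 paste0("md_cube(", nm, ", reflectance_scale=",
                        reflectance_scale, ")"))
  }
  fs
}
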