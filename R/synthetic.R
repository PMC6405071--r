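#' Piecewise-linear endmember templates
#'
#' Qualitative reflectance templates used by the scene generator:
#' `"vegetation"` has the classic green peak (~550 nm), red trough
#' (~670 nm), red-edge rise (700-750 nm), NIR plateau and SWIR water
#' absorption; `"soil"` rises gently with wavelength; `"canopy"` is an
#' even vegetation/soil mixture (sparse canopy / crop residue analog).
#' These are shape stand-ins for curve-shape experiments, not
#' radiative-transfer output.
#'
#' @param wavelengths Numeric vector of wavelengths in nm.
#' @param base `"vegetation"`, `"soil"` or `"canopy"`.
#' @return Numeric reflectance vector in \[0, 1\].
#' @export
endmember_template <- function(wavelengths,
                               base = c("vegetation", "soil", "canopy")) {
  base <- match.arg(base)
  veg_x <- c(400, 500, 550, 600, 670, 700, 750, 850, 970, 1100,
             1200, 1300, 1450, 1550, 1660, 1800, 2500)
  veg_y <- c(0.04, 0.05, 0.10, 0.07, 0.04, 0.08, 0.45, 0.50, 0.42,
             0.48, 0.42, 0.45, 0.18, 0.30, 0.28, 0.22, 0.10)
  soil_x <- c(400, 600, 900, 1300, 1450, 1700, 2100, 2500)
  soil_y <- c(0.08, 0.16, 0.26, 0.34, 0.28, 0.36, 0.38, 0.30)
  veg <- stats::approx(veg_x, veg_y, xout = wavelengths, rule = 2)$y
  soil <- stats::approx(soil_x, soil_y, xout = wavelengths, rule = 2)$y
  switch(base, vegetation = veg, soil = soil,
         canopy = 0.45 * veg + 0.55 * soil)
}

#' Class specification for the scene generator
#'
#' A class is a base template, optional absorption features (raised-
#' cosine dips of given center, full support width and depth, in nm and
#' reflectance units), an amplitude scale, and an optional constant
#' offset restricted to a wavelength interval (used by the confusable-
#' pair construction).
#'
#' @param name Class name.
#' @param base Template name (see [endmember_template()]) or a function
#'   of wavelengths returning reflectance.
#' @param features List of `c(center, width, depth)` absorption dips.
#' @param amplitude Multiplicative scale applied to the base curve.
#' @param offset Constant added inside `offset_range` (nm), default none.
#' @param offset_range Length-2 nm interval for `offset`.
#' @return An object of class `class_spec`.
#' @export
class_spec <- function(name, base = "vegetation", features = list(),
                       amplitude = 1, offset = 0, offset_range = NULL) {
  structure(list(name = name, base = base, features = features,
                 amplitude = amplitude, offset = offset,
                 offset_range = offset_range),
            class = "class_spec")
}

# Raised-cosine absorption dip: depth * 0.5 * (1 + cos(2*pi*(x-c)/w))
# on compact support [c - w/2, c + w/2], zero elsewhere.
.dip_profile <- function(wavelengths, center, width, depth) {
  d <- rep(0, length(wavelengths))
  inside <- abs(wavelengths - center) <= width / 2
  d[inside] <- depth * 0.5 *
    (1 + cos(2 * pi * (wavelengths[inside] - center) / width))
  d
}

#' Realize a class curve on a wavelength grid
#'
#' @param spec A [class_spec()].
#' @param wavelengths Numeric vector in nm.
#' @return Reflectance vector; errors (naming the class) if the curve
#'   leaves \[0, 1\].
#' @export
build_class_curve <- function(spec, wavelengths) {
  rho <- if (is.function(spec$base)) {
    spec$base(wavelengths)
  } else {
    endmember_template(wavelengths, spec$base)
  }
  rho <- rho * spec$amplitude
  for (f in spec$features) {
    rho <- rho - .dip_profile(wavelengths, f[1L], f[2L], f[3L])
  }
  if (spec$offset != 0) {
    inside <- wavelengths >= spec$offset_range[1L] &
      wavelengths <= spec$offset_range[2L]
    rho[inside] <- rho[inside] + spec$offset
  }
  if (any(rho < 0 | rho > 1)) {
    stop("class '", spec$name, "': curve leaves [0, 1] (range ",
         signif(min(rho), 3), " to ", signif(max(rho), 3), ")")
  }
  rho
}

#' Build a shape-confusable class pair
#'
#' Returns two classes that are indistinguishable to every broadband
#' index but distinct in fine spectral structure: class B is class A
#' with a raised-cosine absorption dip added, plus a compensating
#' constant offset over the broadband range containing the dip, chosen
#' so that the two classes have exactly equal means over all four
#' broadband ranges on the given wavelength grid. Their broadband
#' indices (and, when the dip avoids the narrow bands, all six
#' comparison indices) are then equal, while the moment-distance
#' metrics still differ because the curve shapes differ.
#'
#' @param template A [class_spec()] for class A.
#' @param dip `c(center, width, depth)` in nm/nm/reflectance; its support
#'   must lie fully inside one broadband range.
#' @param ranges A [band_ranges()].
#' @param wavelengths The scene's wavelength grid (needed to make the
#'   band-sampled compensation exact).
#' @return List of two [class_spec()]s, `a` and `b`.
#' @export
make_confusable_pair <- function(template,
                                 dip = c(center = 470, width = 60,
                                         depth = 0.05),
                                 ranges = band_ranges(),
                                 wavelengths = default_wavelengths()) {
  lo <- dip[1L] - dip[2L] / 2
  hi <- dip[1L] + dip[2L] / 2
  host <- NULL
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (lo >= r[1L] && hi <= r[2L]) { host <- nm; break }
  }
  if (is.null(host)) {
    stop("dip support [", lo, ", ", hi,
         "] nm must lie fully inside one broadband range")
  }
  r <- ranges[[host]]
  inside <- wavelengths >= r[1L] & wavelengths <= r[2L]
  if (!any(inside)) stop("no wavelength samples inside the '", host,
                         "' range")
  dipvals <- .dip_profile(wavelengths, dip[1L], dip[2L], dip[3L])
  offset <- sum(dipvals[inside]) / sum(inside)
  b <- template
  b$name <- paste0(template$name, "_dip")
  b$features <- c(template$features, list(unname(dip)))
  b$offset <- b$offset + offset
  b$offset_range <- r
  build_class_curve(b, wavelengths)  # validate [0,1], error early
  list(a = template, b = b)
}

#' Default scene wavelength grid
#'
#' 100 bands spanning 400-1700 nm, covering the visible, NIR and enough
#' SWIR for the 1649 nm narrow band of NDII.
#' @param n_bands Number of bands.
#' @param range_nm Length-2 nm interval.
#' @return Numeric vector.
#' @export
default_wavelengths <- function(n_bands = 100L, range_nm = c(400, 1700)) {
  seq(range_nm[1L], range_nm[2L], length.out = n_bands)
}

#' Scene specification
#'
#' Conditions of a synthetic scene: geometry, band grid, class list,
#' per-band Gaussian noise sd, patch grid and border irregularity, seed.
#' The default is the study fixture: 64 x 64 pixels, 100 bands over
#' 400-1700 nm, four classes of which two are a shape-confusable pair,
#' noise sd 0.01.
#'
#' @param rows,cols Scene size in pixels.
#' @param wavelengths Band wavelength grid in nm.
#' @param classes List of [class_spec()]; >= 2.
#' @param noise_sd Per-band Gaussian noise sd (reflectance units).
#' @param amplitude_jitter_sd Sd of the per-pixel multiplicative
#'   brightness factor (illumination / canopy-density variability within
#'   fields), default 0.02. Whole-curve scaling leaves normalized band
#'   ratios untouched in expectation but gives realistic within-field
#'   brightness texture.
#' @param moisture_jitter_sd Sd of the per-pixel zero-mean water-content
#'   term: a raised-cosine absorption profile centred at 1450 nm
#'   (support width 150 nm) scaled by a `N(0, sd)` coefficient per
#'   pixel, default 0.03 reflectance at the trough centre. Water-content
#'   variability is the dominant within-field spectral (as opposed to
#'   brightness) variation in real canopies and soils; being zero-mean
#'   and identically distributed in every class it leaves all class
#'   means untouched.
#' @param patch_grid `c(nx, ny)` blocks of the field layout.
#' @param border_jitter Maximum border displacement in pixels.
#' @param layout `"separated"` (default) alternates blocks of the last
#'   two classes (the confusable pair in [default_classes()]) with
#'   blocks of the remaining classes in a checkerboard, so that
#'   pair-class fields never share a border and every field boundary
#'   carries real spectral contrast, as when two tillage regimes are
#'   interleaved with other cover types; `"random"` assigns block
#'   classes uniformly at random.
#' @param seed Integer seed.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(rows = 64L, cols = 64L,
                       wavelengths = default_wavelengths(),
                       classes = default_classes(wavelengths),
                       noise_sd = 0.01, amplitude_jitter_sd = 0.02,
                       moisture_jitter_sd = 0.03,
                       patch_grid = c(8L, 8L),
                       border_jitter = 2L,
                       layout = c("separated", "random"), seed = 1L) {
  if (length(classes) < 2L) stop("a scene needs at least 2 classes")
  layout <- match.arg(layout)
  if (length(classes) < 3L) layout <- "random"
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 wavelengths = as.numeric(wavelengths), classes = classes,
                 noise_sd = noise_sd,
                 amplitude_jitter_sd = amplitude_jitter_sd,
                 moisture_jitter_sd = moisture_jitter_sd,
                 patch_grid = as.integer(patch_grid),
                 border_jitter = as.integer(border_jitter),
                 layout = layout,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Default four-class list
#'
#' Soil, full vegetation, and a confusable sparse-canopy pair whose
#' member B carries a blue-region absorption dip (centre 470 nm, support
#' 440-500 nm, depth 0.05) with broadband-mean compensation.
#'
#' @param wavelengths Scene wavelength grid.
#' @param dip Dip parameters passed to [make_confusable_pair()].
#' @return List of four [class_spec()]s.
#' @export
default_classes <- function(wavelengths = default_wavelengths(),
                            dip = c(center = 470, width = 60,
                                    depth = 0.05)) {
  pair <- make_confusable_pair(class_spec("canopy_a", base = "canopy"),
                               dip = dip, wavelengths = wavelengths)
  list(class_spec("soil", base = "soil"),
       class_spec("vegetation", base = "vegetation"),
       pair$a, pair$b)
}

# Smooth integer displacement field: coarse random grid, bilinearly
# upsampled, rounded. Used to make patch borders irregular.
.displacement_field <- function(rows, cols, grid, jitter) {
  gx <- max(grid[1L], 2L); gy <- max(grid[2L], 2L)
  coarse <- matrix(stats::runif(gx * gy, -jitter, jitter), gy, gx)
  ri <- seq(1, gy, length.out = rows)
  ci <- seq(1, gx, length.out = cols)
  r0 <- pmin(floor(ri), gy - 1L); c0 <- pmin(floor(ci), gx - 1L)
  fr <- ri - r0; fc <- ci - c0
  out <- outer(seq_len(rows), seq_len(cols), function(i, j) {
    a <- coarse[cbind(r0[i], c0[j])] * (1 - fr[i]) * (1 - fc[j]) +
      coarse[cbind(r0[i] + 1L, c0[j])] * fr[i] * (1 - fc[j]) +
      coarse[cbind(r0[i], c0[j] + 1L)] * (1 - fr[i]) * fc[j] +
      coarse[cbind(r0[i] + 1L, c0[j] + 1L)] * fr[i] * fc[j]
    a
  })
  round(out)
}

#' Generate a synthetic scene
#'
#' Builds the labeled class map (rectangular field patches with
#' irregular borders, obtained by warping a block layout with a smooth
#' random displacement field), then the reflectance cube as the class
#' curve of each pixel plus independent per-band Gaussian noise, clipped
#' to \[0, 1\]. Bit-reproducible under the spec seed; the global RNG
#' state is left untouched.
#'
#' @param spec A [scene_spec()].
#' @return List with `cube` (a [hyper_cube()]), `truth` (integer
#'   `rows x cols` class raster, classes `1..K`), `curves` (bands x K
#'   matrix of noise-free class curves), and `spec`.
#' @export
make_scene <- function(spec = scene_spec()) {
  wl <- spec$wavelengths
  K <- length(spec$classes)
  curves <- vapply(spec$classes, build_class_curve, numeric(length(wl)),
                   wavelengths = wl)
  out <- withr::with_seed(spec$seed, {
    nx <- spec$patch_grid[1L]; ny <- spec$patch_grid[2L]
    blocks <- if (identical(spec$layout, "separated")) {
      pair <- c(K - 1L, K)
      rest <- seq_len(K - 2L)
      bm <- matrix(0L, ny, nx)
      odd <- (row(bm) + col(bm)) %% 2L == 1L
      bm[odd] <- sample(rep_len(pair, sum(odd)))
      bm[!odd] <- sample(rep_len(rest, sum(!odd)))
      bm
    } else {
      matrix(sample(rep_len(seq_len(K), nx * ny)), ny, nx)
    }
    dr <- .displacement_field(spec$rows, spec$cols,
                              spec$patch_grid, spec$border_jitter)
    dc <- .displacement_field(spec$rows, spec$cols,
                              spec$patch_grid, spec$border_jitter)
    rr <- pmin(pmax(row(dr) + dr, 1L), spec$rows)
    cc <- pmin(pmax(col(dc) + dc, 1L), spec$cols)
    br <- pmin(ceiling(rr / (spec$rows / ny)), ny)
    bc <- pmin(ceiling(cc / (spec$cols / nx)), nx)
    truth <- matrix(blocks[cbind(as.vector(br), as.vector(bc))],
                    spec$rows, spec$cols)
    npix <- spec$rows * spec$cols
    vals <- curves[, as.vector(truth), drop = FALSE]
    if (spec$amplitude_jitter_sd > 0) {
      amp <- 1 + stats::rnorm(npix, sd = spec$amplitude_jitter_sd)
      vals <- vals * rep(amp, each = length(wl))
    }
    if (spec$moisture_jitter_sd > 0) {
      water <- .dip_profile(wl, 1450, 150, 1)
      if (any(water > 0)) {
        z <- stats::rnorm(npix, sd = spec$moisture_jitter_sd)
        vals <- vals + outer(water, z)
      }
    }
    if (spec$noise_sd > 0) {
      vals <- vals + stats::rnorm(length(vals), sd = spec$noise_sd)
    }
    if (spec$amplitude_jitter_sd > 0 || spec$noise_sd > 0) {
      vals <- pmin(pmax(vals, 0), 1)
    }
    list(truth = truth,
         values = array(vals, dim = c(length(wl), spec$rows, spec$cols)))
  })
  cube <- hyper_cube(out$values, wl)
  list(cube = cube, truth = out$truth, curves = curves, spec = spec)
}
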