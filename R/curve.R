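#' Construct a spectral curve
#'
#' A spectral curve is one pixel's (or one object's mean) reflectance
#' vector together with the abscissa positions of its samples. The
#' abscissa is the retained-band ordinal index (0, 1, 2, ...) by default,
#' which keeps moment-distance values comparable between sensors with the
#' same band count; wavelengths in nm may be supplied instead.
#'
#' @param reflectance Numeric vector of reflectance values (unitless,
#'   typically in \[0, 1\]).
#' @param abscissa Numeric vector of strictly increasing sample positions,
#'   same length as `reflectance`. Defaults to the 0-based band index.
#' @return An object of class `spectral_curve` with fields `reflectance`,
#'   `abscissa` and `n`.
#' @examples
#' sc <- spectral_curve(c(0.1, 0.5, 0.2))
#' md_metrics(sc)
#' @export
spectral_curve <- function(reflectance,
                           abscissa = seq_along(reflectance) - 1) {
  reflectance <- as.numeric(reflectance)
  abscissa <- as.numeric(abscissa)
  n <- length(reflectance)
  if (n < 1L) {
    stop("a spectral curve needs at least one sample")
  }
  if (length(abscissa) != n) {
    stop("reflectance and abscissa must have equal length (",
         n, " vs ", length(abscissa), ")")
  }
  if (anyNA(abscissa)) {
    stop("abscissa positions must be finite")
  }
  if (n > 1L && any(diff(abscissa) <= 0)) {
    stop("abscissa must be strictly increasing")
  }
  structure(list(reflectance = reflectance, abscissa = abscissa, n = n),
            class = "spectral_curve")
}

#' @export
print.spectral_curve <- function(x, ...) {
  cat("<spectral_curve> ", x$n, " samples, abscissa [",
      x$abscissa[1L], ", ", x$abscissa[x$n], "]\n", sep = "")
  invisible(x)
}

#' Construct a left/right pivot pair
#'
#' Pivots anchor the moment-distance summation: the left pivot (LP) sits
#' at the shorter-wavelength end of the analysis window and the right
#' pivot (RP) at the longer-wavelength end. Both must coincide with
#' abscissa sample positions of the curve they are applied to; `lp == rp`
#' is allowed (single-band degenerate window, where MD reduces to the
#' reflectance at the pivot).
#'
#' @param lp,rp Abscissa positions of the left and right pivot, `lp <= rp`.
#' @return An object of class `pivot_pair`.
#' @export
pivot_pair <- function(lp, rp) {
  lp <- as.numeric(lp)
  rp <- as.numeric(rp)
  if (length(lp) != 1L || length(rp) != 1L || is.na(lp) || is.na(rp)) {
    stop("lp and rp must be single finite positions")
  }
  if (lp > rp) {
    stop("left pivot (", lp, ") must not exceed right pivot (", rp, ")")
  }
  structure(list(lp = lp, rp = rp), class = "pivot_pair")
}

# Resolve the pivot window against a curve: indices of samples whose
# abscissa lies in [lp, rp]. Pivots must land on sample positions.
.pivot_window <- function(curve, pivots, tol = 1e-8) {
  if (is.null(pivots)) {
    pivots <- pivot_pair(curve$abscissa[1L], curve$abscissa[curve$n])
  }
  x <- curve$abscissa
  if (min(abs(x - pivots$lp)) > tol || min(abs(x - pivots$rp)) > tol) {
    stop("pivots must fall on abscissa sample positions; available range [",
         x[1L], ", ", x[length(x)], "]")
  }
  idx <- which(x >= pivots$lp - tol & x <= pivots$rp + tol)
  if (length(idx) == 0L) {
    stop("empty pivot window [", pivots$lp, ", ", pivots$rp, "]")
  }
  list(idx = idx, lp = pivots$lp, rp = pivots$rp)
}

# Shared NaN policy: fail fast unless na_skip.
.window_reflectance <- function(curve, idx, na_skip) {
  rho <- curve$reflectance[idx]
  if (anyNA(rho)) {
    if (!na_skip) {
      stop("NaN reflectance inside the pivot window; set na_skip = TRUE ",
           "to exclude missing samples")
    }
    keep <- !is.na(rho)
    idx <- idx[keep]
    rho <- rho[keep]
  }
  list(idx = idx, rho = rho)
}

#' Moment distance from the left pivot
#'
#' Sum of the hypotenuse lengths drawn from the left pivot on the abscissa
#' to each (position, reflectance) point of the curve inside the pivot
#' window: for each sample i with position x_i in \[lp, rp\], the term is
#' sqrt(rho_i^2 + (x_i - lp)^2). Both pivots are included.
#'
#' @param curve A [spectral_curve()].
#' @param pivots A [pivot_pair()]; `NULL` (default) uses the full curve.
#' @param na_skip If `TRUE`, missing reflectance samples inside the window
#'   are excluded from the sum (their count is attached as attribute
#'   `n_used`); if `FALSE` (default) they raise an error.
#' @return The moment distance (non-negative scalar) with attribute
#'   `n_used` giving the number of samples summed.
#' @seealso [moment_distance_rp()], [md_metrics()]
#' @export
moment_distance_lp <- function(curve, pivots = NULL, na_skip = FALSE) {
  w <- .pivot_window(curve, pivots)
  wr <- .window_reflectance(curve, w$idx, na_skip)
  legs <- curve$abscissa[wr$idx] - w$lp
  out <- sum(sqrt(wr$rho^2 + legs^2))
  attr(out, "n_used") <- length(wr$idx)
  out
}

#' Moment distance from the right pivot
#'
#' Mirror of [moment_distance_lp()]: abscissa legs are measured from the
#' right pivot, so each term is sqrt(rho_i^2 + (rp - x_i)^2).
#'
#' @inheritParams moment_distance_lp
#' @return The moment distance with attribute `n_used`.
#' @export
moment_distance_rp <- function(curve, pivots = NULL, na_skip = FALSE) {
  w <- .pivot_window(curve, pivots)
  wr <- .window_reflectance(curve, w$idx, na_skip)
  legs <- w$rp - curve$abscissa[wr$idx]
  out <- sum(sqrt(wr$rho^2 + legs^2))
  attr(out, "n_used") <- length(wr$idx)
  out
}

#' All moment-distance metrics of a curve
#'
#' Computes the two pivot sums and the four shape indices built from
#' them:
#' * `mdi  = md_rp - md_lp` (unbounded difference),
#' * `mdin = (md_rp - md_lp) / (md_rp + md_lp)` (normalized difference,
#'   bounded in (-1, 1) for positive curves),
#' * `mdrlr = md_lp / md_rp` and `mdrrl = md_rp / md_lp` (the two pivot
#'   ratios; reciprocal of one another).
#'
#' When a denominator is zero (possible only for all-zero reflectance in
#' a degenerate window) the affected ratios and `mdin` are reported as
#' `NaN` with a warning, never silently substituted.
#'
#' @inheritParams moment_distance_lp
#' @return An object of class `md_result`: a list with fields `md_lp`,
#'   `md_rp`, `mdi`, `mdin`, `mdrlr`, `mdrrl`, `n_used`.
#' @examples
#' md_metrics(spectral_curve(c(0.1, 0.5, 0.2)))
#' @export
md_metrics <- function(curve, pivots = NULL, na_skip = FALSE) {
  lp <- moment_distance_lp(curve, pivots, na_skip)
  rp <- moment_distance_rp(curve, pivots, na_skip)
  n_used <- attr(lp, "n_used")
  lp <- as.numeric(lp)
  rp <- as.numeric(rp)
  s <- lp + rp
  if (lp == 0 || rp == 0) {
    warning("zero moment distance: ratio metrics undefined (NaN)")
    mdin <- if (s > 0) (rp - lp) / s else NaN
    mdrlr <- if (rp > 0) lp / rp else NaN
    mdrrl <- if (lp > 0) rp / lp else NaN
  } else {
    mdin <- (rp - lp) / s
    mdrlr <- lp / rp
    mdrrl <- rp / lp
  }
  structure(list(md_lp = lp, md_rp = rp, mdi = rp - lp, mdin = mdin,
                 mdrlr = mdrlr, mdrrl = mdrrl, n_used = n_used),
            class = "md_result")
}

#' @export
print.md_result <- function(x, ...) {
  cat(sprintf(
    "<md_result> MD_LP=%.6g MD_RP=%.6g MDI=%.6g MDIN=%.6g MDRLR=%.6g MDRRL=%.6g (n=%d)\n",
    x$md_lp, x$md_rp, x$mdi, x$mdin, x$mdrlr, x$mdrrl, x$n_used))
  invisible(x)
}

#' Moving-pivot moment-distance sweep
#'
#' Diagnostic used to locate where two curve shapes diverge: one pivot is
#' fixed at an end of the curve and the moment-distance sum is accumulated
#' band by band as the moving end advances across the full range.
#' With `fixed = "lp"` the left pivot stays at the first sample and element
#' k is the moment distance over the window covering the first k bands;
#' with `fixed = "rp"` the right pivot stays at the last sample and element
#' k covers the last k bands (advancing right to left). The final element
#' always equals the full-window [moment_distance_lp()] (resp. `_rp`).
#'
#' @param curve A [spectral_curve()] with at least two samples.
#' @param fixed Which pivot stays put: `"lp"` or `"rp"`.
#' @return Numeric vector of length `curve$n` of cumulative moment
#'   distances, in order of advancement of the moving end.
#' @export
md_sweep <- function(curve, fixed = c("lp", "rp")) {
  fixed <- match.arg(tolower(fixed), c("lp", "rp"))
  if (curve$n < 2L) {
    stop("md_sweep needs a curve with at least two samples")
  }
  x <- curve$abscissa
  rho <- curve$reflectance
  if (anyNA(rho)) stop("md_sweep does not accept missing reflectance")
  if (fixed == "lp") {
    cumsum(sqrt(rho^2 + (x - x[1L])^2))
  } else {
    cumsum(rev(sqrt(rho^2 + (x[curve$n] - x)^2)))
  }
}
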