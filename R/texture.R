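#' Co-occurrence configuration
#'
#' Parameters of the moving-window gray-level co-occurrence (GLCM)
#' texture computation: number of quantization levels, pixel offset
#' distance, and window side length. The four standard directions (0,
#' 45, 90, 135 degrees) are always accumulated into one symmetrized
#' matrix.
#'
#' @param levels Gray levels after quantization (>= 2), default 32.
#' @param distance Pixel offset of the co-occurring pair, default 1.
#' @param window Odd window side length (>= 3), default 7.
#' @return A list of class `cooccurrence_config`.
#' @export
cooccurrence_config <- function(levels = 32L, distance = 1L, window = 7L) {
  levels <- as.integer(levels); distance <- as.integer(distance)
  window <- as.integer(window)
  if (levels < 2L) stop("levels must be >= 2")
  if (distance < 1L) stop("distance must be >= 1")
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  structure(list(levels = levels, distance = distance, window = window),
            class = "cooccurrence_config")
}

#' Quantize an image to gray levels
#'
#' Equal-width binning between the image's 1st and 99th percentile;
#' values outside are clipped. A constant image maps to level 0.
#'
#' @param image Numeric matrix, finite.
#' @param levels Number of levels.
#' @param probs Lower/upper clipping quantiles.
#' @return Integer matrix of levels `0 .. levels-1`.
#' @export
quantize_image <- function(image, levels = 32L, probs = c(0.01, 0.99)) {
  if (any(!is.finite(image))) stop("image must be finite for quantization")
  qs <- stats::quantile(image, probs, names = FALSE)
  lo <- qs[1L]; hi <- qs[2L]
  if (hi <= lo) {
    return(matrix(0L, nrow(image), ncol(image)))
  }
  z <- pmin(pmax(image, lo), hi)
  q <- floor((z - lo) / (hi - lo) * levels)
  q[q >= levels] <- levels - 1L
  matrix(as.integer(q), nrow(image), ncol(image))
}

#' Moving-window co-occurrence texture features
#'
#' Computes the five second-order statistics of the direction-averaged,
#' symmetrized co-occurrence matrix P over a moving window around every
#' pixel (symmetric reflection padding at borders):
#' contrast `CON = sum (i-j)^2 P_ij`, angular second moment
#' `ASM = sum P_ij^2`, entropy `ENT = -sum P_ij ln P_ij` (0 ln 0 = 0),
#' variance `VAR = sum (i - mu)^2 P_ij` with mu the P-mean of i, and
#' correlation `COR = sum (i-mu_i)(j-mu_j) P_ij / (sd_i sd_j)` (`NaN`
#' where a marginal sd is 0, e.g. constant windows).
#'
#' @param image Numeric matrix (one band / score image), finite.
#' @param cfg A [cooccurrence_config()].
#' @return Named list of five matrices `VAR`, `ENT`, `COR`, `CON`, `ASM`.
#' @export
cooccurrence_features <- function(image, cfg = cooccurrence_config()) {
  if (!is.matrix(image)) stop("image must be a matrix")
  if (cfg$window > min(dim(image))) {
    stop("window (", cfg$window, ") larger than image (",
         nrow(image), " x ", ncol(image), ")")
  }
  q <- quantize_image(image, cfg$levels)
  glcm_features_cpp(q, cfg$levels, cfg$window, cfg$distance)
}

#' Principal-component score images of a cube
#'
#' Eigendecomposition of the band covariance matrix of the retained
#' bands (bands mean-centered, not scaled); returns the per-pixel scores
#' on the top-k eigenvectors as images, ordered by explained variance.
#' Pixels containing non-finite values are excluded from the covariance
#' estimate and receive `NaN` scores.
#'
#' @param cube A [hyper_cube()].
#' @param k Number of components (default 3).
#' @return List with `scores` (list of k `rows x cols` matrices),
#'   `explained` (variance fractions, non-increasing), and `rotation`
#'   (bands x k eigenvector matrix).
#' @export
pca_scores <- function(cube, k = 3L) {
  m <- retained_matrix(cube)            # bands x pixels
  if (nrow(m) < k) stop("cube has fewer retained bands than k = ", k)
  X <- t(m)                             # pixels x bands
  ok <- stats::complete.cases(X) & apply(is.finite(X), 1L, all)
  if (sum(ok) < 2L) stop("fewer than two finite pixels")
  Xo <- X[ok, , drop = FALSE]
  mu <- colMeans(Xo)
  Xc <- sweep(Xo, 2L, mu)
  cv <- crossprod(Xc) / (nrow(Xc) - 1L)
  tot <- sum(diag(cv))
  if (tot <= 0) stop("degenerate covariance: cube is constant")
  eg <- eigen(cv, symmetric = TRUE)
  rot <- eg$vectors[, seq_len(k), drop = FALSE]
  # sign convention: largest-magnitude loading positive, for determinism
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  sc <- sweep(X, 2L, mu) %*% rot
  sc[!ok, ] <- NaN
  sh <- cube_shape(cube)
  scores <- lapply(seq_len(k), function(j) {
    matrix(sc[, j], nrow = sh[1L], ncol = sh[2L])
  })
  list(scores = scores,
       explained = eg$values[seq_len(k)] / tot,
       rotation = rot)
}

#' The 15-layer texture stack
#'
#' The five co-occurrence features computed on each of the three highest
#' principal-component score images of the cube, yielding 15 layers named
#' `"VAR(PCA1)"`, `"ENT(PCA1)"`, ..., `"ASM(PCA3)"`.
#'
#' @param cube A [hyper_cube()].
#' @param cfg A [cooccurrence_config()].
#' @param k Number of PC score images (default 3).
#' @return A [feature_stack()] of `5 * k` layers.
#' @export
texture_stack <- function(cube, cfg = cooccurrence_config(), k = 3L) {
  pcs <- pca_scores(cube, k)
  fs <- feature_stack()
  for (j in seq_len(k)) {
    feats <- cooccurrence_features(pcs$scores[[j]], cfg)
    for (nm in names(feats)) {
      fs <- fs_add(fs, sprintf("%s(PCA%d)", nm, j), feats[[nm]],
                   sprintf("cooccurrence on PC%d (levels=%d, window=%d, distance=%d)",
                           j, cfg$levels, cfg$window, cfg$distance))
    }
  }
  fs
}
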