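test_that("cooccurrence_config validates parameters", {
  expect_error(cooccurrence_config(levels = 1), "levels")
  expect_error(cooccurrence_config(window = 4), "odd")
  expect_error(cooccurrence_config(window = 1), "odd")
  cfg <- cooccurrence_config()
  expect_equal(cfg$levels, 32L)
  expect_equal(cfg$window, 7L)
  expect_equal(cfg$distance, 1L)
})

test_that("quantization clips at the 1st/99th percentile into equal bins", {
  img <- matrix(seq(0, 1, length.out = 100), 10, 10)
  q <- quantize_image(img, 4)
  expect_true(all(q %in% 0:3))
  expect_equal(min(q), 0L)
  expect_equal(max(q), 3L)
  expect_true(all(diff(q[order(img)]) >= 0))  # monotone in the input
  expect_equal(quantize_image(matrix(0.7, 5, 5), 8),
               matrix(0L, 5, 5))
})

test_that("constant image yields the degenerate feature values", {
  f <- cooccurrence_features(matrix(0.4, 9, 9),
                             cooccurrence_config(levels = 8, window = 3))
  expect_equal(f$CON, matrix(0, 9, 9))
  expect_equal(f$ENT, matrix(0, 9, 9))
  expect_equal(f$ASM, matrix(1, 9, 9))
  expect_equal(f$VAR, matrix(0, 9, 9))
  expect_true(all(is.na(f$COR)))
})

test_that("features match the brute-force pair enumeration on small fixtures", {
  withr::with_seed(31, {
    for (rep in 1:4) {
      img <- matrix(runif(25), 5, 5)
      cfg <- cooccurrence_config(levels = 4, window = 3, distance = 1)
      f <- cooccurrence_features(img, cfg)
      q <- quantize_image(img, 4)
      for (r in c(1, 3, 5)) {
        for (c in c(1, 2, 4)) {
          o <- glcm_pixel_oracle(q, r, c, 4, 3, 1)
          expect_equal(f$VAR[r, c], o$VAR, tolerance = 1e-12)
          expect_equal(f$ENT[r, c], o$ENT, tolerance = 1e-12)
          expect_equal(f$CON[r, c], o$CON, tolerance = 1e-12)
          expect_equal(f$ASM[r, c], o$ASM, tolerance = 1e-12)
          if (is.nan(o$COR)) expect_true(is.na(f$COR[r, c]))
          else expect_equal(f$COR[r, c], o$COR, tolerance = 1e-12)
          # probability matrix invariants
          expect_true(all(o$P >= 0))
          expect_equal(sum(o$P), 1)
          expect_equal(o$P, t(o$P))
        }
      }
    }
  })
})

test_that("feature ranges hold on random images", {
  withr::with_seed(5, {
    img <- matrix(runif(400), 20, 20)
    f <- cooccurrence_features(img, cooccurrence_config(levels = 8))
    expect_true(all(f$ASM > 0 & f$ASM <= 1))
    expect_true(all(f$ENT >= 0))
    expect_true(all(f$CON >= 0))
    expect_true(all(f$VAR >= 0))
    fin <- f$COR[is.finite(f$COR)]
    expect_true(all(fin >= -1 - 1e-12 & fin <= 1 + 1e-12))
  })
})

test_that("window larger than the image errors", {
  expect_error(cooccurrence_features(matrix(runif(16), 4, 4),
                                     cooccurrence_config(window = 7)),
               "larger")
})

test_that("pca_scores recovers rank-1 structure and orders variance", {
  # rank-1 cube: band b = weight_b * pattern + tiny noise-free offset
  pattern <- outer(sin(seq(0, pi, length.out = 8)),
                   cos(seq(0, pi, length.out = 9)))
  w <- seq(1, 3, length.out = 5)
  arr <- array(0, c(5, 8, 9))
  for (b in 1:5) arr[b, , ] <- w[b] * pattern
  cube <- hyper_cube(arr, seq(500, 900, length.out = 5))
  p <- pca_scores(cube, k = 3)
  expect_gt(p$explained[1], 0.999)
  expect_true(all(diff(p$explained) <= 1e-12))
  expect_lte(sum(p$explained), 1 + 1e-12)
  # PC1 scores reproduce the spatial pattern up to affine scale
  expect_gt(abs(cor(as.vector(p$scores[[1]]), as.vector(pattern))), 0.999)
})

test_that("pca_scores equals the eigendecomposition route on random cubes", {
  cube <- random_cube(bands = 10, rows = 8, cols = 8, seed = 44)
  p <- pca_scores(cube, k = 3)
  X <- t(retained_matrix(cube))
  Xc <- sweep(X, 2, colMeans(X))
  ev <- eigen(cov(Xc), symmetric = TRUE)
  for (j in 1:3) {
    sc <- as.vector(Xc %*% ev$vectors[, j])
    expect_gt(abs(cor(sc, as.vector(p$scores[[j]]))), 1 - 1e-10)
  }
  expect_error(pca_scores(hyper_cube(array(0.5, c(4, 3, 3)),
                                     c(1, 2, 3, 4) * 100)),
               "degenerate|constant")
})

test_that("texture_stack yields 15 deterministically named layers", {
  cube <- random_cube(bands = 8, rows = 12, cols = 12, seed = 3)
  cfg <- cooccurrence_config(levels = 8, window = 3)
  fs <- texture_stack(cube, cfg)
  expect_length(fs$layers, 15)
  expect_true(all(c("ENT(PCA1)", "ASM(PCA2)", "VAR(PCA3)") %in% names(fs)))
  fs2 <- texture_stack(cube, cfg)
  expect_identical(fs$layers, fs2$layers)
})
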