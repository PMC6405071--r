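test_that("spectral_curve and pivot_pair validate their invariants", {
  expect_error(spectral_curve(numeric(0)), "at least one")
  expect_error(spectral_curve(c(0.1, 0.2), abscissa = 1), "equal length")
  expect_error(spectral_curve(c(0.1, 0.2), abscissa = c(2, 1)),
               "strictly increasing")
  expect_error(pivot_pair(3, 1), "must not exceed")
  sc <- spectral_curve(c(0.1, 0.2, 0.3))
  expect_equal(sc$n, 3L)
  expect_equal(sc$abscissa, c(0, 1, 2))
})

test_that("moment distances match hand-worked examples", {
  flat <- spectral_curve(rep(0, 4), 0:3)
  expect_equal(as.numeric(moment_distance_lp(flat)), 6)
  expect_equal(as.numeric(moment_distance_rp(flat)), 6)

  single <- spectral_curve(0.7, 0)
  expect_equal(as.numeric(moment_distance_lp(single, pivot_pair(0, 0))), 0.7)

  sc <- spectral_curve(c(0.1, 0.5, 0.2), 0:2)
  expect_equal(as.numeric(moment_distance_lp(sc)),
               0.1 + sqrt(0.5^2 + 1) + sqrt(0.2^2 + 4))
  expect_equal(as.numeric(moment_distance_rp(sc)),
               0.2 + sqrt(0.5^2 + 1) + sqrt(0.1^2 + 4))
})

test_that("md_metrics combines the sums per the definitions", {
  sym <- spectral_curve(c(0.2, 0.9, 0.2), 0:2)
  m <- md_metrics(sym)
  expect_equal(m$mdi, 0)
  expect_equal(m$mdin, 0)
  expect_equal(m$mdrlr, 1)
  expect_equal(m$mdrrl, 1)

  sc <- spectral_curve(c(0.1, 0.5, 0.2), 0:2)
  m <- md_metrics(sc)
  expect_equal(m$mdi,
               (0.2 + sqrt(1.25) + sqrt(4.01)) -
                 (0.1 + sqrt(1.25) + sqrt(4.04)))
  expect_true(m$mdin > -1 && m$mdin < 1)
  expect_equal(m$mdrlr * m$mdrrl, 1)
})

test_that("degenerate zero curves leave ratios undefined with a warning", {
  z <- spectral_curve(0, 0)
  expect_warning(m <- md_metrics(z, pivot_pair(0, 0)), "undefined")
  expect_true(is.nan(m$mdrlr))
  expect_true(is.nan(m$mdrrl))
  expect_true(is.nan(m$mdin))
})

test_that("NaN policy fails fast unless na_skip is set", {
  sc <- spectral_curve(c(0.1, NA, 0.2), 0:2)
  expect_error(moment_distance_lp(sc), "na_skip")
  v <- moment_distance_lp(sc, na_skip = TRUE)
  expect_equal(attr(v, "n_used"), 2L)
  expect_equal(as.numeric(v), 0.1 + sqrt(0.2^2 + 4))
})

test_that("pivot windows are validated", {
  sc <- spectral_curve(c(0.1, 0.2, 0.3), 0:2)
  expect_error(moment_distance_lp(sc, pivot_pair(0.5, 1.5)),
               "sample positions")
  expect_error(moment_distance_lp(sc, pivot_pair(5, 7)), "sample positions")
})

test_that("md_metrics agrees with the loop oracle on random curves", {
  withr::with_seed(42, {
    for (i in 1:200) {
      n <- sample(2:200, 1)
      rho <- runif(n)
      m <- md_metrics(spectral_curve(rho))
      o <- md_loop_oracle(rho, seq_len(n) - 1)
      expect_equal(m$md_lp, o$md_lp, tolerance = 1e-12)
      expect_equal(m$md_rp, o$md_rp, tolerance = 1e-12)
      expect_equal(m$mdrrl, o$mdrrl, tolerance = 1e-12)
    }
  })
})

test_that("reversal swaps pivots and identity chain holds", {
  withr::with_seed(7, {
    for (i in 1:50) {
      n <- sample(2:100, 1)
      rho <- runif(n)
      m <- md_metrics(spectral_curve(rho))
      r <- md_metrics(spectral_curve(rev(rho)))
      expect_equal(m$md_lp, r$md_rp, tolerance = 1e-12)
      expect_equal(m$md_rp, r$md_lp, tolerance = 1e-12)
      expect_lt(abs(m$mdi + r$mdi), 1e-10 * m$md_lp)
      expect_lt(abs(m$mdin + r$mdin), 1e-12)
      expect_equal(m$mdrlr, r$mdrrl, tolerance = 1e-12)
      # identity chain (absolute error bounded relative to the sums,
      # since the differences themselves can be near zero)
      expect_equal(m$mdin, (m$mdrrl - 1) / (m$mdrrl + 1), tolerance = 1e-10)
      expect_lt(abs(m$mdi - m$md_lp * (m$mdrrl - 1)), 1e-10 * m$md_lp)
      # boundedness for strictly positive curves
      mp <- md_metrics(spectral_curve(rho + 0.01))
      expect_true(mp$mdin > -1 && mp$mdin < 1)
    }
  })
})

test_that("widening the pivot window never decreases the sums", {
  withr::with_seed(12, {
    rho <- runif(30)
    sc <- spectral_curve(rho)
    prev_lp <- 0; prev_rp <- 0
    for (rp in 3:29) {
      m <- md_metrics(sc, pivot_pair(0, rp))
      expect_gte(m$md_lp, prev_lp)
      expect_gte(m$md_rp, 0)
      prev_lp <- m$md_lp
    }
  })
})

test_that("md_sweep accumulates moment distances band by band", {
  flat <- spectral_curve(rep(0, 4), 0:3)
  expect_equal(md_sweep(flat, "lp"), c(0, 1, 3, 6))

  sc <- spectral_curve(c(0.1, 0.5, 0.2), 0:2)
  sw <- md_sweep(sc, "lp")
  running <- cumsum(sqrt(c(0.1, 0.5, 0.2)^2 + (0:2)^2))
  expect_equal(sw, running)
  expect_equal(sw[3], as.numeric(moment_distance_lp(sc)))

  swr <- md_sweep(sc, "rp")
  expect_equal(swr[3], as.numeric(moment_distance_rp(sc)))
  expect_equal(swr[1], 0.2)  # starts at the right end

  expect_error(md_sweep(spectral_curve(0.5), "lp"), "at least two")
})

test_that("md_cube equals per-pixel md_metrics", {
  # constant cube: spatially invariant
  rho <- c(0.2, 0.6, 0.4, 0.1)
  cube <- hyper_cube(array(rep(rho, 6), c(4, 2, 3)),
                     c(450, 550, 650, 750))
  m <- md_metrics(spectral_curve(rho))
  expect_equal(md_cube(cube, metric = "MDI"),
               matrix(m$mdi, 2, 3))
  expect_equal(md_cube(cube, metric = "MDRRL"), matrix(m$mdrrl, 2, 3))

  # all-zero cube: MDI identically zero
  zc <- hyper_cube(array(0, c(4, 2, 2)), c(450, 550, 650, 750))
  expect_equal(md_cube(zc, metric = "MDI"), matrix(0, 2, 2))

  # 2x2 of distinct random curves: pixelwise oracle
  withr::with_seed(5, {
    arr <- array(runif(10 * 2 * 2), c(10, 2, 2))
    cube <- hyper_cube(arr, seq(400, 900, length.out = 10))
    for (metric in c("MDI", "MDIN", "MDRLR", "MDRRL")) {
      got <- md_cube(cube, metric = metric)
      for (r in 1:2) for (c in 1:2) {
        o <- md_loop_oracle(arr[, r, c], 0:9)
        expect_equal(got[r, c], o[[tolower(metric)]], tolerance = 1e-12)
      }
    }
  })
})

test_that("md_cube honors the band mask and validates pivots", {
  withr::with_seed(8, {
    arr <- array(runif(6 * 2 * 2), c(6, 2, 2))
    mask <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)
    cube <- hyper_cube(arr, seq(400, 900, length.out = 6), band_mask = mask)
    got <- md_cube(cube, metric = "MDRRL")
    o <- md_loop_oracle(arr[mask, 1, 2], 0:3)
    expect_equal(got[1, 2], o$mdrrl, tolerance = 1e-12)
    expect_error(md_cube(cube, pivot_pair(0, 5), metric = "MDI"),
                 "retained-band")
  })
})

test_that("reflectance scaling is a plain ordinate unit change", {
  rho <- c(0.1, 0.5, 0.2)
  cube <- hyper_cube(array(rho, c(3, 1, 1)), c(500, 600, 700))
  got <- md_cube(cube, metric = "MD_LP", reflectance_scale = 100)
  expect_equal(got[1, 1], md_loop_oracle(rho * 100, 0:2)$md_lp)
})
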