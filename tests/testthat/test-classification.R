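make_objects <- function(n_per_class, classes = seq_along(n_per_class),
                         seed = 1) {
  withr::with_seed(seed, {
    truth <- rep(classes, n_per_class)
    n <- length(truth)
    data.frame(object_id = seq_len(n), size = sample(1:20, n, TRUE),
               truth = truth,
               f1 = truth + rnorm(n, sd = 0.1),   # separating feature
               f2 = rnorm(n))                      # pure noise
  })
}

test_that("split_train_test stratifies at the requested fraction", {
  ob <- make_objects(c(100))
  sp <- split_train_test(ob, 0.3, seed = 4)
  expect_length(sp$train, 30)
  expect_length(sp$test, 70)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), 1:100)

  # same seed reproduces; different seed differs
  expect_identical(sp, split_train_test(ob, 0.3, seed = 4))
  expect_false(identical(sp, split_train_test(ob, 0.3, seed = 5)))

  # per-class counts equal round(fraction * n_c)
  ob2 <- make_objects(c(10, 23, 57, 8))
  sp2 <- split_train_test(ob2, 0.3, seed = 1)
  got <- table(ob2$truth[sp2$train])
  expect_equal(as.vector(got), round(0.3 * c(10, 23, 57, 8)))
})

test_that("split_train_test rejects classes with fewer than two objects", {
  ob <- make_objects(c(5, 1))
  expect_error(split_train_test(ob, 0.3), "2")
  ob0 <- data.frame(truth = c(0, 0))
  expect_error(split_train_test(ob0), "no labeled")
})

test_that("unlabeled objects stay out of both partitions", {
  ob <- make_objects(c(10, 10))
  ob$truth[c(3, 17)] <- 0L
  sp <- split_train_test(ob, 0.3, seed = 2)
  expect_false(any(c(3, 17) %in% c(sp$train, sp$test)))
  expect_length(c(sp$train, sp$test), 18)
})

test_that("run_set separates separable classes and ranks noise last", {
  ob <- make_objects(c(40, 40), classes = c(1, 2), seed = 6)
  sp <- split_train_test(ob, 0.3, seed = 6)
  rs <- run_set(ob, c("f1", "f2"), sp, seed = 6, ntree = 200)
  acc <- accuracy_assessment(rs$truth, rs$predictions)
  expect_equal(acc$report$oa, 100)
  expect_equal(rs$importance$feature, c("f1", "f2"))

  # determinism under seed
  rs2 <- run_set(ob, c("f1", "f2"), sp, seed = 6, ntree = 200)
  expect_identical(rs$predictions, rs2$predictions)
  expect_identical(rs$importance, rs2$importance)

  expect_error(run_set(ob, c("f1", "nope"), sp), "nope")
})

test_that("classification is robust to an index sign flip", {
  # a monotone sign flip preserves every split partition a tree can
  # make; individual trees may still break split-point ties in scan
  # order, so we assert agreement of the results, not bit-identity
  ob <- make_objects(c(30, 30, 30), classes = 1:3, seed = 9)
  sp <- split_train_test(ob, 0.3, seed = 9)
  rs <- run_set(ob, c("f1", "f2"), sp, seed = 11)
  ob_flip <- ob
  ob_flip$f1 <- -ob_flip$f1
  rs_flip <- run_set(ob_flip, c("f1", "f2"), sp, seed = 11)
  oa <- accuracy_assessment(rs$truth, rs$predictions)$report$oa
  oa_flip <- accuracy_assessment(rs_flip$truth, rs_flip$predictions)$report$oa
  expect_lt(abs(oa - oa_flip), 5)
  expect_gt(mean(as.character(rs$predictions) ==
                 as.character(rs_flip$predictions)), 0.9)
})

test_that("accuracy_assessment matches hand-computed matrices", {
  # diagonal: perfect
  acc <- accuracy_assessment(c(1, 1, 2, 3), c(1, 1, 2, 3))
  expect_equal(acc$report$oa, 100)
  expect_equal(acc$report$kappa, 1)
  expect_true(all(acc$report$pa == 100) && all(acc$report$ua == 100))

  # [[40,10],[20,30]]: OA 70, kappa 0.4 (p_o = .7, p_e = .5)
  truth <- rep(c("a", "a", "b", "b"), c(40, 10, 20, 30))
  pred <- rep(c("a", "b", "a", "b"), c(40, 10, 20, 30))
  acc <- accuracy_assessment(truth, pred)
  expect_equal(unname(acc$confusion),
               matrix(c(40, 20, 10, 30), 2, 2))
  expect_equal(acc$report$oa, 70)
  expect_equal(acc$report$kappa, 0.4)
  expect_equal(unname(acc$report$pa), c(80, 60))
  expect_equal(unname(acc$report$ua), c(200 / 3, 75))
})

test_that("accuracy_assessment equals brute-force counting on random labels", {
  withr::with_seed(23, {
    for (rep in 1:5) {
      truth <- sample(1:4, 200, TRUE)
      pred <- sample(1:4, 200, TRUE)
      acc <- accuracy_assessment(truth, pred)
      o <- accuracy_oracle(truth, pred)
      expect_equal(acc$report$oa, o$oa)
      expect_equal(acc$report$kappa, o$kappa)
      expect_equal(unname(acc$report$pa), o$pa)
      expect_equal(unname(acc$report$ua), o$ua)
    }
    # chance agreement with matched marginals gives kappa near 0
    truth <- sample(rep(1:2, 500))
    pred <- sample(rep(1:2, 500))
    expect_lt(abs(accuracy_assessment(truth, pred)$report$kappa), 0.1)
  })
})

test_that("degenerate accuracy inputs are handled", {
  expect_error(accuracy_assessment(integer(0), integer(0)), "empty")
  expect_error(accuracy_assessment(1:3, 1:2), "differ")
  # class 3 never predicted: its UA is NaN
  acc <- accuracy_assessment(c(1, 1, 3), c(1, 1, 1))
  expect_true(is.nan(unname(acc$report$ua["3"])))
  # kappa = 1 iff the matrix is diagonal with nonzero trace
  acc2 <- accuracy_assessment(c(1, 2, 2), c(1, 2, 2))
  expect_equal(acc2$report$kappa, 1)
  acc3 <- accuracy_assessment(c(1, 2, 2), c(1, 2, 1))
  expect_lt(acc3$report$kappa, 1)
})

test_that("weighted accuracy reweights objects by size", {
  truth <- c(1, 1, 2)
  pred <- c(1, 2, 2)
  w <- c(10, 1, 5)
  acc <- accuracy_assessment(truth, pred, weights = w)
  expect_equal(acc$report$oa, 100 * 15 / 16)
})

test_that("mcnemar_z follows the closed form", {
  # f12 = f21 = 0
  m0 <- mcnemar_z(c(1, 2), c(1, 2), c(1, 2))
  expect_equal(m0$z, 0)
  expect_false(m0$significant)

  # engineered f12 = 20, f21 = 10
  truth <- rep(1, 40)
  a <- c(rep(1, 20), rep(2, 10), rep(1, 5), rep(2, 5))
  b <- c(rep(2, 20), rep(1, 10), rep(1, 5), rep(2, 5))
  m <- mcnemar_z(a, b, truth)
  expect_equal(m$f12, 20)
  expect_equal(m$f21, 10)
  expect_equal(m$z, 10 / sqrt(30))
  expect_false(m$significant)  # 1.83 < 1.96

  # antisymmetry and the significance threshold
  m_swap <- mcnemar_z(b, a, truth)
  expect_equal(m_swap$z, -m$z)
  truth2 <- rep(1, 60)
  a2 <- rep(1, 60)
  b2 <- c(rep(2, 50), rep(1, 10))
  expect_true(mcnemar_z(a2, b2, truth2)$significant)
  expect_error(mcnemar_z(1:3, 1:3, 1:2), "length")
})

test_that("feature_set_specs reproduces the five-set structure", {
  sp <- feature_set_specs()
  expect_length(sp, 5)
  expect_length(sp$set1, 21)
  for (s in 2:5) expect_length(sp[[s]], 22)
  expect_setequal(setdiff(sp$set5, sp$set1), "MDI")
  expect_setequal(setdiff(sp$set2, sp$set1), "MDIN")
  expect_setequal(setdiff(sp$set3, sp$set1), "MDRLR")
  expect_setequal(setdiff(sp$set4, sp$set1), "MDRRL")
  expect_true(all(c("ENT(PCA1)", "ASM(PCA2)") %in% sp$set1))
})

test_that("run_experiment produces a coherent report bundle", {
  scn <- make_scene(scene_spec(rows = 48, cols = 48, seed = 2))
  cfg <- experiment_config(sets = c(1, 4, 5), ntree = 150, seed = 2)
  exp <- run_experiment(scn$cube, scn$truth, cfg)
  expect_named(exp$sets, c("set1", "set4", "set5"))
  expect_equal(exp$sets$set1$n_features, 21)
  expect_equal(exp$sets$set4$n_features, 22)
  expect_setequal(setdiff(exp$sets$set5$features, exp$sets$set1$features),
                  "MDI")
  # McNemar table covers all pairs of run sets
  expect_equal(nrow(exp$mcnemar), 3)
  # classified maps cover the scene with known classes
  expect_true(all(exp$sets$set4$map %in% 1:4))
  expect_equal(dim(exp$sets$set4$map), c(48L, 48L))
  # pixel-weighted accuracy is reported alongside object-weighted
  expect_true(is.numeric(exp$sets$set1$accuracy_pixel$report$oa))
})

test_that("errors inside a stage are labeled with the stage name", {
  scn <- make_scene(scene_spec(rows = 24, cols = 24,
                               wavelengths = default_wavelengths(20, c(400, 900)),
                               classes = default_classes(
                                 default_wavelengths(20, c(400, 900)),
                                 dip = c(470, 60, 0.05)),
                               seed = 1))
  expect_error(run_experiment(scn$cube, scn$truth, experiment_config(sets = 1)),
               "spectral_indices")
})
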