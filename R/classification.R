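#' The five feature-set definitions
#'
#' Set 1 holds the six comparison indices plus the 15 texture layers
#' (21 variables); sets 2-5 add exactly one moment-distance layer:
#' MDIN (set 2), MDRLR (set 3), MDRRL (set 4), MDI (set 5).
#'
#' @param k Number of PC score images behind the texture layers.
#' @return Named list of 5 character vectors of layer names.
#' @export
feature_set_specs <- function(k = 3L) {
  tex <- as.vector(t(outer(seq_len(k), c("VAR", "ENT", "COR", "CON", "ASM"),
                           function(j, f) sprintf("%s(PCA%d)", f, j))))
  base <- c(index_names(), tex)
  list(set1 = base,
       set2 = c(base, "MDIN"),
       set3 = c(base, "MDRLR"),
       set4 = c(base, "MDRRL"),
       set5 = c(base, "MDI"))
}

#' Stratified train/test split of labeled objects
#'
#' Samples `round(fraction * n_c)` training objects per class (clamped to
#' keep at least one object on each side), the rest becoming the test
#' set. Reproducible under `seed`; the global RNG state is left
#' untouched.
#'
#' @param objects `data.frame` with a `truth` column (0 = unlabeled,
#'   excluded).
#' @param fraction Training fraction per class, default 0.30.
#' @param seed Integer seed.
#' @return List with integer row-index vectors `train` and `test`
#'   (disjoint, exhaustive over labeled objects).
#' @export
split_train_test <- function(objects, fraction = 0.30, seed = 1L) {
  if (!"truth" %in% names(objects)) stop("objects must carry a 'truth' column")
  lab <- which(objects$truth > 0L)
  if (!length(lab)) stop("no labeled objects")
  classes <- sort(unique(objects$truth[lab]))
  sizes <- table(objects$truth[lab])
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    stop("class ", paste(small, collapse = ", "),
         " has fewer than 2 labeled objects")
  }
  train <- withr::with_seed(seed, {
    unlist(lapply(classes, function(cl) {
      idx <- lab[objects$truth[lab] == cl]
      n_tr <- min(max(round(fraction * length(idx)), 1L), length(idx) - 1L)
      sort(sample(idx, n_tr))
    }), use.names = FALSE)
  })
  train <- sort(train)
  list(train = train, test = setdiff(lab, train))
}

#' Train and evaluate a random forest on one feature set
#'
#' Fits a bagged CART ensemble (random forest) on the training objects'
#' features, predicts the test objects, and returns the permutation
#' variable importance: mean decrease in out-of-bag accuracy under
#' permutation, normalized by its standard deviation. Deterministic
#' under `seed`.
#'
#' @param objects Object table (see [object_means()]) with a `truth`
#'   column.
#' @param features Character vector of feature column names.
#' @param split A list with `train`/`test` from [split_train_test()].
#' @param seed Integer seed.
#' @param ntree Number of trees (default 500).
#' @param mtry Candidate features per split; default `floor(sqrt(F))`.
#' @param importance_type `"permutation"` (default, scaled mean decrease
#'   in accuracy) or `"gini"` (mean decrease in node impurity).
#' @param keep_model Keep the fitted forest in the result.
#' @return List with `predictions` (factor, test objects), `truth`
#'   (factor), `test_idx`, `importance` (`data.frame` of `feature`,
#'   `score`, descending, ties broken lexicographically), `all_predictions`
#'   (factor over every object row), and optionally `model`.
#' @export
run_set <- function(objects, features, split, seed = 1L, ntree = 500L,
                    mtry = NULL, importance_type = c("permutation", "gini"),
                    keep_model = FALSE) {
  importance_type <- match.arg(importance_type)
  missing_f <- setdiff(features, names(objects))
  if (length(missing_f)) {
    stop("objects lack feature layer(s): ", paste(missing_f, collapse = ", "))
  }
  xtr <- objects[split$train, features, drop = FALSE]
  ytr <- factor(objects$truth[split$train])
  xte <- objects[split$test, features, drop = FALSE]
  if (any(!is.finite(as.matrix(xtr))) || any(!is.finite(as.matrix(xte)))) {
    stop("non-finite feature values in the train/test objects")
  }
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(length(features))))
  fit <- withr::with_seed(seed, {
    randomForest::randomForest(
      x = xtr, y = ytr, ntree = ntree, mtry = mtry,
      importance = (importance_type == "permutation"))
  })
  pred <- predict(fit, xte)
  # map painting covers every object; impute the rare non-finite object
  # mean (e.g. COR over a constant window) with the training mean
  xall <- objects[, features, drop = FALSE]
  for (j in seq_along(xall)) {
    bad <- !is.finite(xall[[j]])
    if (any(bad)) xall[[j]][bad] <- mean(xtr[[j]])
  }
  all_pred <- predict(fit, xall)
  imp <- if (importance_type == "permutation") {
    randomForest::importance(fit, type = 1L, scale = TRUE)[, 1L]
  } else {
    randomForest::importance(fit, type = 2L)[, 1L]
  }
  ranking <- data.frame(feature = names(imp), score = as.numeric(imp),
                        row.names = NULL)
  ranking <- ranking[order(-ranking$score, ranking$feature), ]
  rownames(ranking) <- NULL
  out <- list(predictions = pred,
              truth = factor(objects$truth[split$test],
                             levels = levels(ytr)),
              test_idx = split$test,
              importance = ranking,
              all_predictions = all_pred)
  if (keep_model) out$model <- fit
  out
}

#' Confusion matrix and accuracy report
#'
#' Builds the class-by-class confusion matrix (rows = reference,
#' columns = predicted) and the standard accuracy measures: overall
#' accuracy `OA = 100 trace/total`, per-class producer's accuracy
#' `PA_c = 100 M_cc / row_c` (omission), user's accuracy
#' `UA_c = 100 M_cc / col_c` (commission), and the kappa coefficient
#' `(p_o - p_e) / (1 - p_e)` with `p_e = sum(row_c col_c) / total^2`.
#' Empty reference rows / prediction columns give `NaN` PA / UA.
#'
#' @param truth,predicted Equal-length vectors (coerced to a common
#'   factor).
#' @param weights Optional non-negative sample weights (e.g. object pixel
#'   counts, for pixel-weighted accuracies).
#' @return List with `confusion` (integer or numeric matrix) and `report`
#'   (list `oa`, `kappa`, `pa`, `ua`; accuracies in percent).
#' @export
accuracy_assessment <- function(truth, predicted, weights = NULL) {
  if (length(truth) == 0L) stop("empty assessment input")
  if (length(truth) != length(predicted)) {
    stop("truth and predicted lengths differ")
  }
  lev <- sort(unique(c(as.character(truth), as.character(predicted))))
  tr <- factor(as.character(truth), levels = lev)
  pr <- factor(as.character(predicted), levels = lev)
  if (is.null(weights)) weights <- rep(1, length(tr))
  cm <- tapply(weights, list(tr, pr), sum, default = 0)
  cm <- matrix(cm, length(lev), length(lev),
               dimnames = list(reference = lev, predicted = lev))
  total <- sum(cm)
  diagc <- diag(cm)
  rowc <- rowSums(cm)
  colc <- colSums(cm)
  p_o <- sum(diagc) / total
  p_e <- sum(rowc * colc) / total^2
  kappa <- if (p_e < 1) (p_o - p_e) / (1 - p_e) else NaN
  report <- list(
    oa = 100 * p_o,
    kappa = kappa,
    pa = ifelse(rowc > 0, 100 * diagc / rowc, NaN),
    ua = ifelse(colc > 0, 100 * diagc / colc, NaN))
  list(confusion = cm, report = report)
}

#' McNemar's Z for two classifiers on shared samples
#'
#' With `f12` the number of samples classifier A gets right and B wrong,
#' and `f21` the converse, `Z = (f12 - f21) / sqrt(f12 + f21)` (0 when
#' both are 0). `Z > 0` means A is the more accurate; `|Z| > 1.96` marks
#' a difference significant at the 5% level.
#'
#' @param pred_a,pred_b Predictions of the two classifiers.
#' @param truth Reference labels, same length.
#' @return List with `z`, `f12`, `f21`, `significant`.
#' @export
mcnemar_z <- function(pred_a, pred_b, truth) {
  if (length(pred_a) != length(truth) || length(pred_b) != length(truth)) {
    stop("pred_a, pred_b and truth must have equal length")
  }
  ca <- as.character(pred_a) == as.character(truth)
  cb <- as.character(pred_b) == as.character(truth)
  f12 <- sum(ca & !cb)
  f21 <- sum(!ca & cb)
  z <- if (f12 + f21 == 0L) 0 else (f12 - f21) / sqrt(f12 + f21)
  list(z = z, f12 = f12, f21 = f21, significant = abs(z) > 1.96)
}

#' Experiment configuration
#'
#' Collects every tunable of the end-to-end pipeline with its default.
#'
#' @param ranges [band_ranges()].
#' @param pivots [pivot_pair()] or `NULL` for the full spectrum.
#' @param abscissa `"index"` or `"wavelength"` for the MD abscissa.
#' @param reflectance_scale Reflectance multiplier for the MD layers
#'   (see [md_cube()]); default 1.
#' @param texture [cooccurrence_config()].
#' @param scale Segmentation scale.
#' @param split_fraction Training fraction.
#' @param ntree,mtry Random-forest parameters.
#' @param importance_type `"permutation"` or `"gini"`.
#' @param sets Which of the five feature sets to run (default all).
#' @param connectivity Segmentation connectivity (4 or 8).
#' @param standard_orientation Conventional NDVI sign (default printed
#'   orientation).
#' @param seed Integer master seed.
#' @return Named list of class `experiment_config`.
#' @export
experiment_config <- function(ranges = band_ranges(), pivots = NULL,
                              abscissa = "index", reflectance_scale = 1,
                              texture = cooccurrence_config(),
                              scale = 5, split_fraction = 0.30,
                              ntree = 500L, mtry = NULL,
                              importance_type = "permutation",
                              sets = 1:5, connectivity = 4L,
                              standard_orientation = FALSE, seed = 1L) {
  structure(list(ranges = ranges, pivots = pivots, abscissa = abscissa,
                 reflectance_scale = reflectance_scale,
                 texture = texture, scale = scale,
                 split_fraction = split_fraction, ntree = as.integer(ntree),
                 mtry = mtry, importance_type = importance_type,
                 sets = sets, connectivity = as.integer(connectivity),
                 standard_orientation = standard_orientation,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run the full object-based classification experiment
#'
#' End-to-end pipeline: compute the six comparison indices, the four
#' moment-distance rasters and the 15 texture layers; segment the scene
#' once on the full feature stack; aggregate per-object feature means
#' and majority ground-truth labels; split the labeled objects into
#' train/test; then, for each requested feature set, train/evaluate the
#' random forest and report the object-weighted and pixel-weighted
#' accuracy, the importance ranking, and the per-pixel classified map.
#' All pairwise McNemar Z statistics over the shared test objects are
#' included. Fully deterministic under the config seed.
#'
#' @param cube A [hyper_cube()].
#' @param truth Integer `rows x cols` ground-truth raster (0 = unlabeled).
#' @param config An [experiment_config()].
#' @return List of class `md_experiment`: `sets` (per-set results),
#'   `mcnemar` (data.frame of pairwise comparisons), `segments`,
#'   `objects`, `split`, `features`, `config`.
#' @export
run_experiment <- function(cube, truth, config = experiment_config()) {
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", what, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  idx <- stage("spectral_indices",
               spectral_index_stack(cube, ranges = config$ranges,
                 standard_orientation = config$standard_orientation))
  md <- stage("md_core",
              md_stack(cube, config$pivots, abscissa = config$abscissa,
                       reflectance_scale = config$reflectance_scale))
  tex <- stage("texture", texture_stack(cube, config$texture))
  features <- fs_bind(idx, md, tex)
  seg <- stage("segmentation",
               segment_scene(features, config$scale,
                             connectivity = config$connectivity))
  objects <- stage("object_means", object_means(features, seg))
  objects$truth <- majority_label(seg, truth)
  split <- stage("split", split_train_test(objects, config$split_fraction,
                                           seed = config$seed))
  specs <- feature_set_specs()[config$sets]
  sets <- vector("list", length(specs))
  names(sets) <- names(specs)
  for (i in seq_along(specs)) {
    nm <- names(specs)[i]
    rs <- stage(nm, run_set(objects, specs[[i]], split,
                            seed = config$seed + i,
                            ntree = config$ntree, mtry = config$mtry,
                            importance_type = config$importance_type))
    acc_obj <- accuracy_assessment(rs$truth, rs$predictions)
    acc_pix <- accuracy_assessment(rs$truth, rs$predictions,
                                   weights = objects$size[split$test])
    map <- matrix(as.integer(as.character(
      rs$all_predictions[seg$labels])), nrow(seg$labels), ncol(seg$labels))
    sets[[i]] <- list(set_id = nm, features = specs[[i]],
                      n_features = length(specs[[i]]),
                      predictions = rs$predictions, truth = rs$truth,
                      accuracy = acc_obj, accuracy_pixel = acc_pix,
                      importance = rs$importance, map = map)
  }
  pairs <- if (length(sets) > 1L) utils::combn(names(sets), 2L) else NULL
  mcn <- NULL
  if (!is.null(pairs)) {
    mcn <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1L, j]; b <- pairs[2L, j]
      m <- mcnemar_z(sets[[a]]$predictions, sets[[b]]$predictions,
                     sets[[a]]$truth)
      data.frame(set_a = a, set_b = b, z = m$z, f12 = m$f12, f21 = m$f21,
                 significant = m$significant)
    }))
  }
  structure(list(sets = sets, mcnemar = mcn, segments = seg,
                 objects = objects, split = split, features = features,
                 config = config),
            class = "md_experiment")
}

#' @export
print.md_experiment <- function(x, ...) {
  cat("<md_experiment> ", x$segments$n_segments, " objects at scale ",
      x$config$scale, "; ", length(x$split$train), " train / ",
      length(x$split$test), " test\n", sep = "")
  for (nm in names(x$sets)) {
    s <- x$sets[[nm]]
    cat(sprintf("  %s (%d vars): OA = %.1f%%, kappa = %.3f, top = %s\n",
                nm, s$n_features, s$accuracy$report$oa,
                s$accuracy$report$kappa, s$importance$feature[1L]))
  }
  invisible(x)
}
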