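# two well-separated classes on 5 bands; optionally identical classes
toy_two_class <- function(n = 30, sep = 4, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * 5), n, 5),
             matrix(rnorm(n * 5, mean = sep), n, 5))
  annotation_set(
    data.frame(image_id = rep(sprintf("img_%d", 1:6), length.out = 2 * n),
               x = seq_len(2 * n), y = 1L,
               class = rep(c(0L, 1L), each = n)),
    x)
}

test_that("classifier_spec validates families and hyperparameters", {
  sp <- classifier_spec("lda")
  expect_equal(sp$family, "LDA")
  expect_error(classifier_spec("CNN"), "unknown classifier family")
  expect_error(classifier_spec("RF", list(bogus = 1)), "bogus")
  expect_equal(classifier_spec("PLS-DA")$hyperparams$n_components, 10)
  ann_def <- classifier_spec("ANN")$hyperparams
  expect_equal(ann_def$hidden_layers, 4)
  expect_equal(ann_def$units, 300)
  expect_equal(ann_def$learning_rate, 5e-4)
})

test_that("every family separates well-separated classes", {
  ann <- toy_two_class()
  for (fam in c("MLR", "SVM", "LDA", "QDA", "PLS-DA", "RF", "LASSO")) {
    hp <- switch(fam, "RF" = list(ntree = 50), "PLS-DA" = list(n_components = 2),
                 "LASSO" = list(nfolds = 3), list())
    m <- train_classifier(classifier_spec(fam, hp), ann)
    pred <- predict_pixels(m, ann)
    expect_equal(pixel_accuracy(pred$labels, ann$records$class)$average, 1,
                 info = fam)
    if (!is.null(pred$prob))
      expect_equal(unname(rowSums(pred$prob)), rep(1, n_annotations(ann)),
                   tolerance = 1e-9)
  }
  m_ann <- train_classifier(
    classifier_spec("ANN", list(hidden_layers = 2, units = 16,
                                learning_rate = 0.05, epochs = 100)), ann)
  pred <- predict_pixels(m_ann, ann)
  expect_gte(pixel_accuracy(pred$labels, ann$records$class)$average, 0.95)
})

test_that("indistinguishable classes give chance-level accuracy", {
  set.seed(3)
  x <- matrix(rnorm(120 * 4), 120, 4)
  ann <- annotation_set(
    data.frame(image_id = "img_1", x = 1:120, y = 1L,
               class = rep(c(0L, 1L), each = 60)),
    x)
  m <- train_classifier(classifier_spec("LDA"), ann)
  pred <- predict_pixels(m, ann)
  acc <- pixel_accuracy(pred$labels, ann$records$class)$average
  expect_gt(acc, 0.35); expect_lt(acc, 0.75)
})

test_that("training rejects degenerate inputs and band mismatches", {
  set.seed(1)
  one_cls <- annotation_set(
    data.frame(image_id = "a", x = 1:10, y = 1L, class = rep(1L, 10)),
    matrix(rnorm(50), 10, 5))
  expect_error(train_classifier(classifier_spec("LDA"), one_cls),
               "two classes")
  ann <- toy_two_class()
  m <- train_classifier(classifier_spec("LDA"), ann)
  expect_error(predict_pixels(m, matrix(0, 3, 7)), "band count")
  empty <- predict_pixels(m, matrix(numeric(), 0, 5))
  expect_length(empty$labels, 0)
})

test_that("QDA survives more bands than per-class records via its ridge", {
  set.seed(8)
  n <- 12; b <- 30  # n per class < B: plain class covariances are singular
  x <- rbind(matrix(rnorm(n * b), n, b), matrix(rnorm(n * b, 3), n, b))
  ann <- annotation_set(
    data.frame(image_id = "a", x = 1:(2 * n), y = 1L,
               class = rep(c(0L, 2L), each = n)), x)
  m <- train_classifier(classifier_spec("QDA"), ann)
  pred <- predict_pixels(m, ann)
  expect_equal(pixel_accuracy(pred$labels, ann$records$class)$average, 1)
})

test_that("pixel_accuracy matches hand counts and pools correctly", {
  t1 <- pixel_accuracy(c(0, 1, 1, 1), c(0, 0, 1, 1))
  expect_equal(unname(t1$per_class["background"]), 0.5)
  expect_equal(unname(t1$per_class["leaf"]), 1.0)
  expect_equal(t1$average, 0.75)

  ident <- pixel_accuracy(0:3, 0:3)
  expect_true(all(ident$per_class == 1))
  expect_equal(ident$average, 1)

  expect_error(pixel_accuracy(1:3, 1:4), "equal length")

  # pooled average equals brute-force total correct / total scored
  set.seed(11)
  truth <- sample(0:3, 200, replace = TRUE)
  pred <- sample(0:3, 200, replace = TRUE)
  expect_equal(pixel_accuracy(pred, truth)$average,
               sum(pred == truth) / 200)

  excl <- pixel_accuracy(pred, truth, exclude_classes = 3)
  keep <- truth != 3
  expect_equal(excl$average_excluding,
               sum(pred[keep] == truth[keep]) / sum(keep))
})

test_that("cross-validation partitions whole images and never leaks", {
  ann <- small_annotations()
  cv <- crossvalidate(classifier_spec("LDA"), ann, k = 5, seed = 2)
  folds <- cv$fold_of_image
  expect_equal(sort(unique(folds)), 1:5)
  expect_lte(diff(range(table(folds))), 1)
  # every record predicted exactly once, in its image's fold
  expect_equal(cv$oof$fold,
               unname(folds[cv$oof$image_id]))
  # leak check: image ids in each test fold never appear in that training fold
  for (f in 1:5) {
    test_ids <- names(folds)[folds == f]
    train_ids <- names(folds)[folds != f]
    expect_length(intersect(test_ids, train_ids), 0)
  }
  # determinism of fold assignment
  cv2 <- crossvalidate(classifier_spec("LDA"), ann, k = 5, seed = 2)
  expect_identical(cv$fold_of_image, cv2$fold_of_image)
  expect_equal(cv$accuracy$average, cv2$accuracy$average)

  expect_error(crossvalidate(classifier_spec("LDA"), ann, k = 50),
               "at least k")
})

test_that("LDA reaches high out-of-fold accuracy on generator output", {
  cv <- crossvalidate(classifier_spec("LDA"), small_annotations(),
                      k = 5, seed = 2)
  expect_gte(cv$accuracy$average, 0.95)
})

test_that("linearly separable classes give near-perfect out-of-fold accuracy", {
  ann <- toy_two_class(n = 60, sep = 6)
  for (fam in c("LDA", "MLR")) {
    cv <- crossvalidate(classifier_spec(fam), ann, k = 3, seed = 1)
    expect_gte(cv$accuracy$average, 0.99)
  }
})

test_that("transfer evaluation flags a shifted foreign class", {
  ann <- small_annotations()
  model <- train_classifier(classifier_spec("LDA"), ann)

  # self-transfer equals training accuracy
  self_acc <- transfer_evaluate(model, ann)
  train_acc <- pixel_accuracy(predict_pixels(model, ann)$labels,
                              ann$records$class)
  expect_equal(self_acc$average, train_acc$average)

  # foreign set whose class-3 signature is strongly shifted (tassel vs
  # panicle): class 3 accuracy collapses, other classes stay high
  foreign <- ann
  shift <- foreign$records$class == 3
  foreign$spectra[shift, ] <- pmin(1, foreign$spectra[shift, ] + 0.35)
  tab <- transfer_evaluate(model, foreign, exclude_classes = 3)
  expect_lt(unname(tab$per_class["panicle"]), 0.5)
  expect_gte(min(tab$per_class[c("background", "leaf", "stalk")]), 0.9)
  # the excluding-average recomputes over classes 0-2 only
  keep <- foreign$records$class != 3
  pred <- predict_pixels(model, foreign)$labels
  expect_equal(tab$average_excluding,
               mean(pred[keep] == foreign$records$class[keep]))
})

test_that("Gini importance concentrates on informative bands", {
  set.seed(4)
  n <- 80; b <- 30
  x <- matrix(rnorm(n * b, 0.5, 0.05), n, b)
  cls <- rep(c(0L, 1L), each = n / 2)
  x[cls == 1, 10:14] <- x[cls == 1, 10:14] + 0.4  # signal only in bands 10-14
  ann <- annotation_set(
    data.frame(image_id = "a", x = 1:n, y = 1L, class = cls), x)
  m <- train_classifier(classifier_spec("RF", list(ntree = 200)), ann)
  prof <- gini_importance(m, wavelength_nm = seq_len(b))
  expect_length(prof$importance, b)
  expect_true(all(prof$importance >= 0))
  top5 <- order(prof$importance, decreasing = TRUE)[1:5]
  expect_setequal(top5, 10:14)
  expect_error(gini_importance(train_classifier(classifier_spec("LDA"),
                                                ann)), "random-forest")
})

test_that("important_regions reports maximal runs as wavelength intervals", {
  wl <- band_wavelengths(243, 546, 1700)
  imp <- rep(0, 243)
  prof <- structure(list(importance = imp, wavelength_nm = wl),
                    class = "importance_profile")
  expect_equal(nrow(important_regions(prof)), 0)

  # bands whose wavelengths span 1123-1218 nm exceed the threshold
  in_r2 <- wl >= 1123 & wl <= 1218
  imp2 <- imp; imp2[in_r2] <- 15
  prof2 <- structure(list(importance = imp2, wavelength_nm = wl),
                     class = "importance_profile")
  reg <- important_regions(prof2, threshold = 10)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$wl_start, min(wl[in_r2]))
  expect_equal(reg$wl_end, max(wl[in_r2]))
  expect_lte(abs(reg$wl_start - 1123), diff(wl)[1])
  expect_lte(abs(reg$wl_end - 1218), diff(wl)[1])

  # two separated runs come back in ascending order, and sub-threshold
  # noise elsewhere does not perturb them
  imp3 <- imp2; imp3[wl >= 599 & wl <= 789] <- 12
  set.seed(5)
  imp3 <- imp3 + runif(243, 0, 5)  # stays below threshold where zero
  prof3 <- structure(list(importance = imp3, wavelength_nm = wl),
                     class = "importance_profile")
  reg3 <- important_regions(prof3, threshold = 10)
  expect_equal(nrow(reg3), 2)
  expect_true(all(diff(reg3$wl_start) > 0))
  expect_lt(reg3$wl_start[1], 789)
})

test_that("ordination separates classes and reports sane variance fractions", {
  ann <- small_annotations()
  ord <- ordination(ann, "PCA", n_components = 2)
  expect_true(all(ord$variance_explained >= 0 &
                    ord$variance_explained <= 1))
  expect_true(all(diff(ord$variance_explained) <= 0))
  # leaf vs background separated in the PC1-PC2 plane: centroid distance
  # exceeds 3x the pooled within-class spread
  leaf <- ord$scores[ord$class == 1, ]
  bg <- ord$scores[ord$class == 0, ]
  gap <- sqrt(sum((colMeans(leaf) - colMeans(bg))^2))
  spread <- sqrt(mean(c(apply(leaf, 2, var), apply(bg, 2, var))))
  expect_gt(gap, 3 * spread)

  # data on an exact 2-plane: two PCs explain everything
  set.seed(6)
  basis <- matrix(rnorm(10 * 2), 2, 10)
  flat <- matrix(rnorm(100 * 2), 100, 2) %*% basis
  ann_flat <- annotation_set(
    data.frame(image_id = "a", x = 1:100, y = 1L,
               class = rep(0:1, 50)), flat)
  ord2 <- ordination(ann_flat, "PCA", n_components = 2)
  expect_equal(sum(ord2$variance_explained), 1, tolerance = 1e-9)

  const <- annotation_set(
    data.frame(image_id = "a", x = 1:10, y = 1L, class = rep(0:1, 5)),
    matrix(1, 10, 4))
  expect_error(ordination(const), "degenerate")

  lda_ord <- ordination(ann, "LDA-projection", n_components = 2)
  expect_equal(ncol(lda_ord$scores), 2)
})

test_that("the ANN sweep enumerates the full hyperparameter grid", {
  grid <- enumerate_ann_grid(seed = 1)
  expect_length(grid, 600)
  lrs <- vapply(grid, function(s) s$hyperparams$learning_rate, numeric(1))
  expect_true(all(lrs >= 1e-6 & lrs <= 1e-3))
  combos <- unique(data.frame(
    d = vapply(grid, function(s) s$hyperparams$hidden_layers, numeric(1)),
    w = vapply(grid, function(s) s$hyperparams$units, numeric(1))))
  expect_equal(nrow(combos), 15)

  expect_length(enumerate_ann_grid(n_lr = 1), 15)
  expect_identical(
    vapply(enumerate_ann_grid(seed = 7), function(s)
      s$hyperparams$learning_rate, numeric(1)),
    vapply(enumerate_ann_grid(seed = 7), function(s)
      s$hyperparams$learning_rate, numeric(1)))
})
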