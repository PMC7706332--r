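CLASSIFIER_FAMILIES <- c("MLR", "SVM", "LDA", "QDA", "PLS-DA", "RF",
                         "LASSO", "ANN")

#' Classifier specification
#'
#' Names one of the eight supported per-pixel classifier families together
#' with its hyperparameters. Defaults follow common practice for spectral
#' classification: PLS-DA uses 10 components; the random forest 500 trees
#' with sqrt(B) candidate features per split; the SVM an RBF kernel with
#' cost 1 and gamma 1/B; the LASSO a multinomial fit with its penalty
#' chosen by internal cross-validation; the neural network is a multilayer
#' perceptron with 4 hidden layers of 300 ReLU units, softmax output and
#' minibatch SGD at learning rate 5e-4 (200 epochs, batch 32).
#'
#' @param family one of `"MLR"`, `"SVM"`, `"LDA"`, `"QDA"`, `"PLS-DA"`,
#'   `"RF"`, `"LASSO"`, `"ANN"`.
#' @param hyperparams named list of family-specific settings; unknown names
#'   are rejected.
#' @param seed integer seed used wherever the family trains stochastically.
#' @return An object of class `"classifier_spec"`.
#' @export
classifier_spec <- function(family, hyperparams = list(), seed = 1) {
  family <- toupper(family)
  if (family == "PLSDA") family <- "PLS-DA"
  if (!family %in% CLASSIFIER_FAMILIES)
    stop(sprintf("unknown classifier family '%s'; choose one of %s", family,
                 paste(CLASSIFIER_FAMILIES, collapse = ", ")), call. = FALSE)
  defaults <- switch(family,
    "MLR" = list(maxit = 200),
    "SVM" = list(kernel = "radial", cost = 1, gamma = NULL),
    "LDA" = list(),
    "QDA" = list(ridge_scale = 1e-6),
    "PLS-DA" = list(n_components = 10),
    "RF" = list(ntree = 500, mtry = NULL),
    "LASSO" = list(nfolds = 5, nlambda = 30),
    "ANN" = list(hidden_layers = 4, units = 300, learning_rate = 5e-4,
                 epochs = 200, batch_size = 32))
  unknown <- setdiff(names(hyperparams), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown hyperparameter(s) for %s: %s", family,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  defaults[names(hyperparams)] <- hyperparams
  structure(list(family = family, hyperparams = defaults,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Enumerate a neural-network hyperparameter sweep
#'
#' Builds the full grid of multilayer-perceptron configurations: every
#' combination of hidden-layer count and layer width, each paired with
#' `n_lr` learning rates drawn uniformly from `[lr_low, lr_high]`
#' (deterministic given the seed). The default grid of 3 depths x 5 widths
#' x 40 rates yields 600 specifications; with one rate per architecture it
#' reduces to the 15 distinct architectures.
#'
#' @param depths integer vector of hidden-layer counts (default 2, 3, 4).
#' @param widths integer vector of units per hidden layer (default 200,
#'   250, 300, 350, 400).
#' @param lr_low,lr_high learning-rate range (default 1e-6 to 1e-3).
#' @param n_lr learning rates sampled per architecture (default 40).
#' @param seed integer RNG seed.
#' @return A list of [classifier_spec] objects of length
#'   `length(depths) * length(widths) * n_lr`.
#' @export
enumerate_ann_grid <- function(depths = c(2, 3, 4),
                               widths = c(200, 250, 300, 350, 400),
                               lr_low = 1e-6, lr_high = 1e-3, n_lr = 40,
                               seed = 1) {
  if (length(depths) == 0L || length(widths) == 0L || n_lr < 1)
    stop("`depths`, `widths` must be nonempty and `n_lr` >= 1",
         call. = FALSE)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  specs <- list()
  for (d in depths) for (w in widths) {
    lrs <- stats::runif(n_lr, lr_low, lr_high)
    for (lr in lrs)
      specs[[length(specs) + 1L]] <- classifier_spec(
        "ANN", list(hidden_layers = d, units = w, learning_rate = lr),
        seed = seed)
  }
  specs
}

#' Train a per-pixel classifier on labeled spectra
#'
#' Fits the family named by `spec` to the annotation set's spectra. At
#' least two classes with at least two records each are required. The
#' returned model classifies new spectra via [predict_pixels()] and, where
#' the family supports it, also reports class probabilities.
#'
#' @param spec a [classifier_spec].
#' @param annotations an [annotation_set].
#' @return An object of class `"hyperseg_model"`.
#' @export
train_classifier <- function(spec, annotations) {
  stopifnot(inherits(spec, "classifier_spec"),
            inherits(annotations, "annotation_set"))
  x <- annotations$spectra
  colnames(x) <- paste0("b", seq_len(ncol(x)))
  y <- annotations$records$class
  tab <- table(y)
  if (length(tab) < 2L)
    stop("training data must contain at least two classes", call. = FALSE)
  if (any(tab < 2L))
    stop("every class needs at least two training records", call. = FALSE)
  classes <- sort(unique(y))
  yf <- factor(y, levels = classes)
  hp <- spec$hyperparams
  old <- set_local_seed(spec$seed)
  on.exit(restore_seed(old), add = TRUE)

  fit <- switch(spec$family,
    "MLR" = {
      df <- data.frame(.class = yf, x)
      nnet::multinom(.class ~ ., data = df, trace = FALSE,
                     maxit = hp$maxit, MaxNWts = 1e5)
    },
    "SVM" = {
      gamma <- if (is.null(hp$gamma)) 1 / ncol(x) else hp$gamma
      e1071::svm(x, yf, kernel = hp$kernel, cost = hp$cost, gamma = gamma,
                 probability = TRUE)
    },
    "LDA" = MASS::lda(x, grouping = yf),
    "QDA" = qda_ridge_fit(x, yf, ridge_scale = hp$ridge_scale),
    "PLS-DA" = mixOmics::plsda(x, yf, ncomp = hp$n_components),
    "RF" = {
      mtry <- if (is.null(hp$mtry)) max(1L, floor(sqrt(ncol(x)))) else
        hp$mtry
      randomForest::randomForest(x, yf, ntree = hp$ntree, mtry = mtry,
                                 importance = TRUE)
    },
    "LASSO" = glmnet::cv.glmnet(x, yf, family = "multinomial",
                                nfolds = hp$nfolds, nlambda = hp$nlambda),
    "ANN" = mlp_fit(x, yf,
                    hidden = rep(hp$units, hp$hidden_layers),
                    lr = hp$learning_rate, epochs = hp$epochs,
                    batch_size = hp$batch_size))

  structure(list(spec = spec, fit = fit, classes = classes,
                 n_bands = ncol(x)),
            class = "hyperseg_model")
}

#' @export
print.hyperseg_model <- function(x, ...) {
  cat(sprintf("<hyperseg_model> %s, %d bands, classes: %s\n",
              x$spec$family, x$n_bands, paste(x$classes, collapse = " ")))
  invisible(x)
}

#' Classify pixel spectra
#'
#' @param model a [train_classifier()] model.
#' @param features a `flatten_cube()` feature array, a plain `n x B`
#'   matrix, or an [annotation_set] (whose spectra are used).
#' @return A list with `labels` (integer codes) and `prob` (an `n x K`
#'   matrix of class probabilities, rows summing to 1, or `NULL` for
#'   families without calibrated probabilities).
#' @export
predict_pixels <- function(model, features) {
  stopifnot(inherits(model, "hyperseg_model"))
  x <- if (inherits(features, "annotation_set")) features$spectra else
    as.matrix(features)
  if (nrow(x) == 0L)
    return(list(labels = integer(0), prob = NULL))
  if (ncol(x) != model$n_bands)
    stop(sprintf("feature band count %d does not match training (%d)",
                 ncol(x), model$n_bands), call. = FALSE)
  colnames(x) <- paste0("b", seq_len(ncol(x)))
  cls <- model$classes
  fam <- model$spec$family
  out <- switch(fam,
    "MLR" = {
      df <- as.data.frame(x)
      p <- stats::predict(model$fit, newdata = df, type = "probs")
      if (is.null(dim(p))) p <- cbind(1 - p, p)  # two-class case
      list(labels = cls[max.col(p)], prob = p)
    },
    "SVM" = {
      pred <- stats::predict(model$fit, x, probability = TRUE)
      p <- attr(pred, "probabilities")
      p <- p[, as.character(cls), drop = FALSE]
      list(labels = cls[as.integer(pred)], prob = p)
    },
    "LDA" = {
      pr <- stats::predict(model$fit, x)
      list(labels = cls[as.integer(pr$class)], prob = pr$posterior)
    },
    "QDA" = qda_ridge_predict(model$fit, x, cls),
    "PLS-DA" = {
      pr <- stats::predict(model$fit, x, dist = "max.dist")
      nc <- model$spec$hyperparams$n_components
      list(labels = as.integer(as.character(pr$class$max.dist[, nc])),
           prob = NULL)
    },
    "RF" = {
      p <- stats::predict(model$fit, x, type = "prob")
      list(labels = cls[max.col(p, ties.method = "first")], prob = p)
    },
    "LASSO" = {
      p <- stats::predict(model$fit, x, s = "lambda.min",
                          type = "response")[, , 1L]
      if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
      list(labels = cls[max.col(p)], prob = p)
    },
    "ANN" = {
      p <- mlp_predict_prob(model$fit, x)
      list(labels = cls[max.col(p, ties.method = "first")], prob = p)
    })
  out$labels <- as.integer(out$labels)
  if (!is.null(out$prob)) {
    out$prob <- as.matrix(out$prob)
    colnames(out$prob) <- as.character(cls)[seq_len(ncol(out$prob))]
  }
  out
}

#' Pixel classification accuracy table
#'
#' Accuracy is the number of pixels assigned the same label by the manual
#' annotation and the algorithm, divided by the total number of pixels
#' scored. Per-class accuracy restricts both counts to pixels whose true
#' label is that class; the `average` column pools all scored pixels. An
#' optional class subset recomputes a pooled average excluding some classes
#' (used when a class, such as the maize tassel, is not biologically
#' equivalent between training and evaluation material).
#'
#' @param pred,truth equal-length integer label vectors (codes 0-3).
#' @param exclude_classes class codes excluded from `average_excluding`
#'   (omit for no such column).
#' @return An object of class `"accuracy_table"`: list with `per_class`,
#'   `average`, optional `average_excluding`, and `n_pixels`.
#' @export
pixel_accuracy <- function(pred, truth, exclude_classes = NULL) {
  if (length(pred) != length(truth))
    stop("`pred` and `truth` must have equal length", call. = FALSE)
  pred <- as.integer(pred); truth <- as.integer(truth)
  classes <- sort(unique(truth))
  per <- vapply(classes, function(cl) {
    idx <- truth == cl
    mean(pred[idx] == truth[idx])
  }, numeric(1))
  names(per) <- rownames(ORGAN_PALETTE)[classes + 1L]
  n_pix <- vapply(classes, function(cl) sum(truth == cl), integer(1))
  names(n_pix) <- names(per)
  out <- list(per_class = per, average = mean(pred == truth),
              n_pixels = n_pix)
  if (!is.null(exclude_classes)) {
    keep <- !(truth %in% exclude_classes)
    out$average_excluding <- if (any(keep))
      mean(pred[keep] == truth[keep]) else NA_real_
    out$excluded_classes <- exclude_classes
  }
  structure(out, class = "accuracy_table")
}

#' @export
print.accuracy_table <- function(x, ...) {
  v <- c(x$per_class, Average = x$average)
  if (!is.null(x$average_excluding))
    v <- c(v, `Average (excl.)` = x$average_excluding)
  print(round(v, 3))
  invisible(x)
}

#' Convert an accuracy table to a one-row data frame
#' @param x an `accuracy_table`.
#' @param ... unused.
#' @export
as.data.frame.accuracy_table <- function(x, ...) {
  df <- as.data.frame(as.list(c(x$per_class, average = x$average)))
  if (!is.null(x$average_excluding))
    df$average_excluding <- x$average_excluding
  df
}

#' Image-level k-fold cross-validation
#'
#' Splits the data into folds at the level of whole images, so all pixels
#' annotated on one image land in the same fold and no image contributes to
#' both training and testing. Image ids are shuffled with the seed and
#' dealt round-robin into `k` folds (sizes differ by at most one). Pooled
#' out-of-fold predictions are scored with [pixel_accuracy()].
#'
#' @param spec a [classifier_spec].
#' @param annotations an [annotation_set] spanning at least `k` images.
#' @param k number of folds (default 5).
#' @param seed integer RNG seed for the fold shuffle.
#' @return A list with `accuracy` (pooled [pixel_accuracy()] table),
#'   `fold_of_image` (named fold assignment), `per_fold` (accuracy tables),
#'   and `oof` (data frame of out-of-fold predictions with image ids).
#' @export
crossvalidate <- function(spec, annotations, k = 5, seed = 1) {
  stopifnot(inherits(annotations, "annotation_set"))
  ids <- unique(annotations$records$image_id)
  if (length(ids) < k)
    stop(sprintf("need at least k = %d distinct images, have %d", k,
                 length(ids)), call. = FALSE)
  old <- set_local_seed(seed)
  shuffled <- sample(ids)
  restore_seed(old)
  fold_of_image <- stats::setNames(rep(seq_len(k),
                                       length.out = length(shuffled)),
                                   shuffled)

  rec_fold <- fold_of_image[annotations$records$image_id]
  oof_pred <- integer(nrow(annotations$records))
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(rec_fold == f)
    train_idx <- which(rec_fold != f)
    train_set <- subset_annotations(annotations, train_idx)
    model <- train_classifier(spec, train_set)
    pred <- predict_pixels(model, annotations$spectra[test_idx, ,
                                                      drop = FALSE])
    oof_pred[test_idx] <- pred$labels
    per_fold[[f]] <- pixel_accuracy(pred$labels,
                                    annotations$records$class[test_idx])
  }
  truth <- annotations$records$class
  list(accuracy = pixel_accuracy(oof_pred, truth),
       fold_of_image = fold_of_image,
       per_fold = per_fold,
       oof = data.frame(image_id = annotations$records$image_id,
                        fold = as.integer(rec_fold), truth = truth,
                        pred = oof_pred))
}

subset_annotations <- function(set, idx) {
  annotation_set(set$records[idx, , drop = FALSE],
                 set$spectra[idx, , drop = FALSE],
                 class_names = set$class_names,
                 wavelength_nm = set$wavelength_nm)
}

#' Evaluate a trained model on a foreign annotation set
#'
#' Scores a model trained on one dataset (e.g. grain-fill sorghum) against
#' annotations from another (e.g. maize, where the tassel occupies the
#' panicle class slot). Reports the usual per-class and pooled accuracies
#' plus a pooled average excluding the requested classes.
#'
#' @param model a fitted classifier.
#' @param foreign_annotations an [annotation_set] with a compatible band
#'   count.
#' @param exclude_classes class codes excluded from the extra average
#'   column (e.g. `3` to drop the tassel/panicle slot).
#' @return An `accuracy_table`.
#' @export
transfer_evaluate <- function(model, foreign_annotations,
                              exclude_classes = integer(0)) {
  stopifnot(inherits(foreign_annotations, "annotation_set"))
  truth <- foreign_annotations$records$class
  if (!any(truth %in% model$classes))
    stop("no overlap between model classes and foreign annotation classes",
         call. = FALSE)
  pred <- predict_pixels(model, foreign_annotations)
  pixel_accuracy(pred$labels, truth, exclude_classes = exclude_classes)
}

#' Random-forest band importance profile
#'
#' Extracts the mean decrease in Gini impurity per spectral band from a
#' fitted random forest — the total reduction in Gini impurity across all
#' splits on that band, averaged over trees.
#'
#' @param model a fitted `"RF"` model.
#' @param wavelength_nm optional wavelength grid (length B); defaults to
#'   the 546-1700 nm grid.
#' @return An object of class `"importance_profile"`: list with
#'   `importance` (length-B nonnegative vector) and `wavelength_nm`.
#' @export
gini_importance <- function(model, wavelength_nm = NULL) {
  stopifnot(inherits(model, "hyperseg_model"))
  if (model$spec$family != "RF")
    stop("Gini importance requires a random-forest model", call. = FALSE)
  imp <- randomForest::importance(model$fit)[, "MeanDecreaseGini"]
  if (is.null(wavelength_nm))
    wavelength_nm <- band_wavelengths(length(imp), 546, 1700)
  structure(list(importance = unname(imp),
                 wavelength_nm = wavelength_nm),
            class = "importance_profile")
}

#' Contiguous high-importance spectral regions
#'
#' Finds maximal runs of consecutive bands whose importance exceeds the
#' threshold and reports them as closed wavelength intervals in ascending
#' order.
#'
#' @param profile an [gini_importance()] profile.
#' @param threshold importance cutoff (default 10, the conventional mean
#'   decrease in Gini cutoff for flagging informative spectral regions).
#' @return Data frame with columns `wl_start`, `wl_end`, `band_start`,
#'   `band_end`; zero rows when nothing exceeds the threshold.
#' @export
important_regions <- function(profile, threshold = 10) {
  stopifnot(inherits(profile, "importance_profile"))
  above <- profile$importance > threshold
  if (!any(above))
    return(data.frame(wl_start = numeric(0), wl_end = numeric(0),
                      band_start = integer(0), band_end = integer(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(wl_start = profile$wavelength_nm[starts[keep]],
             wl_end = profile$wavelength_nm[ends[keep]],
             band_start = starts[keep], band_end = ends[keep])
}

#' Per-class mean and standard-deviation reflectance curves
#'
#' @param annotations an [annotation_set].
#' @return A list with `mean` and `sd`, each a `B x n_classes` matrix
#'   (columns named by class), plus `n` per class. Classes with no records
#'   are omitted with a warning.
#' @export
class_spectral_summary <- function(annotations) {
  stopifnot(inherits(annotations, "annotation_set"))
  cls <- annotations$records$class
  present <- sort(unique(cls))
  absent <- setdiff(0:3, present)
  if (length(absent))
    warning(sprintf("no records for class(es): %s",
                    paste(rownames(ORGAN_PALETTE)[absent + 1L],
                          collapse = ", ")))
  b <- ncol(annotations$spectra)
  mu <- sapply(present, function(cl)
    colMeans(annotations$spectra[cls == cl, , drop = FALSE]))
  sdv <- sapply(present, function(cl) {
    xx <- annotations$spectra[cls == cl, , drop = FALSE]
    if (nrow(xx) == 1L) rep(0, b) else apply(xx, 2L, stats::sd)
  })
  colnames(mu) <- colnames(sdv) <- rownames(ORGAN_PALETTE)[present + 1L]
  list(mean = mu, sd = sdv,
       n = stats::setNames(tabulate(cls + 1L, 4L)[present + 1L],
                           colnames(mu)),
       wavelength_nm = annotations$wavelength_nm)
}

#' Low-dimensional ordination of annotated spectra
#'
#' Projects the labeled spectra into a low-dimensional view: principal
#' components of the centred spectra, or the discriminant axes of a linear
#' discriminant analysis. PCA variance fractions are non-increasing and in
#' `[0, 1]`.
#'
#' @param annotations an [annotation_set].
#' @param method `"PCA"` or `"LDA-projection"`.
#' @param n_components number of axes to return (default 2).
#' @return A list with `scores` (`n x n_components`), `variance_explained`
#'   (fractions per returned component), `method`, and the record classes.
#' @export
ordination <- function(annotations, method = c("PCA", "LDA-projection"),
                       n_components = 2) {
  stopifnot(inherits(annotations, "annotation_set"))
  method <- match.arg(method)
  x <- annotations$spectra
  if (nrow(x) <= n_components)
    stop("need more records than components", call. = FALSE)
  sds <- apply(x, 2L, stats::sd)
  if (all(sds == 0))
    stop("degenerate input: all spectra identical", call. = FALSE)
  if (method == "PCA") {
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    ve <- pc$sdev^2 / sum(pc$sdev^2)
    if (sum(ve > 1e-12) < n_components)
      stop("fewer non-degenerate dimensions than components requested",
           call. = FALSE)
    list(scores = pc$x[, seq_len(n_components), drop = FALSE],
         variance_explained = ve[seq_len(n_components)],
         method = method, class = annotations$records$class)
  } else {
    yf <- factor(annotations$records$class)
    if (nlevels(yf) < 2L)
      stop("LDA projection needs at least two classes", call. = FALSE)
    fit <- MASS::lda(x, grouping = yf)
    pr <- stats::predict(fit, x)
    nc <- min(n_components, ncol(pr$x))
    ve <- fit$svd^2 / sum(fit$svd^2)
    list(scores = pr$x[, seq_len(nc), drop = FALSE],
         variance_explained = ve[seq_len(nc)],
         method = method, class = annotations$records$class)
  }
}

# ---- regularized quadratic discriminant analysis -------------------------
# Class-wise Gaussian model with a ridge added to each covariance matrix
# (ridge = ridge_scale * trace(S)/B * I) so that classes with fewer records
# than bands remain invertible.

qda_ridge_fit <- function(x, yf, ridge_scale = 1e-6) {
  classes <- levels(yf)
  b <- ncol(x)
  fits <- lapply(classes, function(cl) {
    xx <- x[yf == cl, , drop = FALSE]
    mu <- colMeans(xx)
    S <- stats::cov(xx)
    ridge <- ridge_scale * sum(diag(S)) / b
    if (!is.finite(ridge) || ridge <= 0) ridge <- 1e-8
    S <- S + diag(ridge, b)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    attempts <- 0L
    while (is.null(ch) && attempts < 12L) {
      ridge <- ridge * 100
      ch <- tryCatch(chol(S + diag(ridge, b)), error = function(e) NULL)
      attempts <- attempts + 1L
    }
    if (is.null(ch))
      stop("singular class covariance in QDA even after ridge; reduce the ",
           "band count or add records", call. = FALSE)
    list(mu = mu, chol = ch, logdet = 2 * sum(log(diag(ch))),
         logprior = log(sum(yf == cl) / length(yf)))
  })
  names(fits) <- classes
  list(classes = classes, fits = fits)
}

qda_ridge_predict <- function(fit, x, cls) {
  scores <- sapply(fit$fits, function(f) {
    d <- forwardsolve(t(f$chol), t(x) - f$mu)
    -0.5 * colSums(d^2) - 0.5 * f$logdet + f$logprior
  })
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  # softmax over discriminant scores gives posterior probabilities
  mx <- apply(scores, 1L, max)
  p <- exp(scores - mx)
  p <- p / rowSums(p)
  list(labels = cls[max.col(scores, ties.method = "first")], prob = p)
}

# ---- multilayer perceptron ----------------------------------------------
# ReLU hidden layers, softmax output, cross-entropy loss, minibatch SGD.

mlp_fit <- function(x, yf, hidden = c(300, 300, 300, 300), lr = 5e-4,
                    epochs = 200, batch_size = 32) {
  n <- nrow(x); k <- nlevels(yf)
  sizes <- c(ncol(x), hidden, k)
  L <- length(sizes) - 1L
  W <- vector("list", L); bvec <- vector("list", L)
  for (l in seq_len(L)) {
    # He initialization suits ReLU layers
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                  sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1L])
    bvec[[l]] <- rep(0, sizes[l + 1L])
  }
  Y <- diag(k)[as.integer(yf), , drop = FALSE]
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      xb <- x[idx, , drop = FALSE]
      yb <- Y[idx, , drop = FALSE]
      # forward
      acts <- vector("list", L + 1L)
      acts[[1L]] <- xb
      for (l in seq_len(L)) {
        z <- sweep(acts[[l]] %*% W[[l]], 2L, bvec[[l]], "+")
        acts[[l + 1L]] <- if (l < L) pmax(z, 0) else {
          zmax <- apply(z, 1L, max)
          ez <- exp(z - zmax)
          ez / rowSums(ez)
        }
      }
      # backward
      delta <- (acts[[L + 1L]] - yb) / nrow(xb)
      for (l in rev(seq_len(L))) {
        gW <- crossprod(acts[[l]], delta)
        gb <- colSums(delta)
        if (l > 1L)
          delta <- (delta %*% t(W[[l]])) * (acts[[l]] > 0)
        W[[l]] <- W[[l]] - lr * gW
        bvec[[l]] <- bvec[[l]] - lr * gb
      }
    }
  }
  list(W = W, b = bvec, levels = levels(yf))
}

mlp_predict_prob <- function(fit, x) {
  a <- x
  L <- length(fit$W)
  for (l in seq_len(L)) {
    z <- sweep(a %*% fit$W[[l]], 2L, fit$b[[l]], "+")
    a <- if (l < L) pmax(z, 0) else {
      zmax <- apply(z, 1L, max)
      ez <- exp(z - zmax)
      ez / rowSums(ez)
    }
  }
  a
}
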