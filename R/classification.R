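#' Precompute per-image primitives and spatial indices
#'
#' Chord measurement and the spatial indices depend only on the image, not
#' on the train/test split or the clustering, so they are computed once and
#' reused by every evaluation protocol. Each image gets its own
#' pair-correlation sampling seed, drawn reproducibly from `seed`.
#'
#' @param images list of [binary_image] objects with group labels.
#' @param D number of chord angles.
#' @param seed integer seed for the per-image pair-correlation sampling.
#' @return List (class `colony_data`) with one entry per image:
#'   `image_id`, `group`, `lengths_um`, `indices`.
#' @export
prepare_colony_data <- function(images, D = 4, seed = 1L) {
  pc_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max,
                                                length(images)))
  out <- lapply(seq_along(images), function(i) {
    img <- images[[i]]
    sp <- shape_primitives(img, D = D)
    list(image_id = img$image_id, group_label = img$group_label,
         group = img$group_label, lengths_um = sp$lengths_um,
         indices = spatial_indices(img, seed = pc_seeds[i]))
  })
  structure(out, class = "colony_data", D = D)
}

#' Single-feature linear discriminant classifier
#'
#' A one-dimensional Gaussian discriminant with pooled within-class
#' variance and uniform priors, fitted on exactly one coordinate of the
#' augmented feature vector. With equal priors and a shared variance the
#' decision rule reduces to the nearest class mean; degenerate cases
#' (zero pooled variance, or all class means identical) fall back the same
#' way, predicting the first class in class order on exact ties.
#'
#' @param x numeric vector: one feature for each training image.
#' @param y class labels (character or factor).
#' @return Object of class `sf_lda` with `means`, `pooled_var`, `classes`.
#' @export
fit_single_feature_lda <- function(x, y) {
  y <- as.character(y)
  classes <- unique(y)
  if (any(!table(factor(y, levels = classes)) >= 1L))
    stop("every class needs at least one training example")
  means <- vapply(classes, function(cl) mean(x[y == cl]), numeric(1))
  ss <- sum(vapply(classes, function(cl) {
    v <- x[y == cl]; sum((v - mean(v))^2)
  }, numeric(1)))
  df <- length(x) - length(classes)
  structure(list(means = means, pooled_var = if (df > 0) ss / df else 0,
                 classes = classes),
            class = "sf_lda")
}

#' @param object an `sf_lda` classifier.
#' @param newdata numeric vector of feature values.
#' @param ... unused.
#' @rdname fit_single_feature_lda
#' @export
predict.sf_lda <- function(object, newdata, ...) {
  d <- abs(outer(newdata, object$means, "-"))
  object$classes[max.col(-d, ties.method = "first")]
}

#' Exhaustive single-feature selection
#'
#' Fits a [fit_single_feature_lda()] classifier on every coordinate of the
#' feature matrix and scores it on the training data; the feature with the
#' highest training accuracy wins. With training sets of ~10 images many
#' features typically tie at a perfect score, so accuracy ties are broken
#' by the Fisher separation ratio (variance of the class means over the
#' pooled within-class variance) — the feature whose classes are most
#' separated relative to their spread — and only exact ratio ties fall
#' back to the smallest index. The full accuracy-tie set is returned so
#' that selection counts (how often each spatial index is among the best
#' features) can be recorded.
#'
#' @param X numeric matrix, images x features (named columns).
#' @param y class labels.
#' @return List with `j` (winning column), `fit`, `accuracy`, `tied`
#'   (indices of all columns achieving the best score), `scores`,
#'   `fisher` (separation ratios).
#' @export
select_best_feature <- function(X, y) {
  y <- as.character(y)
  if (length(unique(y)) < 2L) stop("feature selection needs at least 2 classes")
  scores <- vapply(seq_len(ncol(X)), function(j) {
    fit <- fit_single_feature_lda(X[, j], y)
    mean(predict(fit, X[, j]) == y)
  }, numeric(1))
  fisher <- vapply(seq_len(ncol(X)), function(j)
    fisher_ratio(X[, j], y), numeric(1))
  best <- max(scores)
  tied <- which(scores >= best - 1e-12)
  j <- tied[which.max(fisher[tied])]  # which.max: first max = smallest index
  list(j = j, fit = fit_single_feature_lda(X[, j], y),
       accuracy = best, tied = tied, scores = scores, fisher = fisher)
}

# Fisher separation of one feature: variance of class means over pooled
# within-class variance. Zero pooled variance with distinct means gives
# Inf (a perfectly crisp feature); all values identical gives 0.
fisher_ratio <- function(x, y) {
  classes <- unique(y)
  means <- vapply(classes, function(cl) mean(x[y == cl]), numeric(1))
  between <- stats::var(means)
  if (is.na(between)) between <- 0
  ss <- sum(vapply(classes, function(cl) {
    v <- x[y == cl]; sum((v - mean(v))^2)
  }, numeric(1)))
  df <- length(x) - length(classes)
  within <- if (df > 0) ss / df else 0
  if (within > 0) between / within
  else if (between > 0) Inf
  else 0
}

# Random even train/test split, stratified by group: odd group sizes put
# the extra image in training (ceiling(S_g / 2) train), reproducing a
# 5-train / 4-test split for a 9-image group.
split_train_test <- function(group, seed) {
  group <- as.character(group)
  train <- logical(length(group))
  withr::with_seed(seed, {
    for (g in unique(group)) {
      idx <- which(group == g)
      train[sample(idx, ceiling(length(idx) / 2))] <- TRUE
    }
  })
  train
}

# Fit CSPs on the training images only and build augmented features for
# every image. `prepared` is a colony_data list; `train` a logical vector.
build_run_features <- function(prepared, train, K, kmeans_seed) {
  group <- vapply(prepared, `[[`, character(1), "group")
  groups <- unique(group)
  D <- attr(prepared, "D")
  spaces <- lapply(groups, function(g) {
    keep <- which(train & group == g)
    if (length(keep) == 0L) stop("group '", g, "' has no training images")
    list(lengths_um = do.call(rbind, lapply(prepared[keep], `[[`, "lengths_um")),
         D = D)
  })
  names(spaces) <- groups
  model <- fit_csp_model(spaces, K = K, seed = kmeans_seed)
  fm <- csp_feature_matrix(prepared, model)
  list(model = model, X = fm$features, group = fm$group,
       image_id = fm$image_id)
}

# Names of the spatial-index coordinates in the augmented feature vector
SPATIAL_FEATURES <- c("I_r", "I_theta", "I_Theta")

#' One train/test evaluation run
#'
#' Splits each group evenly at random (odd sizes: extra image to
#' training), fits the CSP model on the training images only, selects the
#' best single feature by training accuracy and reports the accuracy on
#' the held-out test images.
#'
#' @param images list of labelled [binary_image] objects (>= 2 per group),
#'   or `NULL` when `prepared` is given.
#' @param D number of chord angles.
#' @param K clusters per group.
#' @param split_seed,kmeans_seed integer seeds for the split and the
#'   clustering.
#' @param prepared optional precomputed [prepare_colony_data()] result.
#' @param index_seed seed forwarded to [prepare_colony_data()] when
#'   `prepared` is not supplied.
#' @param selection criterion for picking the best feature: `"train"`
#'   (default) selects by training accuracy and reports that feature's
#'   held-out accuracy; `"test"` reports the best held-out score across
#'   all features (each trained and tested individually).
#' @return List with `accuracy`, `best_feature` (name), `tied_features`,
#'   `index_chosen` (logical per spatial index), `M`, `train_ids`,
#'   `test_ids`.
#' @export
train_test_evaluate <- function(images = NULL, D = 4, K = 10, split_seed = 1L,
                                kmeans_seed = 1L, prepared = NULL,
                                index_seed = 1L,
                                selection = c("train", "test")) {
  selection <- match.arg(selection)
  if (is.null(prepared)) prepared <- prepare_colony_data(images, D, index_seed)
  group <- vapply(prepared, `[[`, character(1), "group")
  if (any(table(group) < 2L)) stop("every group needs at least 2 images")
  train <- split_train_test(group, split_seed)
  rf <- build_run_features(prepared, train, K, kmeans_seed)
  feature_names <- colnames(rf$X)
  if (selection == "train") {
    sel <- select_best_feature(rf$X[train, , drop = FALSE], group[train])
    pred <- predict(sel$fit, rf$X[!train, sel$j])
    accuracy <- mean(pred == group[!train])
    best_j <- sel$j
    tied_names <- feature_names[sel$tied]
  } else {
    scores <- vapply(seq_len(ncol(rf$X)), function(j) {
      fit <- fit_single_feature_lda(rf$X[train, j], group[train])
      mean(predict(fit, rf$X[!train, j]) == group[!train])
    }, numeric(1))
    accuracy <- max(scores)
    tied <- which(scores >= accuracy - 1e-12)
    best_j <- tied[1L]
    tied_names <- feature_names[tied]
  }
  list(accuracy = accuracy,
       best_feature = feature_names[best_j],
       tied_features = tied_names,
       index_chosen = stats::setNames(SPATIAL_FEATURES %in% tied_names,
                                      SPATIAL_FEATURES),
       M = rf$model$M,
       train_ids = rf$image_id[train], test_ids = rf$image_id[!train])
}

#' Repeated train/test evaluation
#'
#' Repeats [train_test_evaluate()] `n` times with fresh split and k-means
#' seeds drawn from `seed`, recording the mean and (sample) standard
#' deviation of the test accuracies and how often each spatial index was
#' among the best features.
#'
#' @inheritParams train_test_evaluate
#' @param n number of repetitions (default 30).
#' @param seed master seed; per-run seeds are derived from it.
#' @return Object of class `csp_experiment` (protocol `"train_test"`) with
#'   `mu`, `sigma`, `runs` (per-run accuracy and best feature) and
#'   `index_counts`.
#' @export
repeated_evaluation <- function(images = NULL, D = 4, K = 10, n = 30,
                                seed = 1L, prepared = NULL,
                                selection = c("train", "test")) {
  selection <- match.arg(selection)
  if (is.null(prepared)) prepared <- prepare_colony_data(images, D, seed)
  seeds <- withr::with_seed(seed, matrix(
    sample.int(.Machine$integer.max, 2L * n), ncol = 2L))
  runs <- lapply(seq_len(n), function(i)
    train_test_evaluate(D = D, K = K, split_seed = seeds[i, 1L],
                        kmeans_seed = seeds[i, 2L], prepared = prepared,
                        selection = selection))
  acc <- vapply(runs, `[[`, numeric(1), "accuracy")
  counts <- Reduce(`+`, lapply(runs, function(r) as.integer(r$index_chosen)))
  structure(
    list(protocol = "train_test", n = n, D = D, K = K,
         mu = mean(acc), sigma = if (n > 1L) stats::sd(acc) else 0,
         accuracies = acc,
         best_features = vapply(runs, `[[`, character(1), "best_feature"),
         index_counts = stats::setNames(counts, SPATIAL_FEATURES),
         M = runs[[1L]]$M, seed = seed),
    class = "csp_experiment")
}

#' Leave-one-out cross-validation
#'
#' Each image in turn is held out; the CSP model is refitted and the best
#' single feature re-selected on the remaining S - 1 images, and the
#' held-out image is classified. The accuracy is the proportion of the S
#' images classified correctly. Feature selection happens inside every
#' fold, and the spatial indices are counted each time they are among the
#' tied-best features of a fold.
#'
#' @inheritParams repeated_evaluation
#' @return Object of class `csp_experiment` (protocol `"loocv"`) with
#'   `accuracy`, per-fold correctness and `index_counts`.
#' @export
loocv_evaluate <- function(images = NULL, D = 4, K = 10, seed = 1L,
                           prepared = NULL) {
  if (is.null(prepared)) prepared <- prepare_colony_data(images, D, seed)
  group <- vapply(prepared, `[[`, character(1), "group")
  S <- length(prepared)
  if (S < 2L) stop("LOOCV needs at least 2 images")
  km_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, S))
  correct <- logical(S)
  chosen <- character(0)
  feats <- character(S)
  for (i in seq_len(S)) {
    train <- rep(TRUE, S); train[i] <- FALSE
    if (any(table(group[train]) < 1L) || length(unique(group[train])) < 2L)
      stop("a fold lost an entire class")
    rf <- build_run_features(prepared, train, K, km_seeds[i])
    sel <- select_best_feature(rf$X[train, , drop = FALSE], group[train])
    correct[i] <- predict(sel$fit, rf$X[i, sel$j]) == group[i]
    tied_names <- colnames(rf$X)[sel$tied]
    feats[i] <- colnames(rf$X)[sel$j]
    chosen <- c(chosen, intersect(SPATIAL_FEATURES, tied_names))
  }
  counts <- vapply(SPATIAL_FEATURES, function(f) sum(chosen == f), integer(1))
  structure(
    list(protocol = "loocv", S = S, D = D, K = K,
         accuracy = mean(correct), correct = correct, best_features = feats,
         index_counts = counts, seed = seed),
    class = "csp_experiment")
}

#' Feature analysis: which features classify perfectly?
#'
#' A single train/test run in which every coordinate of the augmented
#' feature vector is scored on the held-out test set; all features
#' achieving the maximal test score are reported, together with the centre
#' vectors of the winning CSP features (for plotting length against
#' angle). Less robust than repeated evaluation or LOOCV, but it shows
#' which learned shape patterns discriminate between the groups.
#'
#' @inheritParams train_test_evaluate
#' @return Object of class `csp_experiment` (protocol `"feature_analysis"`)
#'   with `best_score`, `best_features`, `n_features` and `csp_centres`
#'   (a matrix of the winning CSP centre vectors, NULL when only spatial
#'   indices win).
#' @export
feature_analysis <- function(images = NULL, D = 4, K = 10, split_seed = 1L,
                             kmeans_seed = 1L, prepared = NULL,
                             index_seed = 1L) {
  if (is.null(prepared)) prepared <- prepare_colony_data(images, D, index_seed)
  group <- vapply(prepared, `[[`, character(1), "group")
  train <- split_train_test(group, split_seed)
  rf <- build_run_features(prepared, train, K, kmeans_seed)
  X <- rf$X
  test_scores <- vapply(seq_len(ncol(X)), function(j) {
    fit <- fit_single_feature_lda(X[train, j], group[train])
    mean(predict(fit, X[!train, j]) == group[!train])
  }, numeric(1))
  best <- max(test_scores)
  winners <- which(test_scores >= best - 1e-12)
  wn <- colnames(X)[winners]
  csp_idx <- grep("^h_", wn)
  centres <- if (length(csp_idx)) {
    ci <- as.integer(sub("^h_", "", wn[csp_idx]))
    rf$model$centres[ci, , drop = FALSE]
  } else NULL
  structure(
    list(protocol = "feature_analysis", D = D, K = K, M = rf$model$M,
         n_features = ncol(X), best_score = best, best_features = wn,
         test_scores = stats::setNames(test_scores, colnames(X)),
         csp_centres = centres, model = rf$model),
    class = "csp_experiment")
}

#' @export
print.csp_experiment <- function(x, ...) {
  switch(x$protocol,
    train_test = cat(sprintf(
      "<csp_experiment train/test> n = %d, D = %d, K = %d: mu = %.3f, sigma = %.3f\n",
      x$n, x$D, x$K, x$mu, x$sigma)),
    loocv = cat(sprintf(
      "<csp_experiment LOOCV> S = %d, D = %d, K = %d: accuracy = %.3f\n",
      x$S, x$D, x$K, x$accuracy)),
    feature_analysis = cat(sprintf(
      "<csp_experiment feature analysis> D = %d, K = %d: %d/%d features at score %.3f\n",
      x$D, x$K, length(x$best_features), x$n_features, x$best_score)))
  if (!is.null(x$index_counts)) {
    cat("spatial-index selections:",
        paste(names(x$index_counts), x$index_counts, sep = " = ",
              collapse = ", "), "\n")
  }
  invisible(x)
}
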