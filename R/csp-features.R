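#' Fit clustered shape primitives (CSPs) per group
#'
#' Runs k-means separately on each group's representation space (the
#' physical-unit shape primitives of all its images) and concatenates the
#' K cluster centres per group in group order, so that centre
#' i = (g - 1) * K + k is the k-th CSP of group g and M = K * m centres
#' result. Within a group the K centres are numbered by decreasing
#' cluster size (k-means returns clusters in arbitrary order), so CSP 1
#' of a group is its most prevalent — and hence best-estimated — local
#' shape pattern. Clustering uses k-means++ initialization with 10
#' restarts and Lloyd iterations (tolerance 1e-6 on centre movement, at
#' most 300 iterations); the restart with the lowest within-cluster sum
#' of squares wins. Fully deterministic given `seed`.
#'
#' @param spaces named list, one [representation_space()] per group, in
#'   group order.
#' @param K clusters per group.
#' @param seed integer seed for the k-means initialization.
#' @return Object of class `csp_model`: `centres` (M x D matrix, rows
#'   labelled by group), `group_of_centre`, `groups`, `K`, `m`, `M`, `D`,
#'   `seed`, `inertia` (per-group within-cluster SSE).
#' @export
fit_csp_model <- function(spaces, K, seed = 1L) {
  if (!is.numeric(K) || length(K) != 1L || K < 1 || K != round(K))
    stop("`K` must be a positive integer")
  if (length(spaces) < 1L) stop("at least one group is required")
  groups <- names(spaces)
  if (is.null(groups)) groups <- paste0("group", seq_along(spaces))
  D <- spaces[[1L]]$D
  fits <- withr::with_seed(seed, lapply(spaces, function(sp) {
    x <- sp$lengths_um
    if (nrow(x) < K)
      stop("group has ", nrow(x), " primitives; cannot fit K = ", K, " clusters")
    fit <- kmeans_pp(x, K)
    # number CSPs by decreasing prevalence (deterministic: size, then
    # first centre coordinate on ties)
    size <- tabulate(fit$cluster, nbins = nrow(fit$centers))
    ord <- order(-size, fit$centers[, 1])
    fit$centers <- fit$centers[ord, , drop = FALSE]
    fit
  }))
  centres <- do.call(rbind, lapply(fits, `[[`, "centers"))
  rownames(centres) <- unlist(lapply(groups, function(g) paste0(g, ".", seq_len(K))))
  structure(
    list(centres = centres, group_of_centre = rep(groups, each = K),
         groups = groups, K = K, m = length(spaces), M = K * length(spaces),
         D = D, seed = seed,
         inertia = vapply(fits, `[[`, numeric(1), "tot.withinss")),
    class = "csp_model")
}

# k-means with k-means++ seeding, 10 restarts, Lloyd iterations.
# Relies on stats::kmeans for the Lloyd refinement of each seeded start.
kmeans_pp <- function(x, K, restarts = 10L, iter_max = 300L, tol = 1e-6) {
  best <- NULL
  last_init <- NULL
  for (r in seq_len(restarts)) {
    centres <- x[kmeanspp_init(x, K), , drop = FALSE]
    last_init <- centres
    # Lloyd can abort on an empty cluster (duplicate-heavy spaces); such a
    # restart is discarded. Lloyd stops on an assignment fixpoint, which
    # implies centre movement below any tolerance; `tol` documents that.
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = centres, iter.max = iter_max,
                                     algorithm = "Lloyd")),
      error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || fit$tot.withinss < best$tot.withinss)) best <- fit
    if (K == 1L && !is.null(best)) break  # one cluster: restarts identical
  }
  if (is.null(best)) {
    warning("k-means failed on every restart (too few distinct primitives); ",
            "using unrefined k-means++ centres", call. = FALSE)
    lab <- max.col(-crossdist2(x, last_init), ties.method = "first")
    best <- list(centers = last_init, cluster = lab,
                 tot.withinss = sum((x - last_init[lab, , drop = FALSE])^2))
  }
  best
}

# squared Euclidean cross-distance matrix between rows of a and b
crossdist2 <- function(a, b) {
  outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
}

# k-means++ seeding: first centre uniform, then proportional to squared
# distance from the nearest chosen centre. Returns row indices.
kmeanspp_init <- function(x, K) {
  n <- nrow(x)
  idx <- integer(K)
  idx[1L] <- sample.int(n, 1L)
  if (K == 1L) return(idx)
  d2 <- rowSums(sweep(x, 2, x[idx[1L], ])^2)
  for (k in 2L:K) {
    if (all(d2 == 0)) {
      idx[k] <- sample.int(n, 1L)  # degenerate: all points coincide
    } else {
      idx[k] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[idx[k], ])^2))
  }
  idx
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("<csp_model> m = %d groups x K = %d -> M = %d CSPs, D = %d\n",
              x$m, x$K, x$M, x$D))
  invisible(x)
}

#' Assign each shape primitive to its nearest CSP
#'
#' Labels every primitive with the index of the closest centre in Euclidean
#' distance over all M centres (the CSP map of the image). Ties are broken
#' by the smallest centre index.
#'
#' @param primitives a [shape_primitives] object or an n x D matrix of
#'   physical-unit primitives.
#' @param model a [fit_csp_model()] result.
#' @return Integer vector of labels in 1..M.
#' @export
assign_csp <- function(primitives, model) {
  stopifnot(inherits(model, "csp_model"))
  x <- if (inherits(primitives, "shape_primitives")) primitives$lengths_um
       else as.matrix(primitives)
  if (ncol(x) != model$D)
    stop("primitive dimension ", ncol(x), " does not match model D = ", model$D)
  d2 <- crossdist2(x, model$centres)
  # ties (to numerical tolerance) go to the smallest centre index
  near <- d2 <= apply(d2, 1, min) + 1e-9 * (1 + abs(apply(d2, 1, min)))
  max.col(near, ties.method = "first")
}

#' Normalized CSP histogram of an image
#'
#' h_i is the proportion of boundary pixels whose primitive maps to CSP i;
#' the histogram sums to 1 and is the image's shape feature vector.
#'
#' @param labels integer CSP labels (a CSP map), all in 1..M.
#' @param M total number of CSPs.
#' @return Numeric vector h of length M with `sum(h) == 1`.
#' @export
csp_histogram <- function(labels, M) {
  if (length(labels) == 0L) stop("empty CSP map")
  if (any(labels < 1L | labels > M)) stop("labels must lie in 1..M")
  h <- tabulate(labels, nbins = M) / length(labels)
  names(h) <- paste0("h_", seq_len(M))
  h
}

#' Augment a CSP histogram with the scaled spatial indices
#'
#' Appends I_r / M, I_theta / M and I_Theta / M (in that order) to the
#' M-bin histogram; the 1/M factor puts the indices on the same magnitude
#' as the histogram proportions. The result has length M + 3.
#'
#' @param h length-M CSP histogram.
#' @param indices a [spatial_indices()] result (or any list with `I_r`,
#'   `I_theta`, `I_Theta`).
#' @param M total number of CSPs.
#' @return Numeric vector of length M + 3.
#' @export
augment_features <- function(h, indices, M) {
  if (length(h) != M) stop("histogram length ", length(h), " != M = ", M)
  out <- c(h, indices$I_r / M, indices$I_theta / M, indices$I_Theta / M)
  names(out) <- c(paste0("h_", seq_len(M)), "I_r", "I_theta", "I_Theta")
  out
}

#' Augmented feature matrix for a set of images
#'
#' Computes, for each image, the CSP histogram of its boundary primitives
#' under `model` and the three scaled spatial indices, assembled into one
#' row per image.
#'
#' @param prepared per-image data from [prepare_colony_data()].
#' @param model a [fit_csp_model()] result.
#' @return List with `features` ((M+3)-column matrix), `group` and
#'   `image_id` vectors.
#' @export
csp_feature_matrix <- function(prepared, model) {
  rows <- lapply(prepared, function(p) {
    h <- csp_histogram(assign_csp(p$lengths_um, model), model$M)
    augment_features(h, p$indices, model$M)
  })
  list(features = do.call(rbind, rows),
       group = vapply(prepared, `[[`, character(1), "group"),
       image_id = vapply(prepared, `[[`, character(1), "image_id"))
}

#' Write a CSP model to JSON
#'
#' @param model a [csp_model].
#' @param path output path.
#' @export
write_csp_model <- function(model, path) {
  stopifnot(inherits(model, "csp_model"))
  obj <- list(format = "csp_model", version = 1L, D = model$D, K = model$K,
              m = model$m, M = model$M, seed = model$seed,
              groups = model$groups, group_of_centre = model$group_of_centre,
              inertia = as.list(model$inertia),
              centres = apply(model$centres, 1, as.numeric, simplify = FALSE))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a CSP model from JSON
#'
#' @param path path written by [write_csp_model()].
#' @return A [csp_model].
#' @export
read_csp_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "csp_model")) stop("not a csp_model file: ", path)
  centres <- do.call(rbind, obj$centres)
  rownames(centres) <- unlist(lapply(obj$groups, function(g)
    paste0(g, ".", seq_len(obj$K))))
  structure(
    list(centres = centres, group_of_centre = obj$group_of_centre,
         groups = obj$groups, K = obj$K, m = obj$m, M = obj$M, D = obj$D,
         seed = obj$seed, inertia = unlist(obj$inertia)),
    class = "csp_model")
}
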