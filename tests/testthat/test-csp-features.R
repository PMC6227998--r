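# A tiny deterministic representation space: tight Gaussian clouds around
# known means, so k-means has an unambiguous solution.
cloud_space <- function(means, n = 40, sd = 0.5, D = 4, seed = 1) {
  x <- withr::with_seed(seed, do.call(rbind, lapply(means, function(mu)
    matrix(rnorm(n * D, mu, sd), n, D))))
  list(lengths_um = x, image_id = rep("x", nrow(x)), D = D)
}

test_that("model layout: m groups x K centres, labelled in group order", {
  spaces <- list(g1 = cloud_space(c(10, 100), seed = 1),
                 g2 = cloud_space(c(20, 200), seed = 2))
  model <- fit_csp_model(spaces, K = 5, seed = 3)
  expect_equal(model$M, 10)
  expect_equal(dim(model$centres), c(10, 4))
  expect_equal(model$group_of_centre, rep(c("g1", "g2"), each = 5))
  expect_equal(model$groups, c("g1", "g2"))
  expect_error(fit_csp_model(spaces, K = 0), "positive integer")
  expect_error(fit_csp_model(list(g = cloud_space(10, n = 2)), K = 5),
               "cannot fit")
})

test_that("K = 1 reduces to the component-wise mean", {
  sp <- cloud_space(c(3, 30), seed = 4)
  model <- fit_csp_model(list(g = sp), K = 1, seed = 1)
  expect_equal(drop(model$centres), colMeans(sp$lengths_um),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("well-separated clouds recover their means", {
  x10 <- matrix(10, 30, 4) + withr::with_seed(5, matrix(rnorm(120, 0, 0.3), 30))
  x100 <- matrix(100, 30, 4) + withr::with_seed(6, matrix(rnorm(120, 0, 0.3), 30))
  model <- fit_csp_model(list(g = list(lengths_um = rbind(x10, x100), D = 4)),
                         K = 2, seed = 9)
  cen <- model$centres[order(model$centres[, 1]), ]
  expect_lt(max(abs(cen[1, ] - colMeans(x10))), 1)
  expect_lt(max(abs(cen[2, ] - colMeans(x100))), 1)
  # each group's centre is nearer its own cloud mean than the other's
  expect_lt(sum((cen[1, ] - colMeans(x10))^2), sum((cen[1, ] - colMeans(x100))^2))
})

test_that("k-means is deterministic given the seed and ends at a fixpoint", {
  spaces <- list(g = cloud_space(c(1, 5, 9), n = 50, seed = 7))
  m1 <- fit_csp_model(spaces, K = 3, seed = 42)
  m2 <- fit_csp_model(spaces, K = 3, seed = 42)
  expect_identical(m1$centres, m2$centres)
  expect_identical(m1$inertia, m2$inertia)
  # fixpoint: every primitive is assigned to its nearest centre, and the
  # centres are the means of their assigned primitives
  lab <- assign_csp(spaces$g$lengths_um, m1)
  for (k in sort(unique(lab)))
    expect_equal(colMeans(spaces$g$lengths_um[lab == k, , drop = FALSE]),
                 m1$centres[k, ], tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("nearest-CSP assignment matches brute force with smallest-index ties", {
  model <- structure(
    list(centres = rbind(c(0, 0), c(2, 0), c(5, 5), c(9, 1), c(2, 0)),
         D = 2, M = 5, K = 5, m = 1, groups = "g",
         group_of_centre = rep("g", 5)),
    class = "csp_model")
  expect_equal(assign_csp(rbind(c(5, 5)), model), 3)     # exact centre
  expect_equal(assign_csp(rbind(c(2, 0)), model), 2)     # duplicate: smaller i
  expect_equal(assign_csp(rbind(c(1, 0)), model), 1)     # equidistant 1 vs 2
  x <- withr::with_seed(8, matrix(runif(200 * 2, 0, 10), 200))
  brute <- apply(x, 1, function(v) {
    d <- colSums((t(model$centres) - v)^2)
    which(d <= min(d) + 1e-12)[1]
  })
  expect_equal(assign_csp(x, model), brute)
  expect_error(assign_csp(matrix(0, 1, 3), model), "dimension")
})

test_that("histograms are normalized tallies", {
  expect_equal(unname(csp_histogram(rep(3, 8), M = 5)), c(0, 0, 1, 0, 0))
  expect_equal(unname(csp_histogram(c(1, 1, 2, 2), M = 2)), c(0.5, 0.5))
  labs <- withr::with_seed(2, sample(1:7, 100, TRUE))
  h <- csp_histogram(labs, M = 7)
  expect_equal(unname(h), as.vector(table(factor(labs, 1:7))) / 100)
  expect_equal(sum(h), 1)
  expect_error(csp_histogram(integer(0), M = 3), "empty")
  expect_error(csp_histogram(c(1, 9), M = 3), "1..M")
})

test_that("augmentation appends the scaled indices in order", {
  h <- rep(1 / 20, 20)
  idx <- list(I_r = 0.4, I_theta = 1.2, I_Theta = -0.1)
  a <- augment_features(h, idx, M = 20)
  expect_length(a, 23)
  expect_equal(unname(a[21:23]), c(0.4, 1.2, -0.1) / 20)
  a33 <- augment_features(rep(1 / 30, 30), idx, M = 30)
  expect_length(a33, 33)
  z <- augment_features(h, list(I_r = 0, I_theta = 0, I_Theta = 0), M = 20)
  expect_equal(unname(z), c(h, 0, 0, 0))
  expect_error(augment_features(h, idx, M = 19), "!= M")
})

test_that("histogram features are translation-invariant", {
  px <- random_blob(24, seed = 11)
  big <- matrix(FALSE, 40, 40); big[3:26, 9:32] <- px
  img1 <- binary_image(px, resolution = 2)
  img2 <- binary_image(big, resolution = 2)
  sp1 <- shape_primitives(img1, D = 4)
  sp2 <- shape_primitives(img2, D = 4)
  model <- fit_csp_model(list(g = list(lengths_um = sp1$lengths_um, D = 4)),
                         K = 3, seed = 1)
  expect_equal(csp_histogram(assign_csp(sp1, model), 3),
               csp_histogram(assign_csp(sp2, model), 3))
})

test_that("models round-trip through JSON", {
  spaces <- list(gA = cloud_space(c(10, 50), seed = 3),
                 gB = cloud_space(c(30, 90), seed = 4))
  model <- fit_csp_model(spaces, K = 4, seed = 5)
  f <- tempfile(fileext = ".json")
  write_csp_model(model, f)
  back <- read_csp_model(f)
  expect_equal(back$centres, model$centres)
  expect_equal(back$group_of_centre, model$group_of_centre)
  expect_equal(back$K, model$K)
  expect_equal(back$M, model$M)
  expect_equal(back$D, model$D)
  lab <- withr::with_seed(1, matrix(runif(40, 0, 100), 10, 4))
  expect_equal(assign_csp(lab, back), assign_csp(lab, model))
})
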