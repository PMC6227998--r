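# Classification tests run on small 128 px synthetic colonies (helper
# small_groups) so that chord measurement and k-means stay fast.

test_that("single-feature LDA separates, ties to the first class, handles zeros", {
  fit <- fit_single_feature_lda(c(0, 0, 0, 1, 1, 1), rep(c("a", "b"), each = 3))
  expect_equal(predict(fit, c(0.4, 0.6)), c("a", "b"))  # boundary at 0.5
  expect_equal(mean(predict(fit, c(0, 0, 0, 1, 1, 1)) ==
                      rep(c("a", "b"), each = 3)), 1)

  x <- withr::with_seed(1, c(rnorm(20, 0, 0.1), rnorm(20, 10, 0.1),
                             rnorm(20, 20, 0.1)))
  y <- rep(c("a", "b", "c"), each = 20)
  fit3 <- fit_single_feature_lda(x, y)
  expect_equal(mean(predict(fit3, x) == y), 1)

  # zero pooled variance: classify by nearest class mean
  fz <- fit_single_feature_lda(c(1, 1, 3, 3), c("a", "a", "b", "b"))
  expect_equal(fz$pooled_var, 0)
  expect_equal(predict(fz, c(1.9, 2.1)), c("a", "b"))
  # exact tie between class means: first class in class order
  expect_equal(predict(fz, 2), "a")

  # all class means identical: the first class is predicted
  fi <- fit_single_feature_lda(c(2, 2, 2, 2), c("a", "a", "b", "b"))
  expect_equal(predict(fi, c(0, 2, 5)), c("a", "a", "a"))
})

test_that("1-D LDA with uniform priors agrees with MASS::lda", {
  skip_if_not_installed("MASS")
  x <- withr::with_seed(2, c(rnorm(30, 0), rnorm(30, 2.5), rnorm(30, 6)))
  y <- rep(c("a", "b", "c"), each = 30)
  fit <- fit_single_feature_lda(x, y)
  ref <- MASS::lda(data.frame(x = x), grouping = y,
                   prior = rep(1 / 3, 3))
  xn <- withr::with_seed(3, runif(50, -2, 8))
  got <- predict(fit, xn)
  want <- as.character(predict(ref, data.frame(x = xn))$class)
  expect_equal(got, want)
})

test_that("exhaustive selection finds the dominant feature, smallest index on ties", {
  y <- rep(c("a", "b"), each = 10)
  X <- withr::with_seed(4, cbind(noise1 = runif(20), sep = c(rnorm(10, 0, 0.1),
                                                             rnorm(10, 5, 0.1)),
                                 noise2 = runif(20)))
  sel <- select_best_feature(X, y)
  expect_equal(sel$j, 2)
  expect_equal(sel$accuracy, 1)

  Xt <- cbind(f1 = c(0, 0, 1, 1), f2 = c(0, 0, 1, 1))
  st <- select_best_feature(Xt, c("a", "a", "b", "b"))
  expect_equal(st$j, 1)
  expect_equal(st$tied, c(1, 2))

  # equivalence with a brute-force per-coordinate scan: same accuracies,
  # winner = highest Fisher separation among the accuracy-tied set
  Xr <- withr::with_seed(5, matrix(rnorm(20 * 8), 20))
  yr <- rep(c("a", "b"), 10)
  sel <- select_best_feature(Xr, yr)
  brute <- vapply(seq_len(ncol(Xr)), function(j) {
    f <- fit_single_feature_lda(Xr[, j], yr)
    mean(predict(f, Xr[, j]) == yr)
  }, numeric(1))
  expect_equal(sel$scores, brute)
  tied <- which(brute >= max(brute) - 1e-12)
  ratio <- vapply(tied, function(j) {
    m <- tapply(Xr[, j], yr, mean)
    s <- sum(tapply(Xr[, j], yr, function(v) sum((v - mean(v))^2)))
    var(m) / (s / (length(yr) - 2))
  }, numeric(1))
  expect_equal(sel$j, tied[which.max(ratio)])
  expect_equal(sort(sel$tied), sort(tied))
})

test_that("identically distributed classes score near chance out of sample", {
  accs <- withr::with_seed(6, vapply(1:100, function(i) {
    x <- rnorm(40); y <- rep(c("a", "b"), each = 20)
    train <- c(sample(1:20, 10), sample(21:40, 10))
    fit <- fit_single_feature_lda(x[train], y[train])
    mean(predict(fit, x[-train]) == y[-train])
  }, numeric(1)))
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("splits are stratified and even, odd groups favour training", {
  g <- rep(c("A", "B"), c(10, 9))
  tr <- split_train_test(g, seed = 3)
  expect_equal(sum(tr[g == "A"]), 5)  # 5 train / 5 test
  expect_equal(sum(tr[g == "B"]), 5)  # 5 train / 4 test
  expect_equal(sum(!tr[g == "B"]), 4)
  expect_identical(split_train_test(g, seed = 3), tr)
})

test_that("train/test runs classify separable synthetic groups", {
  imgs <- small_groups(n_per_group = 6, seed = 10)
  prep <- prepare_colony_data(imgs, D = 4, seed = 1)
  run <- train_test_evaluate(D = 4, K = 5, split_seed = 2, kmeans_seed = 3,
                             prepared = prep)
  expect_gte(run$accuracy, 0.8)
  expect_equal(run$M, 10)
  expect_length(run$test_ids, 6)
  expect_true(run$best_feature %in% c(paste0("h_", 1:10),
                                      c("I_r", "I_theta", "I_Theta")))
})

test_that("repeated evaluation aggregates runs consistently and deterministically", {
  imgs <- small_groups(n_per_group = 5, seed = 11)
  prep <- prepare_colony_data(imgs, D = 4, seed = 1)
  r <- repeated_evaluation(D = 4, K = 3, n = 8, seed = 21, prepared = prep)
  expect_equal(r$mu, mean(r$accuracies))
  expect_equal(r$sigma, sd(r$accuracies))
  expect_length(r$accuracies, 8)
  expect_true(all(r$accuracies >= 0 & r$accuracies <= 1))
  expect_true(all(r$index_counts >= 0 & r$index_counts <= 8))

  r2 <- repeated_evaluation(D = 4, K = 3, n = 8, seed = 21, prepared = prep)
  expect_identical(r$accuracies, r2$accuracies)
  expect_identical(r$best_features, r2$best_features)

  r1 <- repeated_evaluation(D = 4, K = 3, n = 1, seed = 5, prepared = prep)
  expect_equal(r1$sigma, 0)
})

test_that("LOOCV classifies each image exactly once with per-fold refits", {
  imgs <- small_groups(n_per_group = 5, seed = 12)
  prep <- prepare_colony_data(imgs, D = 4, seed = 1)
  lo <- loocv_evaluate(D = 4, K = 3, seed = 7, prepared = prep)
  expect_equal(lo$S, 10)
  expect_length(lo$correct, 10)          # one classification event per image
  expect_equal(lo$accuracy, mean(lo$correct))
  expect_gte(lo$accuracy, 0.8)           # separable regimes
  expect_identical(loocv_evaluate(D = 4, K = 3, seed = 7, prepared = prep)$correct,
                   lo$correct)
})

test_that("feature analysis reports every feature tied at the best test score", {
  imgs <- small_groups(n_per_group = 5, seed = 13)
  prep <- prepare_colony_data(imgs, D = 4, seed = 1)
  fa <- feature_analysis(D = 4, K = 10, split_seed = 4, kmeans_seed = 5,
                         prepared = prep)
  expect_equal(fa$n_features, 23)  # K * m + 3 for two groups, K = 10
  expect_equal(fa$best_score, max(fa$test_scores))
  expect_setequal(fa$best_features,
                  names(fa$test_scores)[fa$test_scores >= fa$best_score - 1e-12])
  if (!is.null(fa$csp_centres))
    expect_equal(ncol(fa$csp_centres), 4)
})

test_that("increasing group separation never decreases mean accuracy", {
  # groups differ only in filament length; the ladder widens the gap
  mus <- vapply(c(12, 20, 30), function(len) {
    imgs <- small_groups(n_per_group = 5, seed = 30,
                         lengths = c(a = len, b = 10),
                         n_filaments = c(a = 10, b = 10))
    prep <- prepare_colony_data(imgs, D = 4, seed = 2)
    repeated_evaluation(D = 4, K = 3, n = 10, seed = 9, prepared = prep)$mu
  }, numeric(1))
  expect_true(all(diff(mus) >= -0.05))  # monotone up to run noise
  expect_gte(mus[3], mus[1])
})
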