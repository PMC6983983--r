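test_that("fold assignment balances sizes and stratifies classes", {
  labels <- rep(c("lysine", "cobalamin", "glycine", "SAM-alpha", "SAM-IV",
                  "cyclic-di-GMP-I", "SAH"),
                times = c(47, 430, 44, 40, 40, 155, 52))
  fold <- vfold_assign(labels, v = 10, seed = 1)
  sizes <- as.integer(table(fold))
  expect_equal(sort(sizes), c(80L, 80L, rep(81L, 8)))  # 808 over 10 folds
  expect_equal(sum(sizes), 808L)
  # each class spread as evenly as possible across folds
  for (cl in unique(labels)) {
    per_fold <- table(factor(fold[labels == cl], levels = 1:10))
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
})

test_that("fold assignment: leave-one-out, determinism, N < V error", {
  labels <- rep(c("a", "b"), 5)
  expect_equal(sort(table(vfold_assign(labels, v = 10, seed = 2))),
               sort(table(1:10)))  # ten singletons
  expect_identical(vfold_assign(labels, v = 5, seed = 3),
                   vfold_assign(labels, v = 5, seed = 3))
  expect_error(vfold_assign(labels[1:4], v = 5), "fewer observations")
})

test_that("all four classifiers perfectly separate well-planted families", {
  specs <- list(
    family_spec("near", 30, 100, 2, tibble::tibble(
      motif = "GGAUCCAA", location = 10L, prevalence = 1, jitter = 0L)),
    family_spec("far", 30, 100, 2, tibble::tibble(
      motif = "GGAUCCAA", location = 80L, prevalence = 1, jitter = 0L))
  )
  bench <- generate_benchmark(specs, seed = 4)
  blocks <- tibble::tibble(family = c("near", "far"), motif = "GGAUCCAA",
                           canonical_location = c(10L, 80L),
                           prevalence = 1)
  feats <- build_feature_matrix(bench$records, blocks)
  for (clf in c("lda", "pnn", "tree", "knn")) {
    cv <- cross_validate(feats, classifier = clf, v = 10, seed = 6)
    expect_equal(cv$ccr_mean, 1, info = clf)
    expect_equal(cv$fold_ccr, rep(1, 10), info = clf)
    expect_true(all(cv$confusion$counts[!diag(2) == 1] == 0), info = clf)
  }
})

test_that("KNN with K=1 maps training points to their own labels", {
  withr::with_seed(10, {
    x <- matrix(runif(40), nrow = 8)
    y <- rep(c("a", "b"), each = 4)
  })
  expect_equal(train_predict(x, y, x, "knn", k = 1), y)
})

test_that("PNN posteriors are a proper distribution over classes", {
  withr::with_seed(12, {
    train <- matrix(rnorm(60), nrow = 12)
    test <- matrix(rnorm(25), nrow = 5)
    y <- rep(c("a", "b", "c"), each = 4)
  })
  post <- pnn_posteriors(train, y, test, sigma = 0.7)
  expect_equal(rowSums(post), rep(1, 5))
  expect_true(all(post >= 0))
  expect_equal(colnames(post), c("a", "b", "c"))
})

test_that("PNN degenerates to 1-NN as the bandwidth shrinks", {
  withr::with_seed(13, {
    train <- matrix(rnorm(36), nrow = 6)
    y <- rep(c("a", "b", "c"), 2)
    test <- matrix(rnorm(60), nrow = 10)
  })
  pnn <- train_predict(train, y, test, "pnn", sigma = 1e-4)
  nn1 <- train_predict(train, y, test, "knn", k = 1)
  expect_equal(pnn, nn1)
})

test_that("LDA recovers the midpoint boundary on a 1-feature toy problem", {
  # equal-variance classes centred at 0 and 3: boundary at 1.5
  train <- matrix(c(-1, 0, 1, 2, 3, 4), ncol = 1)
  y <- rep(c("lo", "hi"), each = 3)
  test <- matrix(c(1.4, 1.6), ncol = 1)
  expect_equal(train_predict(train, y, test, "lda"), c("lo", "hi"))
})

test_that("in-package LDA and KNN agree with reference implementations", {
  skip_if_not_installed("MASS")
  skip_if_not_installed("class")
  specs <- list(
    family_spec("p", 20, 60, 2, tibble::tibble(
      motif = "GGAUCCAA", location = 10L, prevalence = 1, jitter = 2L)),
    family_spec("q", 20, 60, 2, tibble::tibble(
      motif = "CCAUGGUU", location = 35L, prevalence = 1, jitter = 2L))
  )
  bench <- generate_benchmark(specs, seed = 17)
  blocks <- tibble::tibble(family = c("p", "q"),
                           motif = c("GGAUCCAA", "CCAUGGUU"),
                           canonical_location = c(10L, 35L), prevalence = 1)
  feats <- build_feature_matrix(bench$records, blocks)
  x <- feature_values(feats)
  y <- feats$family
  train <- seq_len(30)
  test <- setdiff(seq_len(40), train)
  ours_lda <- train_predict(x[train, ], y[train], x[test, ], "lda")
  ref <- MASS::lda(x[train, ], grouping = y[train],
                   prior = c(0.5, 0.5))
  ref_lda <- as.character(predict(ref, x[test, ])$class)
  expect_equal(ours_lda, ref_lda)
  ours_nn <- train_predict(x[train, ], y[train], x[test, ], "knn", k = 1)
  # class::knn on the same standardized scale our KNN uses
  mu <- colMeans(x[train, ]); s <- apply(x[train, ], 2, sd); s[s == 0] <- 1
  zs <- function(m) sweep(sweep(m, 2, mu), 2, s, "/")
  ref_nn <- as.character(class::knn(zs(x[train, ]), zs(x[test, ]),
                                    cl = y[train], k = 1))
  expect_equal(ours_nn, ref_nn)
})

test_that("cross-validation predicts each observation exactly once", {
  specs <- list(
    family_spec("u", 15, 50, 2, tibble::tibble(
      motif = "GGAUCCAA", location = 5L, prevalence = 1, jitter = 1L)),
    family_spec("v", 15, 50, 2, tibble::tibble(
      motif = "GGAUCCAA", location = 30L, prevalence = 1, jitter = 1L))
  )
  bench <- generate_benchmark(specs, seed = 23)
  blocks <- tibble::tibble(family = "u", motif = "GGAUCCAA",
                           canonical_location = 5L, prevalence = 1)
  feats <- build_feature_matrix(bench$records, blocks)
  cv <- cross_validate(feats, "knn", v = 5, seed = 8)
  expect_equal(sort(cv$predictions$id), sort(feats$id))
  expect_equal(sum(cv$confusion$counts), 30)
  expect_equal(cv$ccr_pooled, ccr(cv$confusion))
  # repeated runs are byte-identical
  cv2 <- cross_validate(feats, "knn", v = 5, seed = 8)
  expect_identical(cv$predictions, cv2$predictions)
  # tidy/glance interfaces
  expect_equal(nrow(tidy(cv)), 2)
  g <- glance(cv)
  expect_equal(g$classifier, "knn")
  expect_true(all(c("ccr_mean", "ccr_pooled", "macro_accuracy") %in%
                    names(g)))
})

test_that("degenerate training sets are flagged", {
  x <- matrix(rnorm(20), nrow = 10)
  expect_error(train_predict(x, rep("a", 10), x, "lda"), "single class")
  # a singleton class disappears from training when its only member is
  # held out; prediction proceeds over the remaining classes
  feats <- tibble::tibble(
    id = sprintf("o%d", 1:21),
    family = c("rare", rep(c("x", "y"), each = 10)),
    b1 = c(5L, rep(c(10L, 60L), each = 10)),
    b2 = rep(c(3L, 8L, 40L), times = c(1, 10, 10))
  )
  expect_warning(cross_validate(feats, "knn", v = 5, seed = 2),
                 "lacks class")
})
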