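#' Assign observations to cross-validation folds
#'
#' Partitions `N = length(labels)` observations into `v` disjoint folds of
#' near-equal size (sizes differ by at most 1). With `stratified = TRUE`
#' (the default) each class's members are spread across folds as evenly as
#' possible, which keeps the 40-member families represented in every
#' training split. Deterministic given `seed`.
#'
#' @param labels Class label per observation.
#' @param v Number of folds (default 10).
#' @param seed Integer RNG seed.
#' @param stratified Spread each class evenly over folds?
#' @return Integer vector of fold ids in `1..v`, one per observation.
#' @export
vfold_assign <- function(labels, v = 10, seed = 1, stratified = TRUE) {
  n <- length(labels)
  if (n < v) stop("fewer observations (", n, ") than folds (", v, ")",
                  call. = FALSE)
  stopifnot(v >= 2)
  withr::with_seed(seed, {
    fold <- integer(n)
    counter <- 0L
    groups <- if (stratified) {
      split(seq_len(n), factor(labels, levels = sort(unique(labels))))
    } else {
      list(seq_len(n))
    }
    for (idx in groups) {
      idx <- if (length(idx) > 1) sample(idx) else idx
      fold[idx] <- (counter + seq_along(idx) - 1L) %% v + 1L
      counter <- counter + length(idx)
    }
    fold
  })
}

standardize_fit <- function(x) {
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[!is.finite(s) | s == 0] <- 1  # zero-variance guard: leave unscaled
  list(mu = mu, s = s)
}

standardize_apply <- function(x, fit) {
  sweep(sweep(x, 2, fit$mu, "-"), 2, fit$s, "/")
}

sq_dist <- function(a, b) {
  # squared Euclidean distances, rows of a vs rows of b
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

lda_predict <- function(train_x, train_y, test_x, shrinkage = 1e-3,
                        priors = c("equal", "proportional")) {
  priors <- match.arg(priors)
  classes <- sort(unique(train_y))
  p <- ncol(train_x)
  means <- matrix(vapply(classes, function(cl) {
    colMeans(train_x[train_y == cl, , drop = FALSE])
  }, numeric(p)), nrow = length(classes), byrow = TRUE)
  # pooled within-class covariance
  sw <- matrix(0, p, p)
  for (cl in classes) {
    xc <- scale(train_x[train_y == cl, , drop = FALSE], scale = FALSE)
    sw <- sw + crossprod(xc)
  }
  sw <- sw / (nrow(train_x) - length(classes))
  ridge <- mean(diag(sw))
  if (ridge <= 0) ridge <- 1  # fully degenerate within-class scatter
  sw <- (1 - shrinkage) * sw + shrinkage * ridge * diag(p)
  w <- solve(sw, t(means))                       # p x K
  const <- 0.5 * colSums(t(means) * w)           # K
  scores <- test_x %*% w - rep(const, each = nrow(test_x))
  if (priors == "proportional") {
    logpri <- log(as.numeric(table(factor(train_y, classes))) /
                    length(train_y))
    scores <- scores + rep(logpri, each = nrow(test_x))
  }
  classes[max.col(scores, ties.method = "first")]
}

pnn_posterior <- function(train_x, train_y, test_x, sigma = 1) {
  classes <- sort(unique(train_y))
  d2 <- sq_dist(test_x, train_x)
  # per-row shift keeps the kernel sums finite; as sigma -> 0+ the nearest
  # training point dominates and the rule degenerates to 1-NN
  shift <- apply(d2, 1, min)
  kern <- exp(-(d2 - shift) / (2 * sigma^2))
  sums <- vapply(classes, function(cl) {
    rowSums(kern[, train_y == cl, drop = FALSE])
  }, numeric(nrow(test_x)))
  sums <- matrix(sums, nrow = nrow(test_x),
                 dimnames = list(NULL, classes))
  # priors proportional to class counts cancel the 1/n_c density norm
  post <- sums / rowSums(sums)
  post
}

knn_predict <- function(train_x, train_y, test_x, k = 4) {
  d2 <- sq_dist(test_x, train_x)
  apply_one <- function(d) {
    ord <- order(d, seq_along(d))   # stable: distance ties -> lower index
    nb <- train_y[ord[seq_len(min(k, length(d)))]]
    votes <- table(nb)
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1) return(top)
    nb[nb %in% top][1]              # vote tie -> nearest among tied classes
  }
  vapply(seq_len(nrow(test_x)), function(i) apply_one(d2[i, ]), character(1))
}

tree_predict <- function(train_x, train_y, test_x, min_leaf = 5) {
  df <- as.data.frame(train_x)
  df$.y <- factor(train_y)
  fit <- rpart::rpart(
    .y ~ ., data = df, method = "class",
    parms = list(split = "gini"),
    control = rpart::rpart.control(
      minbucket = min_leaf, minsplit = 2L * min_leaf, cp = 0,
      xval = 0, maxcompete = 0, maxsurrogate = 0, usesurrogate = 0
    )
  )
  as.character(predict(fit, as.data.frame(test_x), type = "class"))
}

#' Train a classifier and predict test labels
#'
#' The four classifiers used to validate block location features:
#' \describe{
#'   \item{`lda`}{class-wise means with a pooled, shrinkage-regularised
#'     covariance; assignment to the highest linear discriminant score
#'     (equal priors by default).}
#'   \item{`pnn`}{probabilistic neural network: Parzen-window
#'     class-conditional densities with an isotropic Gaussian kernel of
#'     bandwidth `sigma` on standardized features; Bayes' rule with priors
#'     proportional to training counts.}
#'   \item{`tree`}{greedy binary decision tree on raw features, Gini
#'     impurity, minimum leaf size `min_leaf`, leaf-majority prediction.}
#'   \item{`knn`}{k-nearest neighbours, Euclidean distance, `k = 4` by
#'     default; vote ties go to the nearest neighbour among tied classes.}
#' }
#' Features are standardized per column (training statistics only) for
#' `lda`, `pnn` and `knn`; location features span 0 to 200+ nucleotides and
#' the distance-based rules are scale-sensitive. All four are deterministic
#' given their inputs.
#'
#' @param train_x,test_x Numeric matrices with matching columns.
#' @param train_y Class label per training row (at least 2 classes).
#' @param classifier One of `"lda"`, `"pnn"`, `"tree"`, `"knn"`.
#' @param k Neighbourhood size for `knn`.
#' @param sigma Gaussian kernel bandwidth for `pnn` (standardized units).
#' @param shrinkage LDA covariance regulariser in `[0, 1]`.
#' @param min_leaf Decision-tree minimum leaf size.
#' @return Character vector of predicted labels, one per test row.
#' @export
train_predict <- function(train_x, train_y, test_x,
                          classifier = c("lda", "pnn", "tree", "knn"),
                          k = 4, sigma = 1, shrinkage = 1e-3, min_leaf = 5) {
  classifier <- match.arg(classifier)
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  if (ncol(train_x) != ncol(test_x)) {
    stop("train and test feature columns differ", call. = FALSE)
  }
  if (length(unique(train_y)) < 2) {
    stop("training set has a single class", call. = FALSE)
  }
  if (classifier %in% c("lda", "pnn", "knn")) {
    zfit <- standardize_fit(train_x)
    train_x <- standardize_apply(train_x, zfit)
    test_x <- standardize_apply(test_x, zfit)
  }
  switch(classifier,
    lda  = lda_predict(train_x, train_y, test_x, shrinkage = shrinkage),
    pnn  = {
      post <- pnn_posterior(train_x, train_y, test_x, sigma = sigma)
      colnames(post)[max.col(post, ties.method = "first")]
    },
    tree = tree_predict(train_x, train_y, test_x, min_leaf = min_leaf),
    knn  = knn_predict(train_x, train_y, test_x, k = k)
  )
}

#' PNN class posterior probabilities
#'
#' Parzen-window posteriors (rows sum to 1) for inspection and testing;
#' [train_predict()] uses the same computation internally.
#'
#' @inheritParams train_predict
#' @param standardize Standardize features with training statistics first?
#' @return Matrix of posteriors, one row per test row, columns = classes.
#' @export
pnn_posteriors <- function(train_x, train_y, test_x, sigma = 1,
                           standardize = TRUE) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  if (standardize) {
    zfit <- standardize_fit(train_x)
    train_x <- standardize_apply(train_x, zfit)
    test_x <- standardize_apply(test_x, zfit)
  }
  pnn_posterior(train_x, train_y, test_x, sigma = sigma)
}

#' Cross-validate a classifier on block location features
#'
#' V-fold cross-validation: the observations are partitioned into `v`
#' near-equal folds ([vfold_assign()]); each fold in turn is held out as
#' test data while the classifier trains on the rest, so every observation
#' is predicted exactly once. The overall correct classification rate (CCR)
#' is reported both as the mean of per-fold CCRs and as the pooled
#' trace/total of the accumulated confusion matrix.
#'
#' @param features Feature tibble from [extract_features()] (columns `id`,
#'   `family`, then one column per block).
#' @param classifier One of `"lda"`, `"pnn"`, `"tree"`, `"knn"`.
#' @param v Number of folds (default 10).
#' @param seed RNG seed for the fold partition.
#' @param stratified Stratify folds by family?
#' @param ... Passed to [train_predict()] (`k`, `sigma`, `shrinkage`,
#'   `min_leaf`).
#' @return An object of class `riboblock_cv`: a list with elements
#'   `classifier`, `predictions` (tibble `id`, `family`, `fold`,
#'   `predicted`), `fold_ccr`, `ccr_mean`, `ccr_pooled`, `confusion`
#'   (a [confusion_matrix()] object) and `config`. Methods: [tidy()],
#'   [glance()], [autoplot()], `print()`.
#' @export
cross_validate <- function(features, classifier = c("lda", "pnn", "tree",
                                                    "knn"),
                           v = 10, seed = 1, stratified = TRUE, ...) {
  classifier <- match.arg(classifier)
  x <- feature_values(features)
  y <- features$family
  classes <- sort(unique(y))
  fold <- vfold_assign(y, v = v, seed = seed, stratified = stratified)
  stopifnot(length(unique(fold)) == v,
            max(table(fold)) - min(table(fold)) <= 1)
  predicted <- character(length(y))
  fold_ccr <- numeric(v)
  for (f in seq_len(v)) {
    test <- fold == f
    missing_cls <- setdiff(classes, unique(y[!test]))
    if (length(missing_cls) > 0) {
      warning("fold ", f, " training data lacks class(es): ",
              paste(missing_cls, collapse = ", "), call. = FALSE)
    }
    predicted[test] <- train_predict(x[!test, , drop = FALSE], y[!test],
                                     x[test, , drop = FALSE],
                                     classifier = classifier, ...)
    fold_ccr[f] <- mean(predicted[test] == y[test])
  }
  conf <- confusion_matrix(truth = y, estimate = predicted,
                           classes = classes)
  structure(list(
    classifier = classifier,
    predictions = tibble(id = features$id, family = y, fold = fold,
                         predicted = predicted),
    fold_ccr = fold_ccr,
    ccr_mean = mean(fold_ccr),
    ccr_pooled = ccr(conf),
    confusion = conf,
    config = list(v = v, seed = seed, stratified = stratified, ...)
  ), class = "riboblock_cv")
}

#' @export
print.riboblock_cv <- function(x, ...) {
  cat("V-fold cross-validation:", x$classifier, "classifier\n")
  cat("  folds:", x$config$v, " observations:", nrow(x$predictions), "\n")
  cat(sprintf("  CCR (mean of fold CCRs): %.2f%%\n", 100 * x$ccr_mean))
  cat(sprintf("  CCR (pooled trace/total): %.2f%%\n", 100 * x$ccr_pooled))
  invisible(x)
}

#' Tidy a cross-validation result
#'
#' @param x A `riboblock_cv` object.
#' @param ... Unused.
#' @return Per-class performance measures, as [class_metrics()] of the
#'   pooled confusion matrix.
#' @method tidy riboblock_cv
#' @export
tidy.riboblock_cv <- function(x, ...) {
  class_metrics(x$confusion)
}

#' One-row summary of a cross-validation result
#'
#' @param x A `riboblock_cv` object.
#' @param ... Unused.
#' @return Tibble with the classifier, fold count, both CCR variants and the
#'   macro-averaged measures.
#' @method glance riboblock_cv
#' @export
glance.riboblock_cv <- function(x, ...) {
  dplyr::bind_cols(
    tibble(classifier = x$classifier, v = x$config$v,
           ccr_mean = x$ccr_mean, ccr_pooled = x$ccr_pooled),
    macro_average(x$confusion)
  )
}
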