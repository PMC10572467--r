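test_that("KNN prediction follows the distance and vote tie rules", {
  X <- rbind(c(0, 0), c(10, 0), c(10, 1))
  y <- c("A", "B", "B")
  # exact training point, k = 1
  expect_identical(knnPredict(X, y, c(10, 0), k = 1), "B")
  # hand-computed distances 9, 1, sqrt(2): majority of 3 nearest is B
  expect_identical(knnPredict(X, y, c(9, 0), k = 3), "B")
  # equidistant training points: lower index wins
  X2 <- rbind(c(-1, 0), c(1, 0))
  expect_identical(knnPredict(X2, c("A", "B"), c(0, 0), k = 1), "A")
  # tied vote resolves to the single nearest neighbour's class
  X3 <- rbind(c(0, 0), c(3, 0), c(3.5, 0), c(4, 0))
  expect_identical(knnPredict(X3, c("A", "A", "B", "B"), c(3.4, 0), k = 4),
                   "B")
  expect_error(knnPredict(X[0, , drop = FALSE], character(0), c(0, 0)),
               "empty training set")
  expect_error(knnPredict(X, y, c(0, 0), k = 5), "exceeds training size")
})

test_that("KNN agrees with an independent implementation on tie-free data", {
  skip_if_not_installed("class")
  set.seed(14)
  for (rep in 1:20) {
    n <- 40; p <- 5
    X <- matrix(rnorm(n * p), n, p)
    y <- sample(c("u", "v", "w"), n, replace = TRUE)
    Q <- matrix(rnorm(10 * p), 10, p)
    ours <- knnPredict(X, y, Q, k = 1)
    ref <- as.character(class::knn(X, Q, factor(y), k = 1))
    expect_identical(ours, ref)
  }
})

test_that("subspace draws are seeded, distinct, and clamped with a warning", {
  set.seed(70)
  X <- matrix(rnorm(40 * 500), 40, 500)
  y <- factor(rep(c("healthy", "MS"), 20))
  m <- fitSubspaceKNN(X, y, seed = 9L)
  expect_identical(m@L, 30L)
  expect_true(all(vapply(m@subsets, length, integer(1)) == 86L))
  expect_true(all(vapply(m@subsets, anyDuplicated, integer(1)) == 0L))
  # learner streams differ from each other
  expect_gt(length(unique(vapply(m@subsets, paste, character(1),
                                 collapse = ","))), 25)
  m2 <- fitSubspaceKNN(X, y, seed = 9L)
  expect_identical(m2@subsets, m@subsets)

  Xs <- X[, 1:50]
  expect_warning(mc <- fitSubspaceKNN(Xs, y, subspaceDim = 86L),
                 "clamped")
  expect_true(all(vapply(mc@subsets, length, integer(1)) == 50L))
  expect_error(fitSubspaceKNN(X, rep("healthy", 40)), "2 classes")
})

test_that("ensemble voting reduces to plain KNN for L = 1 and breaks ties by class order", {
  # agreement case: unanimous learners return their shared label
  set.seed(21)
  X <- matrix(rnorm(30 * 10), 30, 10)
  y <- factor(rep(c("healthy", "MS"), 15))
  m <- suppressWarnings(fitSubspaceKNN(X, y, L = 5L, subspaceDim = 10L,
                                       seed = 2L))
  q <- X[7, ] + 1e-9
  expect_identical(ensemblePredict(m, q), as.character(y[7]))

  # constructed 2-learner split vote: earliest class in order wins
  split <- new("SubspaceKNN",
               subsets = list(1L, 2L), L = 2L, subspaceDim = 1L, k = 1L,
               seed = 0L, trainX = rbind(c(0, 10), c(10, 0)),
               trainY = factor(c("healthy", "MS")),
               classes = c("healthy", "MS"),
               center = c(0, 0), scale = c(1, 1))
  expect_identical(ensemblePredict(split, c(1, 1)), "healthy")

  # property: L = 1 with the full subspace equals plain KNN on the
  # z-normalized features, across 200 random instances
  set.seed(33)
  for (rep in 1:200) {
    n <- sample(10:25, 1); p <- sample(2:6, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- factor(sample(c("A", "B"), n, replace = TRUE))
    if (nlevels(droplevels(y)) < 2) next
    q <- rnorm(p)
    m1 <- suppressWarnings(fitSubspaceKNN(X, y, L = 1L,
                                          subspaceDim = p, k = 1L,
                                          seed = rep))
    Z <- sweep(sweep(X, 2, m1@center), 2, m1@scale, "/")
    zq <- (q - m1@center) / m1@scale
    expect_identical(ensemblePredict(m1, q),
                     knnPredict(Z, as.character(y), zq, k = 1))
  }
})

test_that("stratified folds are balanced partitions, deterministic by seed", {
  y <- rep(c("healthy", "MS"), each = 50)
  fa <- stratifiedKFold(y, K = 10, seed = 4)
  expect_true(all(table(foldIds(fa)) == 10))
  expect_true(all(table(foldIds(fa), y) == 5))

  # uneven classes: per-class fold counts differ by at most one
  y2 <- rep(c("healthy", "MS"), c(101, 49))
  fa2 <- stratifiedKFold(y2, K = 10, seed = 4)
  perClass <- table(foldIds(fa2), y2)
  expect_lte(max(perClass[, 1]) - min(perClass[, 1]), 1)
  expect_lte(max(perClass[, 2]) - min(perClass[, 2]), 1)
  # partition: every sample in exactly one fold
  expect_length(foldIds(fa2), 150L)
  expect_true(all(foldIds(fa2) %in% 1:10))

  expect_identical(foldIds(stratifiedKFold(y2, K = 10, seed = 4)),
                   foldIds(fa2))
  expect_false(identical(foldIds(stratifiedKFold(y2, K = 10, seed = 5)),
                         foldIds(fa2)))
  expect_error(stratifiedKFold(rep(c("a", "b"), c(5, 50)), K = 10),
               "'a' has 5 samples")
})

test_that("cross-validation separates separable data and stays at chance on null data", {
  # linearly separated clusters: diagonal confusion matrix
  set.seed(50)
  n <- 40
  X <- rbind(matrix(rnorm(n / 2 * 5), n / 2, 5),
             matrix(rnorm(n / 2 * 5, mean = 8), n / 2, 5))
  y <- rep(c("healthy", "MS"), each = n / 2)
  fa <- stratifiedKFold(y, K = 10, seed = 1)
  cm <- suppressWarnings(crossValidate(X, y, fa, L = 5, subspaceDim = 5,
                                       seed = 3))
  expect_identical(sum(cm), 40L)
  expect_identical(sum(cm) - sum(diag(cm)), 0L)

  # permuted labels: accuracy within 3 binomial sd of 50%
  set.seed(51)
  Xn <- matrix(rnorm(60 * 5), 60, 5)
  yn <- sample(rep(c("healthy", "MS"), each = 30))
  fan <- stratifiedKFold(yn, K = 10, seed = 2)
  cmn <- suppressWarnings(crossValidate(Xn, yn, fan, L = 5,
                                        subspaceDim = 5, seed = 4))
  acc <- sum(diag(cmn)) / sum(cmn)
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / 60))
})

test_that("per-class one-vs-rest metrics reproduce known F1 arithmetic", {
  # harmonic-mean worked examples on the percentage scale
  expect_equal(round(f1Score(99.60, 100), 2), 99.80)
  expect_equal(round(f1Score(96.92, 99.80), 2), 98.34)
  expect_equal(f1Score(100, 100), 100)
  expect_equal(f1Score(0, 0), 0)

  cm <- matrix(c(5L, 0L, 0L, 5L), 2, 2,
               dimnames = list(c("healthy", "MS"), c("healthy", "MS")))
  met <- computeMetrics(cm)
  expect_true(all(met$accuracy == 100 & met$f1 == 100 &
                    met$recall == 100 & met$precision == 100))
  expect_false(any(met$degenerate))

  # zero-denominator flag: a class never predicted and never present
  cm2 <- matrix(c(8L, 2L, 0L, 0L), 2, 2, byrow = TRUE,
                dimnames = list(c("a", "b"), c("a", "b")))
  met2 <- computeMetrics(cm2)
  expect_true(met2$degenerate[met2$class == "b"])
  expect_identical(met2$recall[met2$class == "b"], 0)

  # F1 lies between min and max of precision and recall
  set.seed(60)
  for (rep in 1:50) {
    P <- runif(1, 0.01, 1); R <- runif(1, 0.01, 1)
    f <- f1Score(P, R)
    expect_gte(f, min(P, R) - 1e-12)
    expect_lte(f, max(P, R) + 1e-12)
  }
})
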