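test_that("equal-width discretization follows the stated bin arithmetic", {
  expect_identical(discretizeFeature(c(0, 1, 2, 3), B = 2)$codes,
                   c(0L, 0L, 1L, 1L))
  expect_identical(discretizeFeature(c(0, 0.49, 0.51, 1), B = 2)$codes,
                   c(0L, 0L, 1L, 1L))
  expect_identical(discretizeFeature(rep(3.7, 5), B = 10)$codes,
                   rep(0L, 5))
  # maximum maps to the top bin, codes stay in range
  x <- runif(100)
  cd <- discretizeFeature(x, B = 7)$codes
  expect_true(all(cd >= 0 & cd <= 6))
  expect_identical(cd[which.max(x)], 6L)
})

test_that("plug-in MI matches direct joint-table computation and its identities", {
  expect_equal(mutualInformation(c(0L, 0L, 1L, 1L), c(0L, 0L, 1L, 1L)), 1)
  expect_equal(mutualInformation(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L)), 0)
  # 3x2 joint table, expected value from the independent brute-force oracle
  a <- c(0L, 0L, 1L, 1L, 2L, 2L); b <- c(0L, 0L, 0L, 1L, 1L, 1L)
  expect_equal(mutualInformation(a, b), miOracle(a, b))
  expect_equal(mutualInformation(a, b), 2 / 3)

  expect_error(mutualInformation(0:3, 0:4), "sample counts differ")

  # property: nonnegative, symmetric, I(X;X) = H(X), equal to the oracle,
  # on random small instances (<= 4 bins, <= 50 samples)
  set.seed(20)
  for (rep in 1:60) {
    n <- sample(5:50, 1)
    a <- sample(0:(sample(2:4, 1) - 1L), n, replace = TRUE)
    b <- sample(0:(sample(2:4, 1) - 1L), n, replace = TRUE)
    mi <- mutualInformation(a, b)
    expect_gte(mi, 0)
    expect_equal(mi, mutualInformation(b, a), tolerance = 1e-12)
    expect_equal(mi, miOracle(a, b), tolerance = 1e-12)
    pa <- tabulate(a + 1L) / n
    expect_equal(mutualInformation(a, a),
                 -sum(pa[pa > 0] * log2(pa[pa > 0])), tolerance = 1e-12)
  }
})

test_that("greedy mRMR ranking matches an exhaustive greedy oracle", {
  # step 1 is always the argmax-relevance feature
  set.seed(31)
  X <- matrix(rnorm(30 * 8), 30, 8)
  y <- factor(rep(c("A", "B"), 15))
  X[y == "B", 5] <- X[y == "B", 5] + 3
  r <- mrmrRank(X, y, m = 8)
  expect_identical(rankedOrder(r)[1], which.max(r@relevance))

  # property: equality with the independently coded oracle over >= 100
  # seeded instances with <= 6 features
  for (s in 1:100) {
    set.seed(1000 + s)
    n <- sample(15:40, 1)
    p <- sample(3:6, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- factor(sample(c("A", "B"), n, replace = TRUE,
                       prob = c(0.5, 0.5)))
    if (nlevels(droplevels(y)) < 2) next
    X[y == "B", 1] <- X[y == "B", 1] + rnorm(1)
    expect_identical(rankedOrder(mrmrRank(X, y, m = p)),
                     mrmrOracle(X, y, m = p),
                     label = sprintf("oracle equality, seed %d", s))
  }

  expect_error(mrmrRank(X, y, m = 50), "exceeds feature count")
})

test_that("redundant copies are demoted below independent features of equal relevance", {
  y <- rep(c(0L, 1L), each = 10)
  x1 <- y; x1[1] <- 1L          # informative, one flip
  x2 <- x1                      # exact copy: redundancy I(x2;x1) = H(x1)
  x3 <- y; x3[20] <- 0L         # equally relevant, different flip
  X <- cbind(x1, x2, x3)
  r <- mrmrRank(X, factor(y), m = 3)
  expect_identical(rankedOrder(r)[1], 1L)   # ties broke to smallest index
  expect_identical(rankedOrder(r)[2], 3L)   # the copy is penalized
  expect_identical(rankedOrder(r)[3], 2L)
})

test_that("iterative size selection minimizes CV error with smallest-q ties", {
  tab <- generateTabular(synthTabularConfig(seed = 5))
  r <- mrmrRank(tab$X, tab$y, m = 20)

  # singleton grid is returned unconditionally
  one <- iterativeSelect(tab$X, tab$y, r, qGrid = 5, folds = 5, seed = 2)
  expect_identical(one@chosenQ, 5L)
  expect_length(chosenFeatures(one), 5L)

  # signal lives in the top-ranked features: error at q = 3 does not
  # exceed error at the largest size
  res <- iterativeSelect(tab$X, tab$y, r, qGrid = c(3, 10, 20),
                         folds = 10, seed = 2)
  err <- selectionCurve(res)
  expect_lte(err$cv_error[err$q == 3], err$cv_error[err$q == 20])

  # deterministic given identical inputs
  res2 <- iterativeSelect(tab$X, tab$y, r, qGrid = c(3, 10, 20),
                          folds = 10, seed = 2)
  expect_identical(selectionCurve(res2), selectionCurve(res))
  expect_identical(res2@chosenQ, res@chosenQ)

  # bit-identical error curve -> smaller q wins: duplicate a perfectly
  # separating feature so q = 1 and q = 2 both classify exactly
  Xdup <- cbind(f1 = c(rep(0, 10), rep(10, 10)),
                f2 = c(rep(0, 10), rep(10, 10)))
  ydup <- factor(rep(c("A", "B"), each = 10))
  rdup <- mrmrRank(Xdup, ydup, m = 2)
  sel <- iterativeSelect(Xdup, ydup, rdup, qGrid = c(1, 2), folds = 5,
                         seed = 1)
  expect_identical(sel@cvError[1], sel@cvError[2])
  expect_identical(sel@chosenQ, 1L)

  expect_error(iterativeSelect(tab$X, tab$y, r, qGrid = integer(0)),
               "empty q grid")
})
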