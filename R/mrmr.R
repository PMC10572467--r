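# Minimum-redundancy maximum-relevance feature ranking with a plug-in
# histogram mutual-information estimator, plus the iterative subset-size
# search over the ranking prefix.
#
# MI is estimated from equal-width discretization (B = 10 bins by default)
# with base-2 logarithms. Equal-width binning over [min, max] is invariant
# under affine transforms, so standardizing features first would not change
# any bin code; features are therefore binned on their raw scale.

#' Equal-width discretization of a feature
#'
#' Bins values into \code{B} equal-width bins over \code{[min(x), max(x)]};
#' the maximum maps to bin \code{B - 1} and a constant feature maps
#' entirely to bin 0.
#'
#' @param x finite numeric vector.
#' @param B number of bins (default 10).
#' @return list with \code{codes} (integer bin indices in \code{0..B-1})
#'   and \code{nBins}.
#' @examples
#' discretizeFeature(c(0, 1, 2, 3), B = 2)$codes  # 0 0 1 1
#' @export
discretizeFeature <- function(x, B = 10L) {
  stopifnot(all(is.finite(x)), B >= 1L)
  B <- as.integer(B)
  rng <- range(x)
  if (rng[1] == rng[2])
    return(list(codes = integer(length(x)), nBins = B))
  codes <- pmin(as.integer(floor((x - rng[1]) / (rng[2] - rng[1]) * B)),
                B - 1L)
  list(codes = codes, nBins = B)
}

# coerce an MI argument (discretized list, factor, or integer codes) to
# 0-based codes plus bin count
asCodes <- function(a) {
  if (is.list(a) && !is.null(a$codes))
    return(list(codes = as.integer(a$codes),
                nBins = max(a$nBins, max(a$codes) + 1L)))
  if (is.factor(a))
    return(list(codes = as.integer(a) - 1L, nBins = nlevels(a)))
  if (is.character(a)) {
    f <- factor(a)
    return(list(codes = as.integer(f) - 1L, nBins = nlevels(f)))
  }
  a <- as.integer(a)
  stopifnot(all(a >= 0L))
  list(codes = a, nBins = max(a) + 1L)
}

#' Plug-in mutual information in bits
#'
#' The maximum-likelihood ("plug-in") estimate
#' \eqn{I = \sum_{a,b} p(a,b) \log_2 \frac{p(a,b)}{p(a)p(b)}}
#' from the joint histogram of two discrete variables. Nonnegative,
#' symmetric, and equal to the entropy H(X) when both arguments are the
#' same variable.
#'
#' @param a,b discretized features (from [discretizeFeature()]), factors,
#'   character labels, or nonnegative integer code vectors of equal length.
#' @return mutual information in bits.
#' @examples
#' mutualInformation(c(0L, 0L, 1L, 1L), c(0L, 0L, 1L, 1L))  # 1 bit
#' mutualInformation(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L))  # 0 bits
#' @export
mutualInformation <- function(a, b) {
  ca <- asCodes(a); cb <- asCodes(b)
  if (length(ca$codes) != length(cb$codes))
    stop("mutualInformation: sample counts differ (",
         length(ca$codes), " vs ", length(cb$codes), ")")
  n <- length(ca$codes)
  joint <- tabulate(ca$codes + ca$nBins * cb$codes + 1L,
                    nbins = ca$nBins * cb$nBins) / n
  pa <- tabulate(ca$codes + 1L, nbins = ca$nBins) / n
  pb <- tabulate(cb$codes + 1L, nbins = cb$nBins) / n
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  max(ent(pa) + ent(pb) - ent(joint), 0)
}

# MI of every column of a 0-based code matrix (B bins each) against one
# fixed code vector v (nbv bins), vectorized as H(a) + H(b) - H(a,b).
miAllColumns <- function(C, v, B, nbv) {
  n <- nrow(C); p <- ncol(C)
  colEnt <- function(cnt, nbins) {
    # cnt: (nbins x p) count matrix
    P <- cnt / n
    Z <- P * log2(P)
    Z[P == 0] <- 0
    -colSums(Z)
  }
  offs <- rep((seq_len(p) - 1L), each = n)
  Ha <- colEnt(matrix(tabulate(as.numeric(C) + offs * B + 1L,
                               nbins = B * p), nrow = B), B)
  pb <- tabulate(v + 1L, nbins = nbv) / n
  Hb <- { q <- pb[pb > 0]; -sum(q * log2(q)) }
  joint <- C + B * v  # v recycles down rows (column-major)
  Hab <- colEnt(matrix(tabulate(as.numeric(joint) + offs * (B * nbv) + 1L,
                                nbins = B * nbv * p), nrow = B * nbv),
                B * nbv)
  pmax(Ha + Hb - Hab, 0)
}

# accept ExemplarFeatures or samples x features matrix
asSampleMatrix <- function(F) {
  if (is(F, "ExemplarFeatures")) featureMatrix(F) else as.matrix(F)
}

#' Greedy mRMR feature ranking (MID criterion)
#'
#' Ranks features by the greedy mutual-information difference criterion:
#' step 1 picks the feature with maximal relevance I(x_j; y); each later
#' step picks the unselected feature maximizing
#' relevance minus the mean redundancy
#' \eqn{I(x_j;y) - \frac{1}{|S|}\sum_{s \in S} I(x_j; x_s)} against the
#' already-selected set S. Score ties break to the smallest feature index.
#'
#' @param F an [ExemplarFeatures-class] or samples x features matrix.
#' @param y class labels (factor or character), one per sample.
#' @param m ranking length (default all features).
#' @param B histogram bins for MI estimation (default 10).
#' @return an [MRMRRanking-class].
#' @export
mrmrRank <- function(F, y, m = NULL, B = 10L) {
  X <- asSampleMatrix(F)
  y <- factor(y)
  if (nlevels(y) < 2L) stop("mrmrRank needs at least 2 classes")
  nf <- ncol(X)
  if (is.null(m)) m <- nf
  m <- as.integer(m)
  if (m > nf) stop("ranking length m = ", m, " exceeds feature count ", nf)
  B <- as.integer(B)
  C <- vapply(seq_len(nf),
              function(j) discretizeFeature(X[, j], B)$codes,
              integer(nrow(X)))
  ycodes <- as.integer(y) - 1L
  relevance <- miAllColumns(C, ycodes, B, nlevels(y))
  redSum <- numeric(nf)
  ord <- integer(m); scores <- numeric(m)
  selected <- logical(nf)
  for (t in seq_len(m)) {
    score <- if (t == 1L) relevance else relevance - redSum / (t - 1L)
    score[selected] <- -Inf
    # ties -> smallest index; scores within 1e-9 of the maximum count as
    # tied so that summation order in the MI estimate cannot flip a pick
    j <- which(score >= max(score) - 1e-9)[1L]
    ord[t] <- j; scores[t] <- score[j]
    selected[j] <- TRUE
    if (t < m)
      redSum <- redSum + miAllColumns(C, C[, j], B, B)
  }
  methods::new("MRMRRanking", order = ord, scores = scores,
               relevance = relevance)
}

#' @rdname accessors
#' @export
setMethod("rankedOrder", "MRMRRanking", function(x) x@order)

setMethod("show", "MRMRRanking", function(object) {
  cat(sprintf("MRMRRanking of %d features (top 5: %s)\n",
              length(object@order),
              paste(utils::head(object@order, 5), collapse = ", ")))
})

#' Iterative subset-size selection over an mRMR ranking
#'
#' For every candidate size q in \code{qGrid}, evaluates the stratified
#' K-fold cross-validated misclassification rate of a 1-nearest-neighbour
#' (Euclidean, z-normalized within training folds) classifier on the top-q
#' ranked features, and picks the size with minimal error (ties to the
#' smallest size).
#'
#' @param F an [ExemplarFeatures-class] or samples x features matrix.
#' @param y class labels.
#' @param ranking an [MRMRRanking-class] for \code{F}.
#' @param qGrid candidate subset sizes; defaults to 1-9 plus
#'   \code{seq(10, 1000, 10)}, capped at the ranking length. Very small
#'   sizes are included because on modest sample counts the error curve
#'   often attains its minimum below 10 features.
#' @param folds number of CV folds (default 10).
#' @param seed fold-assignment seed.
#' @return a [SelectionResult-class].
#' @export
iterativeSelect <- function(F, y, ranking, qGrid = NULL, folds = 10L,
                            seed = 1L) {
  X <- asSampleMatrix(F)
  y <- factor(y)
  m <- length(ranking@order)
  if (is.null(qGrid)) qGrid <- c(1:9, seq(10L, 1000L, by = 10L))
  qGrid <- sort(unique(as.integer(qGrid[qGrid <= m])))
  if (!length(qGrid)) stop("empty q grid (no candidate size <= ranking length)")
  fa <- stratifiedKFold(y, K = folds, seed = seed)
  err <- vapply(qGrid, function(q) {
    idx <- ranking@order[seq_len(q)]
    Xq <- X[, idx, drop = FALSE]
    wrong <- 0L
    for (f in seq_len(fa@K)) {
      te <- which(fa@fold == f); tr <- which(fa@fold != f)
      mu <- colMeans(Xq[tr, , drop = FALSE])
      sg <- apply(Xq[tr, , drop = FALSE], 2L, stats::sd)
      sg[sg == 0 | !is.finite(sg)] <- 1
      Ztr <- sweep(sweep(Xq[tr, , drop = FALSE], 2L, mu), 2L, sg, "/")
      Zte <- sweep(sweep(Xq[te, , drop = FALSE], 2L, mu), 2L, sg, "/")
      pred <- knnPredict(Ztr, y[tr], Zte, k = 1L)
      wrong <- wrong + sum(pred != as.character(y[te]))
    }
    wrong / length(y)
  }, numeric(1))
  best <- qGrid[which.min(err)]   # ties -> smallest q
  methods::new("SelectionResult", qGrid = qGrid, cvError = err,
               chosenQ = best,
               chosenIndices = ranking@order[seq_len(best)])
}

#' @rdname accessors
#' @export
setMethod("chosenFeatures", "SelectionResult", function(x) x@chosenIndices)

#' @rdname accessors
#' @export
setMethod("selectionCurve", "SelectionResult", function(x)
  data.frame(q = x@qGrid, cv_error = x@cvError))

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf(
    "SelectionResult: chose q = %d (CV error %.4f) from %d candidates\n",
    object@chosenQ, object@cvError[match(object@chosenQ, object@qGrid)],
    length(object@qGrid)))
})
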