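# Random-subspace KNN ensemble and cross-validated evaluation.
#
# Tie-breaking is fixed throughout for bit-reproducibility: equal distances
# favour the smaller training-sample index, KNN vote ties fall back to the
# class of the single nearest neighbour, and ensemble vote ties favour the
# class earliest in the model's fixed class order.

#' Stratified K-fold assignment
#'
#' Partitions samples into K folds so that per-class counts across folds
#' differ by at most one: within each class, samples are shuffled with the
#' seed and dealt round-robin starting at a seeded offset.
#'
#' @param y class labels.
#' @param K number of folds (default 10). Every class must have at least K
#'   samples.
#' @param seed shuffle seed.
#' @return a [FoldAssignment-class].
#' @export
stratifiedKFold <- function(y, K = 10L, seed = 1L) {
  y <- factor(y)
  K <- as.integer(K)
  tab <- table(y)
  if (any(tab < K))
    stop("class '", names(tab)[which(tab < K)[1L]], "' has ",
         min(tab), " samples, fewer than K = ", K, " folds")
  fold <- integer(length(y))
  withSeed(as.integer(seed), {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      start <- sample.int(K, 1L)
      fold[idx] <- ((seq_along(idx) - 1L + start - 1L) %% K) + 1L
    }
  })
  methods::new("FoldAssignment", fold = fold, K = K,
               seed = as.integer(seed))
}

#' @rdname accessors
#' @export
setMethod("foldIds", "FoldAssignment", function(x) x@fold)

setMethod("show", "FoldAssignment", function(object) {
  cat(sprintf("FoldAssignment: %d samples in %d folds (seed %d)\n",
              length(object@fold), object@K, object@seed))
})

#' K-nearest-neighbour prediction
#'
#' Plain KNN with Euclidean distance and deterministic tie rules: among
#' equal distances the smaller training index wins a neighbour slot, and a
#' tied majority vote resolves to the class of the single nearest
#' neighbour.
#'
#' @param trainX training matrix (samples x features).
#' @param trainY training labels.
#' @param query one query vector or a matrix of query rows.
#' @param k neighbours (default 1); must not exceed the training size.
#' @return character vector of predicted labels, one per query row.
#' @examples
#' X <- rbind(c(0, 0), c(10, 0), c(10, 1))
#' knnPredict(X, c("A", "B", "B"), c(9, 0), k = 3)  # "B"
#' @export
knnPredict <- function(trainX, trainY, query, k = 1L) {
  trainX <- as.matrix(trainX)
  if (nrow(trainX) == 0L) stop("empty training set")
  if (is.null(dim(query))) query <- matrix(query, nrow = 1L)
  query <- as.matrix(query)
  stopifnot(ncol(query) == ncol(trainX))
  k <- as.integer(k)
  if (k > nrow(trainX))
    stop("k = ", k, " exceeds training size ", nrow(trainX))
  trainY <- as.character(trainY)
  # squared Euclidean distances, queries x train
  d2 <- outer(rowSums(query^2), rowSums(trainX^2), "+") -
    2 * tcrossprod(query, trainX)
  apply(d2, 1L, function(dr) {
    ord <- order(dr)               # stable: distance ties -> smaller index
    nn <- trainY[ord[seq_len(k)]]
    counts <- table(nn)
    winners <- names(counts)[counts == max(counts)]
    if (length(winners) > 1L) trainY[ord[1L]] else winners
  })
}

#' Fit a random-subspace KNN ensemble
#'
#' Builds L nearest-neighbour learners, each bound to
#' \code{min(subspaceDim, n_features)} distinct feature indices drawn
#' uniformly without replacement from a learner-specific stream derived
#' from \code{seed} (identical seed, identical subsets). Features are
#' z-normalized with statistics computed from the training data; a
#' requested subspace larger than the feature count is clamped with a
#' warning.
#'
#' @param X training matrix (samples x features) or
#'   [ExemplarFeatures-class].
#' @param y training labels (at least 2 classes).
#' @param L number of learners (default 30).
#' @param subspaceDim features per learner (default 86).
#' @param k neighbours per learner (default 1).
#' @param seed ensemble seed.
#' @return a [SubspaceKNN-class].
#' @export
fitSubspaceKNN <- function(X, y, L = 30L, subspaceDim = 86L, k = 1L,
                           seed = 1L) {
  X <- asSampleMatrix(X)
  y <- factor(y)
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  L <- as.integer(L); subspaceDim <- as.integer(subspaceDim)
  k <- as.integer(k); seed <- as.integer(seed)
  nf <- ncol(X)
  dim0 <- subspaceDim
  if (subspaceDim > nf) {
    warning("subspaceDim = ", subspaceDim, " clamped to n_features = ", nf)
    dim0 <- nf
  }
  subsets <- lapply(seq_len(L), function(l)
    withSeed(deriveSeed(seed, "learner", l), sample.int(nf, dim0)))
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  methods::new("SubspaceKNN", subsets = subsets, L = L,
               subspaceDim = dim0, k = k, seed = seed, trainX = X,
               trainY = y, classes = levels(y), center = ctr, scale = scl)
}

setMethod("show", "SubspaceKNN", function(object) {
  cat(sprintf(
    "SubspaceKNN: %d learners x %d-dim subspaces, k = %d, %d samples, %s\n",
    object@L, object@subspaceDim, object@k, nrow(object@trainX),
    paste(object@classes, collapse = "/")))
})

#' Predict with a subspace KNN ensemble
#'
#' Each learner votes via [knnPredict()] restricted to its feature
#' subspace on z-normalized features; the majority label wins, with vote
#' ties resolved to the class earliest in the model's class order.
#'
#' @param model a [SubspaceKNN-class].
#' @param query query vector or matrix (full feature space).
#' @return character vector of predicted labels.
#' @export
ensemblePredict <- function(model, query) {
  if (is.null(dim(query))) query <- matrix(query, nrow = 1L)
  query <- as.matrix(query)
  stopifnot(ncol(query) == ncol(model@trainX))
  Ztr <- sweep(sweep(model@trainX, 2L, model@center), 2L, model@scale, "/")
  Zq <- sweep(sweep(query, 2L, model@center), 2L, model@scale, "/")
  votes <- vapply(model@subsets, function(idx)
    knnPredict(Ztr[, idx, drop = FALSE], model@trainY,
               Zq[, idx, drop = FALSE], k = model@k),
    character(nrow(query)))
  votes <- matrix(votes, nrow = nrow(query))
  apply(votes, 1L, function(vr) {
    counts <- table(factor(vr, levels = model@classes))
    model@classes[which.max(counts)]   # ties -> earliest class
  })
}

#' Cross-validate the subspace KNN ensemble
#'
#' For each fold, fits the ensemble on the complement (normalization
#' statistics and learner subspaces re-drawn from a fold-specific stream)
#' and predicts the held-out fold, accumulating one confusion matrix whose
#' total equals the sample count.
#'
#' @param X samples x features matrix or [ExemplarFeatures-class].
#' @param y class labels.
#' @param folds a [FoldAssignment-class] consistent with \code{y}.
#' @param L,subspaceDim,k ensemble parameters (defaults 30, 86, 1).
#' @param seed base seed for per-fold learner streams.
#' @return confusion matrix (rows = true class, cols = predicted).
#' @export
crossValidate <- function(X, y, folds, L = 30L, subspaceDim = 86L, k = 1L,
                          seed = 1L) {
  X <- asSampleMatrix(X)
  y <- factor(y)
  stopifnot(is(folds, "FoldAssignment"), length(folds@fold) == length(y))
  classes <- levels(y)
  cm <- matrix(0L, nlevels(y), nlevels(y),
               dimnames = list(true = classes, predicted = classes))
  for (f in seq_len(folds@K)) {
    te <- which(folds@fold == f)
    tr <- which(folds@fold != f)
    if (!length(te)) next
    model <- withCallingHandlers(
      fitSubspaceKNN(X[tr, , drop = FALSE], y[tr], L = L,
                     subspaceDim = subspaceDim, k = k,
                     seed = deriveSeed(seed, "fold", f)),
      warning = function(w) invokeRestart("muffleWarning"))
    pred <- ensemblePredict(model, X[te, , drop = FALSE])
    for (i in seq_along(te))
      cm[as.character(y[te[i]]), pred[i]] <-
        cm[as.character(y[te[i]]), pred[i]] + 1L
  }
  cm
}

#' F1 score from a precision/recall pair
#'
#' Harmonic mean \eqn{F_1 = 2PR/(P+R)}; accepts either proportions or
#' percentages (the result is on the same scale as the inputs). Zero
#' precision and recall give 0.
#'
#' @param precision,recall the pair.
#' @return the F1 score.
#' @examples
#' f1Score(99.60, 100)    # 99.80
#' f1Score(96.92, 99.80)  # 98.34
#' @export
f1Score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Per-class one-vs-rest metrics from a confusion matrix
#'
#' For each class treated as positive: accuracy \eqn{(TP+TN)/N}, precision
#' \eqn{TP/(TP+FP)}, recall \eqn{TP/(TP+FN)} and F1, as percentages
#' rounded to 2 decimals. A zero denominator yields 0 and sets the
#' \code{degenerate} flag for that class.
#'
#' @param cm square confusion matrix, rows = true class, cols = predicted.
#' @return data.frame with columns \code{class}, \code{accuracy},
#'   \code{f1}, \code{recall}, \code{precision}, \code{degenerate}.
#' @export
computeMetrics <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm), sum(cm) > 0)
  classes <- rownames(cm)
  if (is.null(classes)) classes <- paste0("class", seq_len(nrow(cm)))
  N <- sum(cm)
  out <- lapply(seq_len(nrow(cm)), function(i) {
    TP <- cm[i, i]
    FP <- sum(cm[-i, i])
    FN <- sum(cm[i, -i])
    TN <- N - TP - FP - FN
    degen <- (TP + FP) == 0 || (TP + FN) == 0
    P <- if (TP + FP == 0) 0 else TP / (TP + FP)
    R <- if (TP + FN == 0) 0 else TP / (TP + FN)
    data.frame(class = classes[i],
               accuracy = round(100 * (TP + TN) / N, 2),
               f1 = round(f1Score(100 * P, 100 * R), 2),
               recall = round(100 * R, 2),
               precision = round(100 * P, 2),
               degenerate = degen)
  })
  do.call(rbind, out)
}
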