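# Feature backbones: a uniform image -> fixed-length-vector contract.
#
# The mock backbone is a seeded Gaussian random projection of the
# z-normalized grayscale image: linear, deterministic, and cheap, so the
# whole pipeline can be exercised without pretrained weights. The
# fine-tuned backbone is a small CNN whose convolutional blocks are frozen
# at seeded random values and whose fully connected layers (feature layer +
# softmax head) are trained by backpropagation.

#' Create a deterministic mock backbone
#'
#' The mock backbone resizes any input to \code{inputSize} pixels per side,
#' takes the channel-mean grayscale, z-normalizes the flattened pixels
#' (zero-variance images map to the zero vector), and multiplies by a
#' \code{d x inputSize^2} standard-Gaussian projection matrix fixed at
#' construction from \code{seed}. Same seed, same image: identical features.
#'
#' @param seed integer; fixes the projection matrix.
#' @param d number of output features (default 1000).
#' @param inputSize internal side length (default 28; the projection matrix
#'   has \code{d * inputSize^2} entries, so the default keeps it small while
#'   leaving the contract identical for patches and whole images).
#' @return a [MockBackbone-class].
#' @examples
#' bb <- mockBackbone(seed = 1, d = 8)
#' length(extractFeatures(bb, array(runif(28 * 28 * 3), c(28, 28, 3))))
#' @export
mockBackbone <- function(seed, d = 1000L, inputSize = 28L) {
  d <- as.integer(d); inputSize <- as.integer(inputSize)
  stopifnot(d >= 1L, inputSize >= 8L)
  proj <- withSeed(as.integer(seed),
                  matrix(rnorm(d * inputSize^2), nrow = d))
  methods::new("MockBackbone", name = sprintf("mock-%d", as.integer(seed)),
               inputSize = inputSize, outputDim = d, kind = "mock",
               seed = as.integer(seed), projection = proj)
}

#' Pretrained CNN backbone (weights required)
#'
#' Placeholder constructor for a pretrained MobileNetV2-class backbone. This
#' package ships no network weights and no deep-learning runtime, so calling
#' it without a loadable weight source raises an informative error; use
#' [mockBackbone()] for deterministic testing or [fineTuneBackbone()] to
#' train the small built-in CNN on your data.
#'
#' @param weights path to a weight file (none supported in this build).
#' @export
pretrainedBackbone <- function(weights = NULL) {
  stop("no pretrained weights available",
       if (!is.null(weights)) paste0(" (cannot load '", weights, "')"),
       ": use mockBackbone() for deterministic features or ",
       "fineTuneBackbone() to train the built-in small CNN", call. = FALSE)
}

#' @rdname accessors
#' @export
setMethod("outputDim", "FeatureBackbone", function(x) x@outputDim)

#' @rdname accessors
#' @export
setMethod("inputSize", "FeatureBackbone", function(x) x@inputSize)

#' @rdname accessors
#' @export
setMethod("backboneKind", "FeatureBackbone", function(x) x@kind)

setMethod("show", "FeatureBackbone", function(object) {
  cat(sprintf("%s backbone '%s': input %dx%d -> %d features\n",
              object@kind, object@name, object@inputSize, object@inputSize,
              object@outputDim))
})

# normalize an extractFeatures input to a grayscale inputSize x inputSize
# matrix in [0,1]
prepInput <- function(img, size) {
  px <- if (is(img, "CanonicalImage")) img@pixels
        else if (is(img, "BrainSlice")) img@pixels
        else if (is(img, "Image")) fromEBImage(img)
        else img
  if (!is.numeric(px) || is.null(dim(px)))
    stop("img must be a CanonicalImage or a numeric pixel array")
  toGray(resizeArray(px, size, size))
}

#' @rdname extractFeatures
setMethod("extractFeatures", "MockBackbone", function(backbone, img) {
  g <- prepInput(img, backbone@inputSize)
  as.numeric(backbone@projection %*% zNorm(as.numeric(g)))
})

## ---- small-CNN fine-tuning -------------------------------------------

# Frozen random conv block: 3x3 'same' convolution by shifted sums, ReLU,
# 2x2 mean pooling. x: [h, w, cin]; filt: [3, 3, cin, cout].
convBlock <- function(x, filt) {
  h <- dim(x)[1L]; w <- dim(x)[2L]; cin <- dim(x)[3L]
  cout <- dim(filt)[4L]
  out <- array(0, c(h, w, cout))
  padded <- array(0, c(h + 2L, w + 2L, cin))
  padded[2:(h + 1L), 2:(w + 1L), ] <- x
  for (o in seq_len(cout)) {
    acc <- matrix(0, h, w)
    for (i in seq_len(cin)) for (dy in 0:2) for (dx in 0:2) {
      acc <- acc + filt[dy + 1L, dx + 1L, i, o] *
        padded[(1L + dy):(h + dy), (1L + dx):(w + dx), i]
    }
    out[, , o] <- acc
  }
  out[out < 0] <- 0
  # 2x2 mean pool
  h2 <- h %/% 2L; w2 <- w %/% 2L
  pooled <- array(0, c(h2, w2, cout))
  for (o in seq_len(cout)) {
    m <- out[seq_len(2L * h2), seq_len(2L * w2), o]
    pooled[, , o] <- (m[seq(1, 2 * h2, 2), seq(1, 2 * w2, 2)] +
                      m[seq(2, 2 * h2, 2), seq(1, 2 * w2, 2)] +
                      m[seq(1, 2 * h2, 2), seq(2, 2 * w2, 2)] +
                      m[seq(2, 2 * h2, 2), seq(2, 2 * w2, 2)]) / 4
  }
  pooled
}

# adaptive average pooling of [h, w, c] to an out x out grid per channel
adaptivePool <- function(x, out = 4L) {
  h <- dim(x)[1L]; w <- dim(x)[2L]; ch <- dim(x)[3L]
  rb <- floor(seq(0L, h, length.out = out + 1L))
  cb <- floor(seq(0L, w, length.out = out + 1L))
  res <- array(0, c(out, out, ch))
  for (i in seq_len(out)) for (j in seq_len(out))
    res[i, j, ] <- apply(x[(rb[i] + 1L):rb[i + 1L],
                           (cb[j] + 1L):cb[j + 1L], , drop = FALSE],
                         3L, mean)
  res
}

# forward pass through the frozen conv trunk; coarse 4x4 average pooling
# keeps the representation translation-tolerant (lesions occur anywhere in
# the brain) and small enough that the trained head cannot simply memorize
convTrunk <- function(g, conv1, conv2) {
  x <- array(g, c(dim(g), 1L))
  x <- convBlock(x, conv1)
  x <- convBlock(x, conv2)
  as.numeric(adaptivePool(x, 4L))
}

#' Fine-tune the built-in small CNN backbone
#'
#' Trains a compact stand-in for end-to-end CNN fine-tuning: two seeded
#' random 3 x 3 convolution + ReLU + mean-pool blocks (kept frozen) feed a
#' trainable fully connected feature layer of width \code{d} and a softmax
#' classifier head, optimized with Adam on cross-entropy. The data are
#' split stratified 70:30 into training and validation by
#' \code{trainFraction}, and per-epoch training/validation accuracy is
#' recorded in the returned backbone's \code{history}. Feature extraction
#' from the result uses the linear output of the feature layer, so the
#' [extractFeatures()] contract is unchanged.
#'
#' @param images list of [CanonicalImage-class] (or pixel arrays).
#' @param labels class labels, one per image; at least 2 classes with at
#'   least 4 images each.
#' @param d feature-layer width (default 1000).
#' @param trainFraction fraction used for training (default 0.70).
#' @param epochs training epochs (default 30).
#' @param learningRate Adam step size (default 1e-3).
#' @param seed seed for weight init, shuffling and the split.
#' @param workSize internal image side length the CNN operates at
#'   (default 56; inputs are resized).
#' @param verbose log per-epoch accuracy to stderr.
#' @return a [FineTunedBackbone-class].
#' @export
fineTuneBackbone <- function(images, labels, d = 1000L, trainFraction = 0.70,
                             epochs = 30L, learningRate = 1e-3, seed = 1L,
                             workSize = 56L, verbose = FALSE) {
  stopifnot(length(images) == length(labels),
            trainFraction > 0, trainFraction < 1)
  y <- factor(labels)
  if (nlevels(y) < 2L) stop("fine-tuning needs at least 2 classes")
  if (any(table(y) < 4L)) stop("each class needs at least 4 images")
  d <- as.integer(d); workSize <- as.integer(workSize)
  seed <- as.integer(seed)

  n1 <- 8L; n2 <- 16L   # conv channel counts
  convFeat <- 4L * 4L * n2

  st <- withSeed(deriveSeed(seed, "weights"), {
    list(conv1 = array(rnorm(3 * 3 * 1 * n1, sd = sqrt(2 / 9)),
                       c(3L, 3L, 1L, n1)),
         conv2 = array(rnorm(3 * 3 * n1 * n2, sd = sqrt(2 / (9 * n1))),
                       c(3L, 3L, n1, n2)),
         W1 = matrix(rnorm(d * convFeat, sd = sqrt(2 / convFeat)), d),
         b1 = rep(0, d),
         W2 = matrix(rnorm(nlevels(y) * d, sd = sqrt(2 / d)), nlevels(y)),
         b2 = rep(0, nlevels(y)))
  })

  # frozen conv features for every image, rows = samples
  X <- t(vapply(images, function(im)
    convTrunk(prepInput(im, workSize), st$conv1, st$conv2),
    numeric(convFeat)))
  mu <- colMeans(X); sg <- apply(X, 2L, sd); sg[sg == 0] <- 1
  X <- sweep(sweep(X, 2L, mu), 2L, sg, "/")

  # stratified 70:30 split
  split <- withSeed(deriveSeed(seed, "split"), {
    tr <- unlist(lapply(levels(y), function(cl) {
      idx <- which(y == cl)
      sample(idx, max(1L, round(trainFraction * length(idx))))
    }))
    sort(tr)
  })
  va <- setdiff(seq_along(y), split)
  yi <- as.integer(y)
  C <- nlevels(y); nTr <- length(split)

  softmaxAcc <- function(idx, W1, b1, W2, b2) {
    f <- X[idx, , drop = FALSE] %*% t(W1)
    f <- sweep(f, 2L, b1, "+")
    h <- pmax(f, 0)
    z <- sweep(h %*% t(W2), 2L, b2, "+")
    mean(max.col(z, ties.method = "first") == yi[idx])
  }

  W1 <- st$W1; b1 <- st$b1; W2 <- st$W2; b2 <- st$b2
  m <- lapply(list(W1, b1, W2, b2), function(p) p * 0)
  v <- m
  hist <- data.frame(epoch = integer(), train_acc = numeric(),
                     val_acc = numeric())
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t0 <- 0L
  Xtr <- X[split, , drop = FALSE]
  Ytr <- matrix(0, nTr, C); Ytr[cbind(seq_len(nTr), yi[split])] <- 1

  for (ep in seq_len(epochs)) {
    f <- sweep(Xtr %*% t(W1), 2L, b1, "+")
    h <- pmax(f, 0)
    z <- sweep(h %*% t(W2), 2L, b2, "+")
    z <- z - apply(z, 1L, max)
    p <- exp(z); p <- p / rowSums(p)
    dz <- (p - Ytr) / nTr
    gW2 <- t(dz) %*% h; gb2 <- colSums(dz)
    dh <- dz %*% W2; dh[f <= 0] <- 0
    gW1 <- t(dh) %*% Xtr; gb1 <- colSums(dh)
    grads <- list(gW1, gb1, gW2, gb2)
    pars <- list(W1, b1, W2, b2)
    t0 <- t0 + 1L
    for (j in 1:4) {
      m[[j]] <- beta1 * m[[j]] + (1 - beta1) * grads[[j]]
      v[[j]] <- beta2 * v[[j]] + (1 - beta2) * grads[[j]]^2
      mh <- m[[j]] / (1 - beta1^t0)
      vh <- v[[j]] / (1 - beta2^t0)
      pars[[j]] <- pars[[j]] - learningRate * mh / (sqrt(vh) + eps)
    }
    W1 <- pars[[1]]; b1 <- pars[[2]]; W2 <- pars[[3]]; b2 <- pars[[4]]
    trAcc <- softmaxAcc(split, W1, b1, W2, b2)
    vaAcc <- if (length(va)) softmaxAcc(va, W1, b1, W2, b2) else NA_real_
    hist <- rbind(hist, data.frame(epoch = ep, train_acc = trAcc,
                                   val_acc = vaAcc))
    if (verbose)
      message(sprintf("epoch %d: train %.3f  val %.3f", ep, trAcc, vaAcc))
  }

  # fold the conv-feature standardization into the feature layer so that
  # extractFeatures needs only the raw conv trunk output
  W1s <- sweep(W1, 2L, sg, "/")
  b1s <- b1 - as.numeric(W1s %*% mu)
  methods::new("FineTunedBackbone",
               name = sprintf("small-cnn-%d", seed),
               inputSize = workSize, outputDim = d, kind = "finetuned",
               seed = seed, conv1 = st$conv1, conv2 = st$conv2,
               W1 = W1s, b1 = b1s, W2 = W2, b2 = b2,
               classes = levels(y), history = hist)
}

#' @rdname extractFeatures
setMethod("extractFeatures", "FineTunedBackbone", function(backbone, img) {
  g <- prepInput(img, backbone@inputSize)
  cf <- convTrunk(g, backbone@conv1, backbone@conv2)
  as.numeric(backbone@W1 %*% cf + backbone@b1)
})

#' Training history of a fine-tuned backbone
#' @param x a [FineTunedBackbone-class].
#' @return data.frame with per-epoch \code{train_acc} and \code{val_acc}.
#' @export
trainingHistory <- function(x) {
  stopifnot(is(x, "FineTunedBackbone"))
  x@history
}
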