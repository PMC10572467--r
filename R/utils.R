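# Internal helpers: seed streams, EBImage conversions, resizing.

# Derive a reproducible 31-bit sub-seed from a base seed plus arbitrary
# integer/character tags. Multiplicative hashing keeps streams for different
# stages (folds, learners, per-image noise) decoupled.
deriveSeed <- function(seed, ...) {
  h <- as.double(seed %% 2147483647L)
  for (tag in list(...)) {
    codes <- if (is.character(tag)) utf8ToInt(paste(tag, collapse = "|"))
             else as.integer(tag)
    for (v in codes) h <- (h * 48271 + as.double(v) + 1) %% 2147483647
  }
  as.integer(h)
}

# Standard R array [h, w(, ch)] -> EBImage Image (x = width, y = height).
asEBImage <- function(px) {
  d <- dim(px)
  if (length(d) == 2L) {
    EBImage::Image(t(px))
  } else {
    EBImage::Image(aperm(px, c(2L, 1L, 3L)), colormode = "Color")
  }
}

# EBImage Image -> standard array [h, w(, ch)]. Frames beyond 3 dropped
# (e.g. PNG alpha).
fromEBImage <- function(img) {
  px <- EBImage::imageData(img)
  d <- dim(px)
  if (length(d) == 2L) return(t(px))
  if (d[3L] > 3L) px <- px[, , seq_len(3L), drop = FALSE]
  if (d[3L] == 2L) px <- px[, , 1L, drop = FALSE]  # gray+alpha
  aperm(px, c(2L, 1L, 3L))
}

# Anti-aliased bilinear resize of a [h, w(, ch)] array to h2 x w2.
resizeArray <- function(px, h2, w2) {
  if (!is.null(dim(px)) && dim(px)[1L] == h2 && dim(px)[2L] == w2) return(px)
  out <- EBImage::resize(asEBImage(px), w = w2, h = h2,
                         filter = "bilinear", antialias = TRUE)
  fromEBImage(out)
}

# Channel-mean grayscale of a [h, w(, ch)] array.
toGray <- function(px) {
  d <- dim(px)
  if (length(d) == 2L) px else apply(px, c(1L, 2L), mean)
}

# z-normalize a vector; zero-variance input maps to zeros (stated
# degenerate rule for the mock backbone).
zNorm <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Run code under a local RNG state so package internals never disturb the
# caller's .Random.seed stream.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
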