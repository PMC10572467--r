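# Shared fixtures, built in code at test time.

# A filled bright disk on black: known foreground mask for crop tests.
diskImage <- function(size = 100L, cy = 50, cx = 50, r = 20,
                      fg = 0.9, bg = 0) {
  yy <- matrix(seq_len(size), size, size)
  xx <- t(yy)
  mask <- (yy - cy)^2 + (xx - cx)^2 <= r^2
  px <- matrix(bg, size, size)
  px[mask] <- fg
  list(slice = new("BrainSlice", pixels = px), mask = mask)
}

# Tiny canonical image with deterministic content (no segmentation).
tinyCanonical <- function(size = 56L, seed = 1L) {
  size <- as.integer(size)
  set.seed(seed)
  px <- array(runif(size * size * 3), c(size, size, 3L))
  new("CanonicalImage", pixels = px,
      crop = new("CropBox", top = 0L, left = 0L,
                 bottom = size, right = size),
      label = "healthy", view = "axial")
}

# Brute-force plug-in MI oracle: direct joint-table computation, base 2.
# Kept independent of the package's estimator on purpose.
miOracle <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  mi <- 0
  pa <- unname(rowSums(tab) / n)
  pb <- unname(colSums(tab) / n)
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    pij <- tab[i, j] / n
    if (pij > 0) mi <- mi + pij * log2(pij / (pa[i] * pb[j]))
  }
  mi
}

# Exhaustive greedy mRMR oracle: re-evaluates the MID criterion from
# scratch at every step using miOracle on package discretization codes.
mrmrOracle <- function(X, y, m, B = 10L) {
  codes <- lapply(seq_len(ncol(X)),
                  function(j) discretizeFeature(X[, j], B)$codes)
  ycodes <- as.integer(factor(y)) - 1L
  rel <- vapply(codes, miOracle, numeric(1), b = ycodes)
  sel <- integer(0)
  for (t in seq_len(m)) {
    cand <- setdiff(seq_len(ncol(X)), sel)
    sc <- vapply(cand, function(j) {
      red <- if (length(sel)) {
        mean(vapply(sel, function(s) miOracle(codes[[j]], codes[[s]]),
                    numeric(1)))
      } else 0
      rel[j] - red
    }, numeric(1))
    # same near-tie rule as the package: smallest index within 1e-9 of max
    sel <- c(sel, cand[which(sc >= max(sc) - 1e-9)[1]])
  }
  sel
}

# Easy synthetic image dataset written to a session-scoped temp dir, reused
# across test files to keep the suite fast.
easyImageSet <- local({
  cache <- NULL
  function(nPerClass = 12L, seed = 101L) {
    if (!is.null(cache)) return(cache)
    td <- file.path(tempdir(), sprintf("easyimg_%d_%d", nPerClass, seed))
    cfg <- synthImageConfig(nPerClass = nPerClass, seed = seed)
    man <- generateDataset(cfg, td)
    cache <<- list(cfg = cfg, manifest = man, dir = td)
    cache
  }
})
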