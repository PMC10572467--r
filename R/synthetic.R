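# Synthetic MRI-like fixtures: elliptical "brain" on a dark background,
# with hyperintense Gaussian lesion blobs for the MS class, plus a tabular
# generator with known informative features. Everything is deterministic
# given (seed, class, index), with geometry, lesions and noise drawn from
# separate derived streams so that a zero-effect configuration produces
# bit-identical images across classes.

#' Configuration for the synthetic brain-slice generator
#'
#' Defaults describe an easily separable two-class problem: a bright
#' elliptical brain (intensity about 0.5) on a near-black background, the
#' MS class carrying 3-6 hyperintense lesion blobs at +0.5 intensity, and
#' mild additive Gaussian noise (sd 0.02) on the [0,1] scale.
#'
#' @param imageSize square side length in pixels before cropping
#'   (default 256).
#' @param nPerClass images per class (default 30).
#' @param lesionCountRange integer range of lesions per MS image
#'   (default \code{c(3, 6)}).
#' @param lesionIntensityDelta added lesion intensity on [0,1]
#'   (default 0.5); 0 disables lesion drawing entirely.
#' @param noiseSd additive Gaussian noise sd (default 0.02).
#' @param view \code{"axial"} (rounder ellipse) or \code{"sagittal"}
#'   (more elongated).
#' @param seed base seed.
#' @return a validated config list of class \code{"SynthImageConfig"}.
#' @export
synthImageConfig <- function(imageSize = 256L, nPerClass = 30L,
                             lesionCountRange = c(3L, 6L),
                             lesionIntensityDelta = 0.5, noiseSd = 0.02,
                             view = c("axial", "sagittal"), seed = 1L) {
  view <- match.arg(view)
  stopifnot(imageSize >= 32L, nPerClass >= 1L,
            lesionIntensityDelta >= 0, noiseSd >= 0,
            length(lesionCountRange) == 2L,
            lesionCountRange[1L] >= 1L,
            lesionCountRange[2L] >= lesionCountRange[1L])
  structure(list(imageSize = as.integer(imageSize),
                 nPerClass = as.integer(nPerClass),
                 lesionCountRange = as.integer(lesionCountRange),
                 lesionIntensityDelta = lesionIntensityDelta,
                 noiseSd = noiseSd, view = view, seed = as.integer(seed)),
            class = "SynthImageConfig")
}

#' Generate one synthetic brain slice
#'
#' Draws a filled bright ellipse (the "brain") off-centre on a dark
#' background; for \code{classLabel = "MS"} with a positive intensity
#' delta, adds \code{lesionCountRange} hyperintense Gaussian blobs inside
#' the ellipse; then adds Gaussian noise and clips to [0,1]. Geometry and
#' noise streams depend only on (seed, index), the lesion stream on
#' (seed, index, lesions), so healthy and MS images share anatomy.
#'
#' @param cfg a [synthImageConfig()] configuration.
#' @param classLabel class name; lesions are drawn only for \code{"MS"}.
#' @param index image index within the class (part of the random stream).
#' @param masks if \code{TRUE}, return a list with the image plus logical
#'   \code{brainMask} and \code{lesionMask} ground-truth masks.
#' @return a [BrainSlice-class], or a list if \code{masks = TRUE}.
#' @export
generateBrainImage <- function(cfg, classLabel, index = 1L, masks = FALSE) {
  stopifnot(inherits(cfg, "SynthImageConfig"))
  sz <- cfg$imageSize
  geom <- withSeed(deriveSeed(cfg$seed, "geom", index), {
    list(cy = sz * runif(1, 0.45, 0.55), cx = sz * runif(1, 0.45, 0.55),
         ry = sz * runif(1, 0.30, 0.36) *
           if (cfg$view == "sagittal") 1.05 else 1,
         rx = sz * runif(1, 0.22, 0.28) *
           if (cfg$view == "sagittal") 1.25 else 1,
         theta = runif(1, -0.2, 0.2))
  })
  yy <- matrix(seq_len(sz), sz, sz)
  xx <- t(yy)
  dy <- yy - geom$cy; dx <- xx - geom$cx
  u <- cos(geom$theta) * dy + sin(geom$theta) * dx
  v <- -sin(geom$theta) * dy + cos(geom$theta) * dx
  brainMask <- (u / geom$ry)^2 + (v / geom$rx)^2 <= 1
  img <- matrix(0.03, sz, sz)
  # slight radial shading so the brain is not flat
  shade <- 0.5 * (1 - 0.15 * ((u / geom$ry)^2 + (v / geom$rx)^2))
  img[brainMask] <- shade[brainMask]
  lesionMask <- matrix(FALSE, sz, sz)
  if (identical(classLabel, "MS") && cfg$lesionIntensityDelta > 0) {
    les <- withSeed(deriveSeed(cfg$seed, "lesions", index), {
      nles <- sample(seq(cfg$lesionCountRange[1L],
                         cfg$lesionCountRange[2L]), 1L)
      lapply(seq_len(nles), function(i) {
        # polar placement well inside the ellipse
        rho <- sqrt(runif(1)) * 0.7
        ang <- runif(1, 0, 2 * pi)
        list(cy = geom$cy + rho * geom$ry * cos(ang) * cos(geom$theta) -
               rho * geom$rx * sin(ang) * sin(geom$theta),
             cx = geom$cx + rho * geom$ry * cos(ang) * sin(geom$theta) +
               rho * geom$rx * sin(ang) * cos(geom$theta),
             sd = runif(1, sz / 60, sz / 30))
      })
    })
    for (b in les) {
      r2 <- (yy - b$cy)^2 + (xx - b$cx)^2
      blob <- exp(-r2 / (2 * b$sd^2))
      img <- img + cfg$lesionIntensityDelta * blob
      lesionMask <- lesionMask | (blob > 0.5 & brainMask)
    }
  }
  if (cfg$noiseSd > 0) {
    noise <- withSeed(deriveSeed(cfg$seed, "noise", index),
                      matrix(rnorm(sz * sz, sd = cfg$noiseSd), sz, sz))
    img <- img + noise
  }
  img[img < 0] <- 0; img[img > 1] <- 1
  slice <- methods::new("BrainSlice", pixels = img,
                        label = as.character(classLabel), view = cfg$view)
  if (masks) list(image = slice, brainMask = brainMask,
                  lesionMask = lesionMask)
  else slice
}

#' Generate a synthetic two-class image dataset on disk
#'
#' Writes \code{nPerClass} 8-bit grayscale PNGs per class under
#' \code{<outDir>/<class>/} and a \code{manifest.csv} with columns
#' \code{path,label,view}, loadable by [readManifest()].
#'
#' @param cfg a [synthImageConfig()] configuration.
#' @param outDir output directory (created if needed).
#' @param classes class names (default \code{c("healthy", "MS")}).
#' @return the manifest data.frame (invisibly written to
#'   \code{<outDir>/manifest.csv}).
#' @export
generateDataset <- function(cfg, outDir,
                            classes = c("healthy", "MS")) {
  stopifnot(inherits(cfg, "SynthImageConfig"))
  ok <- dir.exists(outDir) || dir.create(outDir, recursive = TRUE)
  if (!ok || file.access(outDir, 2L) != 0L)
    stop("cannot write to output directory: ", outDir)
  rows <- list()
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    dir.create(file.path(outDir, cl), showWarnings = FALSE)
    for (i in seq_len(cfg$nPerClass)) {
      # disjoint index ranges per class: every image gets its own anatomy
      # (no cross-class "twin" brains, as with distinct patients)
      slice <- generateBrainImage(cfg, cl,
                                  (ci - 1L) * cfg$nPerClass + i)
      f <- file.path(outDir, cl, sprintf("%s_%03d.png", cl, i))
      EBImage::writeImage(asEBImage(slice@pixels), f, bits = 8L)
      rows[[length(rows) + 1L]] <-
        data.frame(path = f, label = cl, view = cfg$view)
    }
  }
  man <- do.call(rbind, rows)
  utils::write.csv(man, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  man
}

#' Configuration for the synthetic tabular generator
#'
#' @param nSamples total samples, split evenly over two classes
#'   (default 60).
#' @param nInformative features whose class means differ (default 3).
#' @param nNoise class-independent standard-normal features (default 47).
#' @param classSeparation distance between class means in units of the
#'   within-class sd (default 4).
#' @param seed base seed.
#' @return config list of class \code{"SynthTabularConfig"}.
#' @export
synthTabularConfig <- function(nSamples = 60L, nInformative = 3L,
                               nNoise = 47L, classSeparation = 4,
                               seed = 1L) {
  stopifnot(nSamples >= 4L, nInformative >= 1L, nNoise >= 0L,
            classSeparation >= 0)
  structure(list(nSamples = as.integer(nSamples),
                 nInformative = as.integer(nInformative),
                 nNoise = as.integer(nNoise),
                 classSeparation = classSeparation,
                 seed = as.integer(seed)),
            class = "SynthTabularConfig")
}

#' Generate a labelled tabular feature set with known informative features
#'
#' Informative features are standard normal with class means separated by
#' \code{classSeparation} within-class standard deviations; noise features
#' are standard normal regardless of class. Informative columns are placed
#' at seeded random positions and their indices returned as ground truth.
#'
#' @param cfg a [synthTabularConfig()] configuration.
#' @return list with \code{X} (samples x features matrix), \code{y}
#'   (factor \code{A}/\code{B}) and \code{informative} (integer column
#'   indices).
#' @export
generateTabular <- function(cfg) {
  stopifnot(inherits(cfg, "SynthTabularConfig"))
  n <- cfg$nSamples
  p <- cfg$nInformative + cfg$nNoise
  n1 <- n %/% 2L
  y <- factor(rep(c("A", "B"), c(n1, n - n1)))
  withSeed(cfg$seed, {
    X <- matrix(rnorm(n * p), n, p)
    inf <- sort(sample.int(p, cfg$nInformative))
    shift <- cfg$classSeparation
    X[y == "B", inf] <- X[y == "B", inf] + shift
    colnames(X) <- paste0("f", seq_len(p))
    list(X = X, y = y, informative = inf)
  })
}
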