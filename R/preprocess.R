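#' Load a 2-D slice image from disk
#'
#' Reads a PNG, JPEG or TIFF file into a [BrainSlice-class]. Integer pixel
#' data are scaled by the dtype maximum at decode time (EBImage convention),
#' so intensities arrive as floats; grayscale files stay single-channel at
#' this stage. RGB(A) files keep their first three channels.
#'
#' @param path file to read.
#' @param label optional class label to attach.
#' @param view anatomical view, one of \code{"axial"}, \code{"sagittal"},
#'   \code{"unknown"}.
#' @return a [BrainSlice-class].
#' @examples
#' td <- tempfile()
#' man <- generateDataset(synthImageConfig(nPerClass = 1, seed = 7), td)
#' sl <- loadImage(man$path[1], label = man$label[1], view = man$view[1])
#' dim(slicePixels(sl))
#' @export
loadImage <- function(path, label = NA_character_, view = "unknown") {
  if (!file.exists(path))
    stop("cannot read image: file does not exist: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e)
                    stop("undecodable image file '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  px <- fromEBImage(img)
  d <- dim(px)
  if (prod(d[1:2]) == 0L)
    stop("zero-size image: ", path)
  methods::new("BrainSlice", pixels = px, sourcePath = path,
               label = as.character(label), view = view)
}

#' Pixel array of a slice
#' @param x a [BrainSlice-class].
#' @return the \code{h x w (x ch)} numeric array.
#' @export
slicePixels <- function(x) x@pixels

#' Isolate the brain area of a slice
#'
#' Finds the brain region as the bounding box of the largest foreground
#' connected component: Otsu threshold on the channel-mean grayscale image,
#' binary closing with a 3 x 3 box, 8-connected labelling, then the bounding
#' box of the largest component. A slice with no foreground (uniform image)
#' falls back to the full frame with a warning rather than an error.
#'
#' @param img a [BrainSlice-class].
#' @return list with elements \code{image} (the cropped [BrainSlice-class])
#'   and \code{crop} (the [CropBox-class], 0-based half-open).
#' @export
segmentBrainArea <- function(img) {
  stopifnot(is(img, "BrainSlice"))
  px <- img@pixels
  g <- toGray(px)
  h <- nrow(g); w <- ncol(g)
  fullBox <- methods::new("CropBox", top = 0L, left = 0L,
                          bottom = h, right = w)
  rng <- range(g)
  if (rng[1] == rng[2]) {
    warning("uniform image, no foreground: using full-frame crop")
    return(list(image = img, crop = fullBox))
  }
  eb <- asEBImage(g)
  th <- EBImage::otsu(eb, range = rng)
  bw <- EBImage::closing(eb > th, EBImage::makeBrush(3L, shape = "box"))
  lab <- EBImage::bwlabel(bw)
  labArr <- t(EBImage::imageData(lab))
  n <- max(labArr)
  if (n == 0L) {
    warning("no foreground component found: using full-frame crop")
    return(list(image = img, crop = fullBox))
  }
  sizes <- tabulate(labArr[labArr > 0L], nbins = n)
  keep <- which.max(sizes)
  idx <- which(labArr == keep, arr.ind = TRUE)
  box <- methods::new("CropBox",
                      top = min(idx[, 1L]) - 1L, left = min(idx[, 2L]) - 1L,
                      bottom = max(idx[, 1L]), right = max(idx[, 2L]))
  cropped <- if (length(dim(px)) == 2L)
    px[(box@top + 1L):box@bottom, (box@left + 1L):box@right, drop = FALSE]
  else
    px[(box@top + 1L):box@bottom, (box@left + 1L):box@right, , drop = FALSE]
  out <- methods::new("BrainSlice", pixels = cropped,
                      sourcePath = img@sourcePath, label = img@label,
                      view = img@view)
  list(image = out, crop = box)
}

#' Canonicalize a slice to the pipeline's working format
#'
#' Crops to the brain area (unless \code{segment = FALSE}), resizes
#' anisotropically to \code{size x size} with anti-aliased bilinear
#' interpolation, replicates grayscale data across 3 channels, and rescales
#' intensities to [0,1]. Loaded integer images are already on [0,1] (scaled
#' by dtype maximum at decode); in-memory float arrays outside [0,1] are
#' min-max scaled per image.
#'
#' @param img a [BrainSlice-class].
#' @param size output side length in pixels (default 224).
#' @param segment apply [segmentBrainArea()] first (default \code{TRUE}).
#' @return a [CanonicalImage-class].
#' @export
canonicalizeImage <- function(img, size = 224L, segment = TRUE) {
  stopifnot(is(img, "BrainSlice"))
  size <- as.integer(size)
  if (segment) {
    seg <- segmentBrainArea(img)
    px <- seg$image@pixels
    box <- seg$crop
  } else {
    px <- img@pixels
    box <- methods::new("CropBox", top = 0L, left = 0L,
                        bottom = nrow(px), right = dim(px)[2L])
  }
  rng <- range(px)
  if (rng[1] < 0 || rng[2] > 1) {
    if (rng[2] > 1 && rng[1] >= 0 && max(abs(px - round(px))) < 1e-9) {
      # integer-coded array passed in memory: scale by bit-depth maximum
      denom <- if (rng[2] <= 255) 255 else 65535
      px <- px / denom
    } else {
      px <- (px - rng[1]) / (rng[2] - rng[1])
    }
  }
  px <- resizeArray(px, size, size)
  if (length(dim(px)) == 2L) px <- array(px, c(size, size, 3L))
  else if (dim(px)[3L] == 1L) px <- array(px[, , 1L], c(size, size, 3L))
  px[px < 0] <- 0; px[px > 1] <- 1  # clamp interpolation overshoot
  methods::new("CanonicalImage", pixels = px, crop = box,
               label = img@label, view = img@view)
}

#' Pixel array of a canonical image
#' @param x a [CanonicalImage-class].
#' @return the \code{size x size x 3} array.
#' @export
canonicalPixels <- function(x) x@pixels

#' @rdname accessors
#' @export
setMethod("cropBox", "CanonicalImage", function(x) x@crop)

#' Read a label manifest or class-per-directory layout
#'
#' A manifest is a CSV with header \code{path,label,view}; relative paths
#' are resolved against the manifest's directory. Alternatively a root
#' directory with one subdirectory per class
#' (\code{<root>/<label>/*.png}) is scanned.
#'
#' @param path manifest CSV file or dataset root directory.
#' @return data.frame with columns \code{path}, \code{label}, \code{view}.
#' @export
readManifest <- function(path) {
  if (dir.exists(path)) {
    classes <- list.dirs(path, recursive = FALSE)
    if (!length(classes)) stop("no class subdirectories under ", path)
    rows <- lapply(classes, function(d) {
      fs <- list.files(d, pattern = "\\.(png|jpe?g|tiff?)$",
                       ignore.case = TRUE, full.names = TRUE)
      if (!length(fs)) return(NULL)
      data.frame(path = fs, label = basename(d), view = "unknown")
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) stop("no images found under ", path)
    return(out)
  }
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "label", "view")
  if (!all(need %in% names(man)))
    stop("manifest must have columns path,label,view")
  rel <- !file.exists(man$path)
  man$path[rel] <- file.path(dirname(path), man$path[rel])
  man[, need]
}

#' Load and canonicalize every image in a manifest
#'
#' @param manifest data.frame from [readManifest()] (or a path passed to it).
#' @param size canonical side length.
#' @param segment apply the brain-area crop.
#' @return list of [CanonicalImage-class].
#' @export
loadDataset <- function(manifest, size = 224L, segment = TRUE) {
  if (is.character(manifest)) manifest <- readManifest(manifest)
  lapply(seq_len(nrow(manifest)), function(i)
    canonicalizeImage(
      loadImage(manifest$path[i], label = manifest$label[i],
                view = manifest$view[i]),
      size = size, segment = segment))
}

setMethod("show", "CropBox", function(object) {
  cat(sprintf("CropBox [%d,%d) x [%d,%d)\n",
              object@top, object@bottom, object@left, object@right))
})

setMethod("show", "BrainSlice", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("BrainSlice %dx%d, %d channel(s), label=%s, view=%s\n",
              d[1L], d[2L], if (length(d) == 3L) d[3L] else 1L,
              object@label, object@view))
})

setMethod("show", "CanonicalImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("CanonicalImage %dx%dx%d, label=%s, view=%s, crop ", d[1L],
              d[2L], d[3L], object@label, object@view))
  show(object@crop)
})
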