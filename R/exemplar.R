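# Exemplar decomposition: tile a canonical image into non-overlapping
# p x p patches and concatenate backbone features of the whole image and of
# every patch into one merged vector. With the defaults (224 canvas, p = 28,
# d = 1000) that is 1 + 64 blocks of 1000 features = 65,000 entries.

#' Tile a canonical image into non-overlapping patches
#'
#' Splits the image into an \code{r x c} grid of \code{p x p x 3} blocks in
#' row-major order (left-to-right, top-to-bottom); the blocks exactly
#' partition the image. Patch coordinates are 0-based grid positions.
#'
#' @param img a [CanonicalImage-class] or an \code{h x w x 3} array.
#' @param p patch side length in pixels (default 28). Both image dimensions
#'   must be divisible by \code{p}.
#' @return list with \code{patchSize}, \code{rows}, \code{cols},
#'   \code{coords} (n x 2 matrix of 0-based row/col grid positions) and
#'   \code{patches} (\code{p x p x 3 x n} array, row-major order).
#' @examples
#' cv <- canonicalizeImage(generateBrainImage(
#'   synthImageConfig(seed = 3), "healthy", 1))
#' g <- patchify(cv)
#' g$rows * g$cols   # 64 patches for a 224x224 image
#' @export
patchify <- function(img, p = 28L) {
  px <- if (is(img, "CanonicalImage")) img@pixels else img
  p <- as.integer(p)
  d <- dim(px)
  stopifnot(length(d) == 3L, d[3L] == 3L)
  if (d[1L] %% p != 0L || d[2L] %% p != 0L)
    stop(sprintf("image size %dx%d is not divisible by patch size %d",
                 d[1L], d[2L], p))
  r <- d[1L] %/% p; cc <- d[2L] %/% p
  n <- r * cc
  coords <- cbind(row = rep(seq_len(r) - 1L, each = cc),
                  col = rep(seq_len(cc) - 1L, times = r))
  patches <- array(0, c(p, p, 3L, n))
  for (i in seq_len(n)) {
    rr <- coords[i, 1L]; ci <- coords[i, 2L]
    patches[, , , i] <- px[(rr * p + 1L):((rr + 1L) * p),
                           (ci * p + 1L):((ci + 1L) * p), , drop = FALSE]
  }
  list(patchSize = p, rows = r, cols = cc, coords = coords,
       patches = patches)
}

#' Reassemble a patch grid into an image array
#'
#' Inverse of [patchify()]; useful for asserting that the tiling is an
#' exact partition.
#'
#' @param grid a list as returned by [patchify()].
#' @return the \code{h x w x 3} array.
#' @export
unpatchify <- function(grid) {
  p <- grid$patchSize
  out <- array(0, c(grid$rows * p, grid$cols * p, 3L))
  for (i in seq_len(nrow(grid$coords))) {
    rr <- grid$coords[i, 1L]; ci <- grid$coords[i, 2L]
    out[(rr * p + 1L):((rr + 1L) * p),
        (ci * p + 1L):((ci + 1L) * p), ] <- grid$patches[, , , i]
  }
  out
}

#' Merged whole-image + exemplar-patch features
#'
#' Extracts backbone features from the whole image and from every
#' non-overlapping \code{p x p} patch, concatenated as: whole-image block
#' first, then patch blocks in row-major order, each of length
#' \code{outputDim(backbone)}.
#'
#' @param img a [CanonicalImage-class] or \code{h x w x 3} array.
#' @param backbone a [FeatureBackbone-class].
#' @param p patch side length (default 28).
#' @return a [MergedFeatures-class]; for a 224 canvas with \code{p = 28}
#'   and a 1000-dimensional backbone its length is 65,000.
#' @export
extractExemplarFeatures <- function(img, backbone, p = 28L) {
  grid <- patchify(img, p)
  d <- backbone@outputDim
  n <- nrow(grid$coords)
  blocks <- c("whole",
              sprintf("patch_%d_%d", grid$coords[, 1L], grid$coords[, 2L]))
  vals <- numeric((n + 1L) * d)
  vals[seq_len(d)] <- extractFeatures(backbone, img)
  for (i in seq_len(n))
    vals[(i * d + 1L):((i + 1L) * d)] <-
      extractFeatures(backbone, grid$patches[, , , i])
  names(vals) <- paste0(rep(blocks, each = d), "_f",
                        formatC(rep(seq_len(d), n + 1L), width = 4,
                                flag = "0"))
  layout <- data.frame(block = blocks,
                       start = seq(1L, by = d, length.out = n + 1L),
                       length = d)
  methods::new("MergedFeatures", values = vals, layout = layout)
}

#' @describeIn extractExemplarFeatures numeric values of a merged vector.
#' @param x a [MergedFeatures-class].
#' @export
mergedValues <- function(x) x@values

#' @describeIn extractExemplarFeatures block layout of a merged vector.
#' @export
mergedLayout <- function(x) x@layout

setMethod("show", "MergedFeatures", function(object) {
  cat(sprintf("MergedFeatures: %d values in %d blocks (%s...)\n",
              length(object@values), nrow(object@layout),
              paste(utils::head(object@layout$block, 3), collapse = ", ")))
})

#' Build the exemplar feature matrix for a set of images
#'
#' Runs [extractExemplarFeatures()] on every image and assembles an
#' [ExemplarFeatures-class] (a \code{SummarizedExperiment}: features as
#' rows, samples as columns, in input order). Labels and views are taken
#' from the images.
#'
#' @param images non-empty list of [CanonicalImage-class].
#' @param backbone a [FeatureBackbone-class].
#' @param p patch side length (default 28).
#' @param sampleIds optional sample identifiers (default \code{s1, s2, ...}).
#' @return an [ExemplarFeatures-class].
#' @export
buildFeatureMatrix <- function(images, backbone, p = 28L,
                               sampleIds = NULL) {
  if (!length(images)) stop("empty image list")
  if (is.null(sampleIds)) sampleIds <- paste0("s", seq_along(images))
  merged <- lapply(images, extractExemplarFeatures, backbone = backbone,
                   p = p)
  mat <- vapply(merged, mergedValues,
                numeric(length(merged[[1L]]@values)))
  rownames(mat) <- names(merged[[1L]]@values)
  colnames(mat) <- sampleIds
  lay <- merged[[1L]]@layout
  rd <- S4Vectors::DataFrame(
    block = rep(lay$block, each = lay$length[1L]),
    within = rep(seq_len(lay$length[1L]), nrow(lay)))
  cd <- S4Vectors::DataFrame(
    sample_id = sampleIds,
    label = vapply(images, function(x) x@label, character(1)),
    view = vapply(images, function(x) x@view, character(1)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = mat), rowData = rd, colData = cd)
  methods::as(se, "ExemplarFeatures")
}

#' @rdname accessors
#' @export
setMethod("featureMatrix", "ExemplarFeatures", function(x)
  t(SummarizedExperiment::assay(x, "features")))

#' @rdname accessors
#' @export
setMethod("sampleLabels", "ExemplarFeatures", function(x)
  as.character(SummarizedExperiment::colData(x)$label))

#' Write / read a feature matrix as CSV
#'
#' The CSV has one row per sample: \code{sample_id}, \code{label},
#' \code{view}, then one column per feature. \code{readFeatureCSV} inverts
#' it losslessly (block structure is recovered from the feature names).
#'
#' @param x an [ExemplarFeatures-class].
#' @param path output CSV path.
#' @return \code{writeFeatureCSV} returns \code{path} invisibly;
#'   \code{readFeatureCSV} returns an [ExemplarFeatures-class].
#' @export
writeFeatureCSV <- function(x, path) {
  df <- data.frame(
    sample_id = SummarizedExperiment::colData(x)$sample_id,
    label = sampleLabels(x),
    view = SummarizedExperiment::colData(x)$view,
    featureMatrix(x), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureCSV
#' @export
readFeatureCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- df[, c("sample_id", "label", "view")]
  mat <- t(as.matrix(df[, -(1:3), drop = FALSE]))
  colnames(mat) <- meta$sample_id
  block <- sub("_f[0-9]+$", "", rownames(mat))
  within <- as.integer(sub("^.*_f", "", rownames(mat)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = mat),
    rowData = S4Vectors::DataFrame(block = block, within = within),
    colData = S4Vectors::DataFrame(meta))
  methods::as(se, "ExemplarFeatures")
}
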