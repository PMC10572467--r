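#' @import methods
#' @importFrom stats rnorm runif sd
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Crop box in pixel coordinates
#'
#' Half-open rectangle \code{[top, bottom) x [left, right)} in 0-based pixel
#' indices, recording where a brain-area crop was taken from the source slice.
#'
#' @slot top,left,bottom,right integer pixel bounds, 0-based, half-open.
#' @export
setClass("CropBox",
  representation(top = "integer", left = "integer",
                 bottom = "integer", right = "integer"),
  validity = function(object) {
    if (length(object@top) != 1L || length(object@bottom) != 1L ||
        length(object@left) != 1L || length(object@right) != 1L)
      return("all bounds must be scalar")
    if (object@top < 0L || object@left < 0L)
      return("top/left must be >= 0")
    if (object@bottom <= object@top) return("bottom must exceed top")
    if (object@right <= object@left) return("right must exceed left")
    TRUE
  })

#' Raw 2-D brain slice
#'
#' A slice image as loaded from disk or produced by the synthetic generator:
#' a height x width (x 3) array of finite intensities, normally in [0,1]
#' (integer PNG/JPEG/TIFF data are scaled by their bit-depth maximum at load
#' time), plus label and anatomical view metadata.
#'
#' @slot pixels numeric array, \code{h x w} (grayscale) or \code{h x w x 3}.
#' @slot sourcePath character; file of origin, or \code{NA} for in-memory.
#' @slot label character class label, or \code{NA} if unlabelled.
#' @slot view one of \code{"axial"}, \code{"sagittal"}, \code{"unknown"}.
#' @export
setClass("BrainSlice",
  representation(pixels = "array", sourcePath = "character",
                 label = "character", view = "character"),
  prototype(sourcePath = NA_character_, label = NA_character_,
            view = "unknown"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (!length(d) %in% c(2L, 3L)) return("pixels must be 2-D or 3-D")
    if (d[1L] < 8L || d[2L] < 8L) return("image must be at least 8x8")
    if (length(d) == 3L && !d[3L] %in% c(1L, 3L))
      return("channel count must be 1 or 3")
    if (!all(is.finite(object@pixels))) return("intensities must be finite")
    if (!object@view %in% c("axial", "sagittal", "unknown"))
      return("view must be axial, sagittal or unknown")
    TRUE
  })

#' Canonical preprocessed image
#'
#' The pipeline's working representation: a 224 x 224 x 3 float array with
#' all values in [0,1], together with the crop box that was applied to the
#' source slice and the carried-over label/view metadata.
#'
#' @slot pixels numeric array \code{size x size x 3}, values in [0,1].
#' @slot crop a [CropBox-class] recording the brain-area crop.
#' @slot label,view carried over from the source [BrainSlice-class].
#' @export
setClass("CanonicalImage",
  representation(pixels = "array", crop = "CropBox",
                 label = "character", view = "character"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (length(d) != 3L || d[3L] != 3L || d[1L] != d[2L])
      return("pixels must be size x size x 3")
    if (min(object@pixels) < 0 || max(object@pixels) > 1)
      return("pixel values must lie in [0,1]")
    TRUE
  })

#' Feature-extraction backbones
#'
#' A backbone maps any canonical image or patch to a fixed-length feature
#' vector of \code{outputDim} finite floats (1000 by default, matching the
#' fully connected output of the reference CNN). Two concrete kinds are
#' provided: a deterministic seeded Gaussian-projection mock
#' ([MockBackbone-class]) and a small trainable CNN
#' ([FineTunedBackbone-class]).
#'
#' @slot name human-readable backbone name.
#' @slot inputSize side length (pixels) images are resized to internally.
#' @slot outputDim number of features produced per image.
#' @slot kind one of \code{"mock"}, \code{"pretrained"}, \code{"finetuned"}.
#' @export
setClass("FeatureBackbone",
  representation("VIRTUAL", name = "character", inputSize = "integer",
                 outputDim = "integer", kind = "character"),
  validity = function(object) {
    if (object@outputDim < 1L) return("outputDim must be >= 1")
    if (object@inputSize < 8L) return("inputSize must be >= 8")
    TRUE
  })

#' @describeIn FeatureBackbone-class deterministic mock backbone: resize,
#'   grayscale, z-normalize, multiply by a seed-fixed Gaussian projection.
#' @slot seed integer seed that fixed the projection matrix.
#' @slot projection \code{outputDim x inputSize^2} Gaussian matrix.
#' @export
setClass("MockBackbone", contains = "FeatureBackbone",
  representation(seed = "integer", projection = "matrix"),
  validity = function(object) {
    if (!all(dim(object@projection) ==
             c(object@outputDim, object@inputSize^2)))
      return("projection must be outputDim x inputSize^2")
    TRUE
  })

#' @describeIn FeatureBackbone-class small CNN with seeded frozen
#'   convolutional blocks and trained fully connected layers; the feature
#'   vector is the linear output of the fully connected feature layer.
#' @slot seed training seed.
#' @slot conv1,conv2 convolution filter banks (frozen after seeding).
#' @slot W1,b1 fully connected feature layer (trained).
#' @slot W2,b2 softmax classifier head (trained).
#' @slot classes class levels seen during training.
#' @slot history per-epoch training/validation accuracy log.
#' @export
setClass("FineTunedBackbone", contains = "FeatureBackbone",
  representation(seed = "integer", conv1 = "array", conv2 = "array",
                 W1 = "matrix", b1 = "numeric", W2 = "matrix", b2 = "numeric",
                 classes = "character", history = "data.frame"))

#' Merged exemplar feature vector
#'
#' Ordered concatenation of whole-image features followed by per-patch
#' features in row-major patch order, each block \code{d} entries long.
#' With the defaults (224 canvas, 28-pixel patches, d = 1000) the length is
#' (64 + 1) * 1000 = 65,000.
#'
#' @slot values named numeric vector of length \code{(r*c + 1) * d}.
#' @slot layout data.frame with one row per block: \code{block} name
#'   ("whole" or "patch_<row>_<col>"), 1-based \code{start}, \code{length}.
#' @export
setClass("MergedFeatures",
  representation(values = "numeric", layout = "data.frame"),
  validity = function(object) {
    if (!all(is.finite(object@values))) return("values must be finite")
    if (sum(object@layout$length) != length(object@values))
      return("layout lengths must sum to value length")
    TRUE
  })

#' Exemplar feature matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one assay,
#' \code{"features"}, with features as rows and samples as columns.
#' \code{rowData} records each feature's block of origin ("whole" or
#' "patch_<row>_<col>") and its index within the block; \code{colData} holds
#' \code{sample_id}, \code{label} and \code{view}.
#'
#' @seealso [buildFeatureMatrix()], [featureMatrix()], [sampleLabels()]
#' @export
setClass("ExemplarFeatures", contains = "SummarizedExperiment",
  validity = function(object) {
    if (!"features" %in% SummarizedExperiment::assayNames(object))
      return("assay 'features' is required")
    if (!"label" %in% colnames(SummarizedExperiment::colData(object)))
      return("colData must contain a 'label' column")
    if (!all(is.finite(SummarizedExperiment::assay(object, "features"))))
      return("features must be finite")
    TRUE
  })

#' Greedy mRMR feature ranking
#'
#' The result of the greedy minimum-redundancy maximum-relevance pass:
#' a prefix of the feature indices in selection order, the selection score
#' at each step (relevance minus mean redundancy against the already-selected
#' set), and the per-feature relevance I(x_j; y) in bits.
#'
#' @slot order integer feature indices in selection order (no repeats).
#' @slot scores numeric selection score per step.
#' @slot relevance numeric, I(x_j; y) for every feature.
#' @export
setClass("MRMRRanking",
  representation(order = "integer", scores = "numeric",
                 relevance = "numeric"),
  validity = function(object) {
    if (anyDuplicated(object@order)) return("order must not repeat indices")
    if (length(object@scores) != length(object@order))
      return("scores must match order length")
    TRUE
  })

#' Iterative subset-size selection result
#'
#' The cross-validated misclassification curve over candidate prefix sizes
#' of an mRMR ranking, and the chosen size (minimum error, ties broken to
#' the smallest size).
#'
#' @slot qGrid candidate subset sizes evaluated.
#' @slot cvError misclassification rate per size.
#' @slot chosenQ the selected subset size.
#' @slot chosenIndices ranking prefix of length \code{chosenQ}.
#' @export
setClass("SelectionResult",
  representation(qGrid = "integer", cvError = "numeric",
                 chosenQ = "integer", chosenIndices = "integer"),
  validity = function(object) {
    if (length(object@qGrid) != length(object@cvError))
      return("qGrid and cvError must align")
    if (!object@chosenQ %in% object@qGrid)
      return("chosenQ must be in qGrid")
    TRUE
  })

#' Random-subspace KNN ensemble
#'
#' Thirty (by default) k-nearest-neighbour learners, each bound to a random
#' 86-dimensional (by default) feature subspace drawn without replacement
#' from a learner-specific seeded stream. Distances are Euclidean on
#' z-normalized features; normalization statistics are learned from the
#' training data stored in the model.
#'
#' @slot subsets list of integer feature-index vectors, one per learner.
#' @slot L learner count.
#' @slot subspaceDim requested subspace dimension (clamped to n_features).
#' @slot k neighbours per learner.
#' @slot seed ensemble seed.
#' @slot trainX training matrix (samples x features, raw scale).
#' @slot trainY factor of training labels.
#' @slot classes fixed class order used for vote tie-breaking.
#' @slot center,scale per-feature z-normalization statistics.
#' @export
setClass("SubspaceKNN",
  representation(subsets = "list", L = "integer", subspaceDim = "integer",
                 k = "integer", seed = "integer", trainX = "matrix",
                 trainY = "factor", classes = "character",
                 center = "numeric", scale = "numeric"),
  validity = function(object) {
    if (length(object@subsets) != object@L)
      return("one subset per learner required")
    TRUE
  })

#' Stratified fold assignment
#'
#' A partition of samples into K folds in which per-class counts across
#' folds differ by at most one.
#'
#' @slot fold integer fold index (1..K) per sample.
#' @slot K number of folds.
#' @slot seed seed used for the shuffle.
#' @export
setClass("FoldAssignment",
  representation(fold = "integer", K = "integer", seed = "integer"),
  validity = function(object) {
    if (any(object@fold < 1L) || any(object@fold > object@K))
      return("fold indices must lie in 1..K")
    TRUE
  })
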