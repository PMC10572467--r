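#' Extract a feature vector from an image or patch
#'
#' Maps a canonical image, a raw pixel array, or an EBImage \code{Image} to
#' \code{outputDim(backbone)} finite floats. Inputs of any spatial size are
#' resized internally to the backbone's input size, so 28 x 28 exemplar
#' patches and full 224 x 224 images share one contract.
#'
#' @param backbone a [FeatureBackbone-class].
#' @param img a [CanonicalImage-class], or a numeric array
#'   (\code{h x w} or \code{h x w x 3}) with values in [0,1].
#' @return numeric vector of length \code{outputDim(backbone)}.
#' @export
setGeneric("extractFeatures", function(backbone, img)
  standardGeneric("extractFeatures"))

#' @rdname accessors
#' @export
setGeneric("outputDim", function(x) standardGeneric("outputDim"))

#' @rdname accessors
#' @export
setGeneric("inputSize", function(x) standardGeneric("inputSize"))

#' @rdname accessors
#' @export
setGeneric("backboneKind", function(x) standardGeneric("backboneKind"))

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname accessors
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @rdname accessors
#' @export
setGeneric("cropBox", function(x) standardGeneric("cropBox"))

#' @rdname accessors
#' @export
setGeneric("rankedOrder", function(x) standardGeneric("rankedOrder"))

#' @rdname accessors
#' @export
setGeneric("chosenFeatures", function(x) standardGeneric("chosenFeatures"))

#' @rdname accessors
#' @export
setGeneric("selectionCurve", function(x) standardGeneric("selectionCurve"))

#' @rdname accessors
#' @export
setGeneric("foldIds", function(x) standardGeneric("foldIds"))

#' Accessors for exemplarMRI classes
#'
#' Small read-only accessors: \code{outputDim}/\code{inputSize}/
#' \code{backboneKind} for backbones, \code{featureMatrix} (samples x
#' features) and \code{sampleLabels} for [ExemplarFeatures-class],
#' \code{cropBox} for canonical images, \code{rankedOrder} for rankings,
#' \code{chosenFeatures}/\code{selectionCurve} for selection results, and
#' \code{foldIds} for fold assignments.
#'
#' @param x the object.
#' @name accessors
NULL
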