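#' Capture activations and gradients at a named layer
#'
#' Runs one forward and one backward pass and records, at the virtual
#' identity point immediately after the named layer, the layer output
#' activations together with the gradient of the cross-entropy loss
#' (against \code{targetClass}) with respect to that output. The capture is
#' a pure observation: it never changes the network prediction.
#'
#' @param model a \linkS4class{ToyClassifier}.
#' @param image numeric matrix \code{H x W} in \eqn{[0,1]} (grayscale) or an
#'   \code{H x W x C} array matching the model input shape. Grayscale input
#'   is replicated across channels for 3-channel models.
#' @param layerId one of \code{namedLayers(model)}.
#' @param targetClass 0-based class index in \code{[0, numClasses)}.
#' @param inputId identifier stored in the capture record.
#' @return a \linkS4class{LayerCapture}.
#' @export
setGeneric("captureLayer", function(model, image, layerId, targetClass,
                                    inputId = "input") {
  standardGeneric("captureLayer")
})

#' Re-draw model parameters under a randomisation scheme
#'
#' \code{FR} (fully randomised) re-draws every trainable weight with He
#' initialisation (fan-in, normal) and zeroes the biases. \code{SR}
#' (semi-randomised) keeps the backbone of \code{model} bit-identical and
#' re-draws only the final classification head. Both are deterministic
#' given \code{seed}.
#'
#' @param model a \linkS4class{ToyClassifier} (the reference model).
#' @param kind \code{"FR"} or \code{"SR"}.
#' @param seed integer seed for the re-draw.
#' @return a new \linkS4class{ToyClassifier}.
#' @export
setGeneric("randomiseModel", function(model, kind, seed) {
  standardGeneric("randomiseModel")
})

#' Gaussian smoothing of a saliency map
#'
#' Separable 2-D Gaussian convolution with reflect boundary handling and
#' the kernel truncated at radius \code{ceiling(4 * sigma)};
#' \code{sigma = 0} is the identity.
#'
#' @param map a \linkS4class{SaliencyMap}.
#' @param sigma standard deviation in pixels (default 1.0).
#' @return a smoothed \linkS4class{SaliencyMap} with the \code{smoothed}
#'   flag set.
#' @export
setGeneric("smoothMap", function(map, sigma = 1.0) standardGeneric("smoothMap"))

#' Difference of Means between two trial-accuracy sets
#'
#' \code{dom = |mean(a) - mean(b)|}, the linear-kernel maximum mean
#' discrepancy between two one-dimensional empirical sets. Lower values
#' mean the saliency detector behaves more consistently across the two
#' architectures.
#'
#' @param a,b \linkS4class{TrialAccuracySet} objects (or bare numeric
#'   vectors of accuracies).
#' @return a \linkS4class{DoMResult}.
#' @export
setGeneric("domConsistency", function(a, b) standardGeneric("domConsistency"))

#' @rdname accessors
#' @export
setGeneric("namedLayers", function(x) standardGeneric("namedLayers"))
#' @rdname accessors
#' @export
setGeneric("numClasses", function(x) standardGeneric("numClasses"))
#' @rdname accessors
#' @export
setGeneric("inputShape", function(x) standardGeneric("inputShape"))
#' @rdname accessors
#' @export
setGeneric("architectureId", function(x) standardGeneric("architectureId"))
#' @rdname accessors
#' @export
setGeneric("saliencyValues", function(x) standardGeneric("saliencyValues"))
#' @rdname accessors
#' @export
setGeneric("activations", function(x) standardGeneric("activations"))
#' @rdname accessors
#' @export
setGeneric("gradients", function(x) standardGeneric("gradients"))
#' @rdname accessors
#' @export
setGeneric("boxes", function(x) standardGeneric("boxes"))
#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))
#' @rdname accessors
#' @export
setGeneric("argmaxRC", function(x) standardGeneric("argmaxRC"))
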