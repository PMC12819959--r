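#' Build an instrumented toy CNN classifier
#'
#' Constructs one of the two built-in classifier families with
#' He-initialised parameters. Both families expose named capture layers
#' (block outputs plus a penultimate layer) through
#' \code{\link{namedLayers}} and are deterministic given \code{seed}.
#'
#' \describe{
#'   \item{\code{toy_a}}{plain strided conv-ReLU blocks with ResNet-style
#'     layer names \code{conv1.0}, \code{conv2.0}, \code{conv3.0},
#'     \code{conv4.0}, \code{conv4.1}, \code{conv4.2}; global average
#'     pooling and a linear head.}
#'   \item{\code{toy_b}}{a depthwise-separable family of different widths
#'     and depth (names \code{features.0.0} ... \code{features.6.0}),
#'     giving a genuinely different architecture for cross-architecture
#'     consistency experiments.}
#' }
#'
#' @param architectureId \code{"toy_a"} or \code{"toy_b"}.
#' @param numClasses number of output classes (>= 2).
#' @param inputShape integer \code{(C, H, W)}; channels must be 1 or 3.
#' @param seed integer seed for He initialisation.
#' @return a \linkS4class{ToyClassifier}.
#' @examples
#' m <- buildClassifier("toy_a", seed = 7)
#' namedLayers(m)
#' @export
buildClassifier <- function(architectureId, numClasses = 2L,
                            inputShape = c(1L, 64L, 64L), seed = 1L) {
  if (!architectureId %in% c("toy_a", "toy_b"))
    stop("unknown architecture_id: ", architectureId)
  inputShape <- as.integer(inputShape)
  layers <- switch(architectureId,
                   toy_a = .toyALayers(inputShape, as.integer(numClasses)),
                   toy_b = .toyBLayers(inputShape, as.integer(numClasses)))
  layers <- .withSeed(seed, lapply(layers, .heInitLayer))
  ids <- vapply(layers, function(l) l$id %||% NA_character_, "")
  new("ToyClassifier", architectureId = architectureId, layers = layers,
      namedLayers = ids[!is.na(ids)], numClasses = as.integer(numClasses),
      inputShape = inputShape, seed = as.integer(seed))
}

.toyALayers <- function(inputShape, numClasses) {
  C <- inputShape[1L]; H <- inputShape[2L]; W <- inputShape[3L]
  widths <- c(12L, 16L, 24L, 32L, 32L, 32L)
  strides <- c(2L, 2L, 2L, 2L, 1L, 1L)
  ids <- c("conv1.0", "conv2.0", "conv3.0", "conv4.0", "conv4.1", "conv4.2")
  layers <- list()
  inC <- C
  for (i in seq_along(widths)) {
    cv <- .convLayer(NULL, inC, widths[i], 3L, strides[i], 1L, H, W)
    layers <- c(layers, list(cv, .reluLayer(ids[i])))
    H <- cv$outH; W <- cv$outW; inC <- widths[i]
  }
  c(layers, list(.gapLayer(), .fcLayer(NULL, inC, numClasses)))
}

.toyBLayers <- function(inputShape, numClasses) {
  C <- inputShape[1L]; H <- inputShape[2L]; W <- inputShape[3L]
  layers <- list()
  stem <- .convLayer(NULL, C, 16L, 3L, 2L, 1L, H, W)
  layers <- c(layers, list(stem, .reluLayer("features.0.0")))
  H <- stem$outH; W <- stem$outW
  blocks <- list(list(s = 2L, outC = 24L), list(s = 1L, outC = 24L),
                 list(s = 2L, outC = 32L), list(s = 1L, outC = 32L),
                 list(s = 2L, outC = 48L))
  inC <- 16L
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    dw <- .dwLayer(NULL, inC, 3L, b$s, 1L, H, W)
    H <- dw$outH; W <- dw$outW
    pw <- .convLayer(NULL, inC, b$outC, 1L, 1L, 0L, H, W)
    layers <- c(layers, list(dw, .reluLayer(NULL), pw,
                             .reluLayer(sprintf("features.%d.0", i))))
    inC <- b$outC
  }
  head <- .convLayer(NULL, inC, 64L, 1L, 1L, 0L, H, W)
  layers <- c(layers, list(head, .reluLayer("features.6.0"), .gapLayer(),
                           .fcLayer(NULL, 64L, numClasses)))
  layers
}

## Coerce a grayscale matrix or H x W x C array to the model's input
## layout, replicating grayscale across channels for 3-channel models,
## and center [0,1] intensities to [-1,1] (the model's fixed input
## normalization; zero-centred inputs keep the bias-free first layer from
## saturating early in training).
.coerceImage <- function(model, image) {
  if (any(!is.finite(image))) stop("non-finite values in input image")
  sh <- model@inputShape
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1L))
  d <- dim(image)
  if (length(d) != 3L) stop("image must be H x W or H x W x C")
  if (d[1L] != sh[2L] || d[2L] != sh[3L])
    stop(sprintf("image is %dx%d but model expects %dx%d",
                 d[1L], d[2L], sh[2L], sh[3L]))
  if (d[3L] == 1L && sh[1L] == 3L)
    image <- array(image, dim = c(d[1L], d[2L], 3L))
  else if (d[3L] != sh[1L])
    stop("image channels incompatible with model input shape")
  2 * image - 1
}

#' Forward-evaluate a classifier
#'
#' @param model a \linkS4class{ToyClassifier}.
#' @param image grayscale matrix or \code{H x W x C} array.
#' @return numeric logit vector of length \code{numClasses(model)}.
#' @export
classifierLogits <- function(model, image) {
  x <- .coerceImage(model, image)
  .netForward(model@layers, x)$logits
}

#' Predicted class probabilities
#'
#' @inheritParams classifierLogits
#' @return softmax probabilities over classes.
#' @export
classifierProbs <- function(model, image) {
  .softmax(classifierLogits(model, image))
}

.layerIndex <- function(model, layerId) {
  ids <- vapply(model@layers, function(l) l$id %||% NA_character_, "")
  at <- match(layerId, ids)
  if (is.na(at))
    stop("unknown layer id '", layerId, "'; available: ",
         paste(model@namedLayers, collapse = ", "))
  at
}

#' @rdname captureLayer
#' @export
setMethod("captureLayer", "ToyClassifier",
          function(model, image, layerId, targetClass, inputId = "input") {
  at <- .layerIndex(model, layerId)
  targetClass <- as.integer(targetClass)
  if (targetClass < 0L || targetClass >= model@numClasses)
    stop("targetClass out of range")
  x <- .coerceImage(model, image)
  fw <- .netForward(model@layers, x)
  bw <- .netBackward(model@layers, fw, targetClass)
  acts <- fw$caches[[at]]$out
  grads <- bw$dacts[[at]]
  new("LayerCapture", layerId = layerId, activations = acts,
      gradients = array(grads, dim = dim(acts)),
      targetClass = targetClass, inputId = inputId)
})

#' @rdname randomiseModel
#' @export
setMethod("randomiseModel", "ToyClassifier", function(model, kind, seed) {
  if (!kind %in% c("FR", "SR")) stop("scheme kind must be 'FR' or 'SR'")
  layers <- model@layers
  .withSeed(seed, {
    for (i in seq_along(layers)) {
      l <- layers[[i]]
      if (l$type %in% c("conv", "dwconv") && kind == "FR")
        layers[[i]] <- .heInitLayer(l)
      else if (l$type == "fc")
        layers[[i]] <- .heInitLayer(l)
    }
  })
  initialize(model, layers = layers)
})

#' Flattened model parameters
#'
#' Returns the trainable parameters as a named list of numeric arrays,
#' one \code{<n>.W} / \code{<n>.b} pair per parameterised layer in network
#' order. Mainly used to verify the randomisation-scheme contracts.
#'
#' @param model a \linkS4class{ToyClassifier}.
#' @param backboneOnly drop the final classification head.
#' @return named list of numeric arrays.
#' @export
modelParameters <- function(model, backboneOnly = FALSE) {
  out <- list()
  for (i in seq_along(model@layers)) {
    l <- model@layers[[i]]
    if (!l$type %in% c("conv", "dwconv", "fc")) next
    if (backboneOnly && l$type == "fc") next
    out[[sprintf("layer%02d.W", i)]] <- l$W
    out[[sprintf("layer%02d.b", i)]] <- l$b
  }
  out
}

#' Multi-layer saliency presets
#'
#' The default layer sets used for multi-layer NormGrad aggregation:
#' for \code{toy_a} the four block outputs \code{conv2.0, conv3.0,
#' conv4.0, conv4.2}; for \code{toy_b} every named block output including
#' the penultimate layer.
#'
#' @param model a \linkS4class{ToyClassifier} or an architecture id string.
#' @return character vector of layer identifiers.
#' @export
layerPreset <- function(model) {
  id <- if (is(model, "ToyClassifier")) model@architectureId else model
  switch(id,
         toy_a = c("conv2.0", "conv3.0", "conv4.0", "conv4.2"),
         toy_b = c("features.0.0", "features.1.0", "features.2.0",
                   "features.3.0", "features.4.0", "features.5.0",
                   "features.6.0"),
         stop("unknown architecture_id: ", id))
}

#' Penultimate capture layer
#'
#' The last named convolutional layer before global average pooling; the
#' default target of single-layer saliency methods.
#'
#' @param model a \linkS4class{ToyClassifier}.
#' @export
penultimateLayer <- function(model) {
  nl <- model@namedLayers
  nl[length(nl)]
}
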