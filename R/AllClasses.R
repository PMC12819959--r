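#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Virtual identity layer specification
#'
#' The virtual identity layer (VIL) is the imagined identity transformation
#' inserted immediately after a target layer so that activations and
#' gradients are read at the same network point. Its assumed parametric
#' form determines the NormGrad spatial-contribution formula:
#' \code{"scaling"} treats it as a per-position channel scaling,
#' \code{"conv"} as an \code{N x N} convolution (the spatial contribution
#' becomes an outer product of the upstream gradient with the unfolded
#' activation patch).
#'
#' @slot kind \code{"scaling"} or \code{"conv"}.
#' @slot N odd kernel size; used only when \code{kind == "conv"}.
#' @export
setClass("VILSpec", representation(kind = "character", N = "integer"),
         prototype(kind = "scaling", N = 1L))

setValidity("VILSpec", function(object) {
  if (length(object@kind) != 1L || !object@kind %in% c("scaling", "conv"))
    return("kind must be 'scaling' or 'conv'")
  if (object@kind == "conv") {
    if (length(object@N) != 1L || is.na(object@N) || object@N < 1L)
      return("conv VIL requires N >= 1")
    if (object@N %% 2L == 0L)
      return("conv VIL kernel size N must be odd")
  }
  TRUE
})

#' @param kind,N see slots.
#' @rdname VILSpec-class
#' @export
vilSpec <- function(kind = c("scaling", "conv"), N = 1L) {
  kind <- match.arg(kind)
  new("VILSpec", kind = kind, N = as.integer(N))
}

setClassUnion("VILSpecOrNULL", c("VILSpec", "NULL"))

#' Instrumented toy CNN classifier
#'
#' A small convolutional classifier whose named internal layers can all be
#' observed: for any layer identifier the forward activations and the
#' backward gradients of the loss are read at the same point (the virtual
#' identity layer contract). Two deliberately distinct families exist:
#' \code{"toy_a"} (plain strided conv blocks, ResNet-style layer names
#' \code{conv1.0 ... conv4.2}) and \code{"toy_b"} (depthwise-separable
#' blocks, names \code{features.0.0 ... features.6.0}).
#'
#' Activation tensors are stored as \code{H x W x K} arrays (rows = image
#' rows, channels last).
#'
#' @slot architectureId \code{"toy_a"} or \code{"toy_b"}.
#' @slot layers internal ordered list of layer records (weights, geometry).
#' @slot namedLayers capture-point identifiers in network order.
#' @slot numClasses number of output classes.
#' @slot inputShape integer \code{(C, H, W)}.
#' @slot seed build seed.
#' @export
setClass("ToyClassifier",
         representation(architectureId = "character", layers = "list",
                        namedLayers = "character", numClasses = "integer",
                        inputShape = "integer", seed = "integer"))

setValidity("ToyClassifier", function(object) {
  if (length(object@inputShape) != 3L) return("inputShape must be (C, H, W)")
  if (!object@inputShape[1L] %in% c(1L, 3L))
    return("input channels must be 1 or 3")
  if (object@numClasses < 2L) return("numClasses must be >= 2")
  ids <- vapply(object@layers, function(l) l$id %||% NA_character_, "")
  if (!all(object@namedLayers %in% ids))
    return("every named layer must resolve to exactly one layer record")
  TRUE
})

#' Captured activations and gradients of one layer
#'
#' The record accumulated at a virtual identity layer: output activations
#' \code{x^out} and the upstream gradient \code{g^out} of the scalar
#' cross-entropy loss with respect to that output, for one input image and
#' one target class. Both arrays are \code{H' x W' x K'}.
#'
#' @slot layerId the named layer.
#' @slot activations \code{H' x W' x K'} array (\code{x^out}).
#' @slot gradients \code{H' x W' x K'} array (\code{g^out}).
#' @slot targetClass 0-based class the loss was taken against.
#' @slot inputId input identifier.
#' @export
setClass("LayerCapture",
         representation(layerId = "character", activations = "array",
                        gradients = "array", targetClass = "integer",
                        inputId = "character"))

setValidity("LayerCapture", function(object) {
  if (!identical(dim(object@activations), dim(object@gradients)))
    return("activations and gradients must have identical shape")
  if (length(dim(object@activations)) != 3L)
    return("captures are H' x W' x K' arrays")
  TRUE
})

#' Saliency heat map
#'
#' A non-negative 2-D heat map at input resolution, with provenance
#' metadata: the detector that produced it, the virtual identity layer
#' variant (for NormGrad), the contributing layers, and whether Gaussian
#' smoothing has been applied.
#'
#' @slot values non-negative finite \code{H x W} matrix.
#' @slot method detector name (e.g. \code{"normgrad"}, \code{"grad_cam"}).
#' @slot vil a \linkS4class{VILSpec} or \code{NULL}.
#' @slot layers contributing layer identifiers.
#' @slot smoothed logical flag.
#' @export
setClass("SaliencyMap",
         representation(values = "matrix", method = "character",
                        vil = "VILSpecOrNULL", layers = "character",
                        smoothed = "logical"),
         prototype(method = "unknown", vil = NULL, layers = character(),
                   smoothed = FALSE))

setValidity("SaliencyMap", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (anyNA(v) || any(!is.finite(v))) return("values must be finite")
  if (any(v < 0)) return("values must be non-negative")
  TRUE
})

#' Annotated image record
#'
#' One grayscale image with its binary quality label and zero or more
#' ground-truth bounding boxes. Boxes are 0-based, half-open pixel
#' rectangles \code{[x_min, x_max) x [y_min, y_max)} with \code{x} the
#' column and \code{y} the row coordinate. A record is positive
#' (label 1) if and only if it carries at least one box.
#'
#' @slot inputId identifier.
#' @slot pixels \code{H x W} matrix in \eqn{[0,1]}.
#' @slot label 0 or 1.
#' @slot boxes data.frame with columns \code{x_min, y_min, x_max, y_max}.
#' @export
setClass("AnnotatedImage",
         representation(inputId = "character", pixels = "matrix",
                        label = "integer", boxes = "data.frame"))

setValidity("AnnotatedImage", function(object) {
  b <- object@boxes
  need <- c("x_min", "y_min", "x_max", "y_max")
  if (!all(need %in% names(b))) return("boxes need x_min,y_min,x_max,y_max")
  if ((object@label == 1L) != (nrow(b) > 0L))
    return("label must be 1 iff at least one box is present")
  if (nrow(b)) {
    H <- nrow(object@pixels); W <- ncol(object@pixels)
    if (any(b$x_min >= b$x_max) || any(b$y_min >= b$y_max))
      return("boxes must satisfy x_min < x_max and y_min < y_max")
    if (any(b$x_min < 0) || any(b$y_min < 0) ||
        any(b$x_max > W) || any(b$y_max > H))
      return("boxes must lie within image bounds")
  }
  TRUE
})

#' Pointing Game evaluation result
#'
#' Per-image hit/miss decisions and the aggregate accuracy
#' \eqn{A = T/(T+F)} over all scored images (images without boxes are
#' excluded from scoring). \code{tau} is the tolerance in pixels by which
#' each ground-truth box was dilated on all four sides.
#'
#' @slot hits number of hits \eqn{T}.
#' @slot misses number of misses \eqn{F}.
#' @slot tau tolerance in pixels.
#' @slot perImage data.frame with columns \code{input_id, row, col, hit}.
#' @export
setClass("PointingGameResult",
         representation(hits = "integer", misses = "integer",
                        tau = "integer", perImage = "data.frame"))

setValidity("PointingGameResult", function(object) {
  if (object@hits < 0L || object@misses < 0L) return("negative counts")
  if (object@hits + object@misses < 1L) return("at least one decision needed")
  TRUE
})

#' Repeated-trial Pointing Game accuracies
#'
#' Pointing Game accuracies of one saliency method on several
#' independently trained (or randomised) models of one architecture. Pairs
#' of these across two architectures feed the Difference-of-Means
#' consistency metric.
#'
#' @slot architectureId architecture name.
#' @slot method saliency method name.
#' @slot accuracies numeric vector in \eqn{[0,1]}, one per trial.
#' @export
setClass("TrialAccuracySet",
         representation(architectureId = "character", method = "character",
                        accuracies = "numeric"))

setValidity("TrialAccuracySet", function(object) {
  a <- object@accuracies
  if (!length(a)) return("accuracies must be non-empty")
  if (anyNA(a) || any(a < 0) || any(a > 1)) return("accuracies must be in [0,1]")
  TRUE
})

#' @param architectureId,method,accuracies see slots.
#' @rdname TrialAccuracySet-class
#' @export
trialAccuracySet <- function(accuracies, architectureId = "unknown",
                             method = "unknown") {
  new("TrialAccuracySet", architectureId = architectureId, method = method,
      accuracies = as.numeric(accuracies))
}

#' Difference-of-Means result
#'
#' \code{dom = |meanA - meanB|}; equals the linear-kernel maximum mean
#' discrepancy between the two 1-D accuracy sets, so it is symmetric and
#' non-negative. Lower values indicate a detector that is more consistent
#' across architectures.
#'
#' @slot meanA,meanB the two repeated Pointing Game means.
#' @slot dom the absolute difference of the means.
#' @export
setClass("DoMResult",
         representation(meanA = "numeric", meanB = "numeric", dom = "numeric"))

setValidity("DoMResult", function(object) {
  if (object@dom < 0) return("dom must be non-negative")
  if (abs(object@dom - abs(object@meanA - object@meanB)) > 1e-12)
    return("dom must equal |meanA - meanB|")
  TRUE
})

#' Synthetic benchmark specification
#'
#' Parameters of the synthetic localized-quality-defect generator. Mode
#' \code{"foreign_object"} emulates chest-X-ray-like frames containing
#' zero or more high-contrast radio-opaque shapes (disks, bars, rings);
#' mode \code{"lvot"} emulates cardiac-MR-like frames containing zero or
#' one small soft-edged blob near the image center.
#'
#' @slot mode \code{"foreign_object"} or \code{"lvot"}.
#' @slot nImages total number of images.
#' @slot imageSize integer \code{(H, W)}.
#' @slot positiveFraction fraction of images carrying defects.
#' @slot objectsPerPositive integer range \code{(lo, hi)} (foreign_object).
#' @slot objectSizePx integer range of object diameters in pixels.
#' @slot contrast peak defect intensity above local background, in
#'   \eqn{[0,1]} units.
#' @slot noiseSd pixel noise standard deviation.
#' @slot centerJitterPx maximal blob offset from center (lvot).
#' @slot seed generator seed.
#' @export
setClass("SyntheticSpec",
         representation(mode = "character", nImages = "integer",
                        imageSize = "integer", positiveFraction = "numeric",
                        objectsPerPositive = "integer",
                        objectSizePx = "integer", contrast = "numeric",
                        noiseSd = "numeric", centerJitterPx = "integer",
                        seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  if (!object@mode %in% c("foreign_object", "lvot"))
    return("mode must be 'foreign_object' or 'lvot'")
  if (object@positiveFraction <= 0 || object@positiveFraction >= 1)
    return("positiveFraction must be in (0,1)")
  if (object@contrast <= 0 || object@contrast > 1)
    return("contrast must be in (0,1]")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (max(object@objectSizePx) >= min(object@imageSize))
    return("objects must be smaller than the image")
  TRUE
})

#' Synthetic annotated dataset with disjoint splits
#'
#' @slot train,val,test lists of \linkS4class{AnnotatedImage}.
#' @slot spec the generating \linkS4class{SyntheticSpec}.
#' @export
setClass("SyntheticDataset",
         representation(train = "list", val = "list", test = "list",
                        spec = "SyntheticSpec"))

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- accessors ----

#' Accessors
#'
#' @param x an object of the matching class.
#' @name accessors
#' @aliases namedLayers numClasses inputShape architectureId saliencyValues
#'   activations gradients boxes pixels accuracy argmaxRC
NULL

#' @rdname accessors
#' @export
setMethod("namedLayers", "ToyClassifier", function(x) x@namedLayers)
#' @rdname accessors
#' @export
setMethod("numClasses", "ToyClassifier", function(x) x@numClasses)
#' @rdname accessors
#' @export
setMethod("inputShape", "ToyClassifier", function(x) x@inputShape)
#' @rdname accessors
#' @export
setMethod("architectureId", "ToyClassifier", function(x) x@architectureId)
#' @rdname accessors
#' @export
setMethod("saliencyValues", "SaliencyMap", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("activations", "LayerCapture", function(x) x@activations)
#' @rdname accessors
#' @export
setMethod("gradients", "LayerCapture", function(x) x@gradients)
#' @rdname accessors
#' @export
setMethod("boxes", "AnnotatedImage", function(x) x@boxes)
#' @rdname accessors
#' @export
setMethod("pixels", "AnnotatedImage", function(x) x@pixels)

#' @rdname accessors
#' @export
setMethod("accuracy", "PointingGameResult", function(x) {
  x@hits / (x@hits + x@misses)
})
#' @rdname accessors
#' @export
setMethod("accuracy", "TrialAccuracySet", function(x) x@accuracies)

#' @rdname accessors
#' @export
setMethod("argmaxRC", "SaliencyMap", function(x) saliencyArgmax(x@values))

## ---- show methods ----

setMethod("show", "ToyClassifier", function(object) {
  cat("ToyClassifier '", object@architectureId, "' (seed ", object@seed,
      ")\n", sep = "")
  cat("  input: ", paste(object@inputShape, collapse = "x"),
      "  classes: ", object@numClasses, "\n", sep = "")
  cat("  named layers: ", paste(object@namedLayers, collapse = ", "),
      "\n", sep = "")
})

setMethod("show", "SaliencyMap", function(object) {
  d <- dim(object@values)
  am <- saliencyArgmax(object@values)
  cat("SaliencyMap ", d[1L], "x", d[2L], " [", object@method,
      if (!is.null(object@vil))
        paste0(", vil=", object@vil@kind,
               if (object@vil@kind == "conv") paste0(object@vil@N, "x",
                                                     object@vil@N)),
      if (object@smoothed) ", smoothed", "]\n", sep = "")
  if (length(object@layers))
    cat("  layers: ", paste(object@layers, collapse = ", "), "\n", sep = "")
  cat("  argmax (row,col) = (", am[1L], ",", am[2L], ")  max = ",
      signif(max(object@values), 4L), "\n", sep = "")
})

setMethod("show", "LayerCapture", function(object) {
  d <- dim(object@activations)
  cat("LayerCapture at '", object@layerId, "' for '", object@inputId,
      "': ", d[1L], "x", d[2L], "x", d[3L], " (H'xW'xK'), target class ",
      object@targetClass, "\n", sep = "")
})

setMethod("show", "PointingGameResult", function(object) {
  cat("PointingGameResult: T=", object@hits, " F=", object@misses,
      "  A=", format(accuracy(object), digits = 4L),
      "  (tau=", object@tau, ")\n", sep = "")
})

setMethod("show", "DoMResult", function(object) {
  cat("DoM = |", format(object@meanA, digits = 4L), " - ",
      format(object@meanB, digits = 4L), "| = ",
      format(object@dom, digits = 4L), "\n", sep = "")
})

setMethod("show", "TrialAccuracySet", function(object) {
  ms <- repeatedAccuracy(object)
  cat("TrialAccuracySet [", object@architectureId, ", ", object@method,
      "]: n=", length(object@accuracies), "  ",
      format(ms[["mean"]], digits = 4L), " +/- ",
      format(ms[["std"]], digits = 4L), "\n", sep = "")
})

setMethod("show", "SyntheticDataset", function(object) {
  cat("SyntheticDataset (", object@spec@mode, "): train=",
      length(object@train), " val=", length(object@val), " test=",
      length(object@test), ", ", paste(object@spec@imageSize, collapse = "x"),
      " px, seed ", object@spec@seed, "\n", sep = "")
})
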