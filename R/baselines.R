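#' Baseline saliency detectors
#'
#' The standard comparison detectors evaluated alongside NormGrad. All
#' share the cross-entropy gradient convention of
#' \code{\link{captureLayer}} and return non-negative
#' \linkS4class{SaliencyMap}s at input resolution.
#'
#' \describe{
#'   \item{\code{inputXGrad}}{elementwise product of the input with the
#'     gradient of the loss with respect to the input; absolute value,
#'     summed over channels.}
#'   \item{\code{guidedBackprop}}{input gradient computed with every ReLU
#'     backward rule replaced by the guided rule: the upstream gradient
#'     passes only where the forward input was positive \emph{and} the
#'     upstream gradient is positive; absolute value, channel-summed.}
#'   \item{\code{gradCAM}}{channel weights \eqn{\alpha_k} are the spatial
#'     averages of the layer gradient; the map is
#'     \eqn{\mathrm{ReLU}(\sum_k \alpha_k x^{out}_k)}, upsampled.}
#'   \item{\code{guidedGradCAM}}{pixelwise product of the upsampled
#'     Grad-CAM map and the Guided Backpropagation map.}
#' }
#'
#' @inheritParams captureLayer
#' @param layerId target layer for the CAM-family methods.
#' @return a \linkS4class{SaliencyMap}.
#' @name baselines
NULL

## Gradients are reported with respect to the raw [0,1] image (the chain
## rule through the fixed [-1,1] centering contributes the factor 2), so
## input-space maps refer to the image the user sees.
.inputSpaceMap <- function(model, image, targetClass, guided) {
  targetClass <- as.integer(targetClass)
  if (targetClass < 0L || targetClass >= model@numClasses)
    stop("targetClass out of range")
  x <- .coerceImage(model, image)
  fw <- .netForward(model@layers, x)
  bw <- .netBackward(model@layers, fw, targetClass, guided = guided)
  list(raw = (x + 1) / 2, dinput = 2 * bw$dinput)
}

#' @rdname baselines
#' @export
inputXGrad <- function(model, image, targetClass = 1L) {
  r <- .inputSpaceMap(model, image, targetClass, guided = FALSE)
  d <- dim(r$raw)
  v <- matrix(rowSums(matrix(abs(r$raw * r$dinput), d[1L] * d[2L], d[3L])),
              d[1L], d[2L])
  new("SaliencyMap", values = v, method = "input_x_grad", vil = NULL,
      layers = character(), smoothed = FALSE)
}

#' @rdname baselines
#' @export
guidedBackprop <- function(model, image, targetClass = 1L) {
  if (!any(vapply(model@layers, function(l) l$type == "relu", TRUE)))
    stop("guided backpropagation requires ReLU nonlinearities")
  r <- .inputSpaceMap(model, image, targetClass, guided = TRUE)
  d <- dim(r$raw)
  v <- matrix(rowSums(matrix(abs(r$dinput), d[1L] * d[2L], d[3L])),
              d[1L], d[2L])
  new("SaliencyMap", values = v, method = "guided_backprop", vil = NULL,
      layers = character(), smoothed = FALSE)
}

#' @rdname baselines
#' @export
gradCAM <- function(model, image, layerId = penultimateLayer(model),
                    targetClass = 1L) {
  cap <- .captureAll(model, image, layerId, targetClass)[[1L]]
  a <- cap@activations
  g <- cap@gradients
  d <- dim(a)
  alpha <- colMeans(matrix(g, d[1L] * d[2L], d[3L]))
  cam <- matrix(matrix(a, d[1L] * d[2L], d[3L]) %*% alpha, d[1L], d[2L])
  cam <- pmax(cam, 0)
  toSaliency(cam, model@inputShape[2:3], method = "grad_cam",
             layers = layerId)
}

#' @rdname baselines
#' @export
guidedGradCAM <- function(model, image, layerId = penultimateLayer(model),
                          targetClass = 1L) {
  gc <- gradCAM(model, image, layerId, targetClass)
  gb <- guidedBackprop(model, image, targetClass)
  new("SaliencyMap", values = gc@values * gb@values,
      method = "guided_grad_cam", vil = NULL, layers = layerId,
      smoothed = FALSE)
}
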