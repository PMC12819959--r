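#' NormGrad spatial contributions
#'
#' NormGrad forms, at every spatial position \eqn{u} of a target layer,
#' the gradient of the loss with respect to the parameters of a virtual
#' identity layer inserted right after it, and takes its Frobenius norm.
#'
#' For a \emph{scaling} virtual identity layer the per-position
#' contribution is the elementwise product \eqn{g^{out}_u \odot x^{out}_u}
#' and the map value is its norm over channels,
#' \eqn{\sqrt{\sum_k (g_{k,u} x_{k,u})^2}}.
#'
#' For an \emph{N x N convolutional} virtual identity layer the
#' contribution is the outer product \eqn{g^{out}_u (x^{out}_{u,N\times
#' N})^\top} of the channel gradient with the unfolded (im2col,
#' zero-padded, stride 1) activation patch; since the Frobenius norm of an
#' outer product factorises, the map value is
#' \eqn{\lVert g^{out}_u\rVert_2 \cdot \lVert x^{out}_{u,N\times
#' N}\rVert_2}.
#'
#' @param capture a \linkS4class{LayerCapture}.
#' @param N odd kernel size of the convolutional virtual identity layer.
#' @return numeric \code{H' x W'} matrix of non-negative contributions at
#'   the layer's own resolution.
#' @seealso \code{\link{normGrad}} for the full pipeline including
#'   upsampling, \code{\link{combineMulti}} for multi-layer aggregation.
#' @export
contributionScaling <- function(capture) {
  a <- capture@activations
  g <- capture@gradients
  if (!identical(dim(a), dim(g))) stop("activation/gradient shape mismatch")
  d <- dim(a)
  p <- matrix(a * g, d[1L] * d[2L], d[3L])
  matrix(sqrt(rowSums(p * p)), d[1L], d[2L])
}

#' @rdname contributionScaling
#' @export
contributionConv <- function(capture, N = 1L) {
  N <- as.integer(N)
  if (N < 1L || N %% 2L == 0L) stop("conv VIL kernel size N must be odd")
  a <- capture@activations
  g <- capture@gradients
  if (!identical(dim(a), dim(g))) stop("activation/gradient shape mismatch")
  d <- dim(a)
  gn <- matrix(sqrt(rowSums(matrix(g * g, d[1L] * d[2L], d[3L]))),
               d[1L], d[2L])
  sq <- matrix(rowSums(matrix(a * a, d[1L] * d[2L], d[3L])), d[1L], d[2L])
  xn <- sqrt(.boxSumZero(sq, (N - 1L) %/% 2L))
  gn * xn
}

## Sum over the (2r+1) x (2r+1) neighbourhood of each pixel with zero
## padding outside the map (the im2col patch-norm accumulator).
.boxSumZero <- function(m, r) {
  if (r == 0L) return(m)
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (dy in -r:r) for (dx in -r:r) {
    ys <- max(1L, 1L - dy):min(H, H - dy)
    xs <- max(1L, 1L - dx):min(W, W - dx)
    out[ys, xs] <- out[ys, xs] + m[ys + dy, xs + dx]
  }
  out
}

## Center-aligned separable bilinear interpolation matrix from n input to
## m output samples: output pixel centers are mapped into the input grid
## with no corner alignment, border samples clamped.
.bilinearMatrix <- function(nOut, nIn) {
  A <- matrix(0, nOut, nIn)
  src <- (seq_len(nOut) - 0.5) * nIn / nOut - 0.5
  i0 <- floor(src)
  w <- src - i0
  i0c <- pmin(pmax(i0, 0), nIn - 1) + 1
  i1c <- pmin(pmax(i0 + 1, 0), nIn - 1) + 1
  for (i in seq_len(nOut)) {
    A[i, i0c[i]] <- A[i, i0c[i]] + (1 - w[i])
    A[i, i1c[i]] <- A[i, i1c[i]] + w[i]
  }
  A
}

.upsampleBilinear <- function(m, outH, outW) {
  if (nrow(m) == outH && ncol(m) == outW) return(m)
  R <- .bilinearMatrix(outH, nrow(m))
  C <- .bilinearMatrix(outW, ncol(m))
  R %*% m %*% t(C)
}

#' Turn a spatial contribution into an input-resolution saliency map
#'
#' Bilinear upsampling (output samples at cell centers, no corner
#' alignment) of a layer-resolution contribution map to the input image
#' size. Non-negativity is preserved; interpolation of a constant map is
#' that constant.
#'
#' @param contribution non-negative numeric matrix at layer resolution.
#' @param targetShape integer \code{(H, W)} of the input image.
#' @param method,vil,layers,smoothed provenance metadata.
#' @return a \linkS4class{SaliencyMap}.
#' @export
toSaliency <- function(contribution, targetShape, method = "normgrad",
                       vil = NULL, layers = character(),
                       smoothed = FALSE) {
  if (any(!is.finite(contribution))) stop("non-finite contribution values")
  if (nrow(contribution) > targetShape[1L] ||
      ncol(contribution) > targetShape[2L])
    stop("target shape must be >= contribution shape")
  v <- .upsampleBilinear(contribution, targetShape[1L], targetShape[2L])
  v[v < 0] <- 0  # guards rounding dust; bilinear weights are in [0,1]
  new("SaliencyMap", values = v, method = method, vil = vil,
      layers = as.character(layers), smoothed = smoothed)
}

## Min-max normalisation to [0,1]; an all-constant map carries no
## localization evidence and maps to all-zero.
.minMaxNorm <- function(m) {
  lo <- min(m); hi <- max(m)
  if (hi - lo <= 0) return(matrix(0, nrow(m), ncol(m)))
  (m - lo) / (hi - lo)
}

#' Combine per-layer saliency maps by pixelwise geometric mean
#'
#' The multi-layer NormGrad aggregation: each map is min-max normalised
#' to \eqn{[0,1]} (so layers of incomparable scales contribute equally),
#' a small \code{eps} is added so exact zeros cannot annihilate the
#' product, and the pixelwise geometric mean
#' \eqn{(\prod_j m_j)^{1/J}} is returned. With a single map this is the
#' normalised map itself; the operation is invariant to the order of the
#' inputs.
#'
#' @param maps list of \linkS4class{SaliencyMap} objects sharing shape and
#'   virtual-identity-layer kind.
#' @param eps additive floor applied after normalisation.
#' @return a combined \linkS4class{SaliencyMap}; \code{layers} is the
#'   union of the input layers.
#' @export
combineMulti <- function(maps, eps = 1e-12) {
  if (!length(maps)) stop("need at least one map")
  stopifnot(all(vapply(maps, is, TRUE, "SaliencyMap")))
  dims <- lapply(maps, function(m) dim(m@values))
  if (!all(vapply(dims, identical, TRUE, dims[[1L]])))
    stop("maps must share shape")
  vils <- lapply(maps, slot, "vil")
  key <- vapply(vils, function(v)
    if (is.null(v)) "none" else paste(v@kind, v@N), "")
  if (length(unique(key)) != 1L)
    stop("maps must share the virtual identity layer kind")
  J <- length(maps)
  logSum <- 0
  for (m in maps) logSum <- logSum + log(.minMaxNorm(m@values) + eps)
  new("SaliencyMap", values = exp(logSum / J),
      method = if (J > 1L) paste0(maps[[1L]]@method, "_multi")
               else maps[[1L]]@method,
      vil = vils[[1L]],
      layers = unique(unlist(lapply(maps, slot, "layers"))),
      smoothed = FALSE)
}

## One forward + one backward, captures at several layers at once.
.captureAll <- function(model, image, layerIds, targetClass,
                        inputId = "input") {
  targetClass <- as.integer(targetClass)
  if (targetClass < 0L || targetClass >= model@numClasses)
    stop("targetClass out of range")
  x <- .coerceImage(model, image)
  fw <- .netForward(model@layers, x)
  bw <- .netBackward(model@layers, fw, targetClass)
  lapply(layerIds, function(id) {
    at <- .layerIndex(model, id)
    acts <- fw$caches[[at]]$out
    new("LayerCapture", layerId = id, activations = acts,
        gradients = array(bw$dacts[[at]], dim = dim(acts)),
        targetClass = targetClass, inputId = inputId)
  })
}

.vilContribution <- function(capture, vil) {
  if (vil@kind == "scaling") contributionScaling(capture)
  else contributionConv(capture, vil@N)
}

#' Single-layer NormGrad saliency map
#'
#' Captures activations and loss gradients at the named layer, computes
#' the virtual-identity-layer spatial contribution, and upsamples it to
#' input resolution. Deterministic for a fixed model and input.
#'
#' @inheritParams captureLayer
#' @param vil a \linkS4class{VILSpec}; default scaling.
#' @return a \linkS4class{SaliencyMap}.
#' @examples
#' m <- buildClassifier("toy_a", seed = 1)
#' img <- matrix(runif(64 * 64), 64, 64)
#' sal <- normGrad(m, img, "conv4.2", targetClass = 1)
#' argmaxRC(sal)
#' @export
normGrad <- function(model, image, layerId = penultimateLayer(model),
                     targetClass = 1L, vil = vilSpec("scaling")) {
  validObject(vil)
  cap <- .captureAll(model, image, layerId, targetClass)[[1L]]
  toSaliency(.vilContribution(cap, vil), model@inputShape[2:3],
             method = "normgrad", vil = vil, layers = layerId)
}

#' Multi-layer NormGrad saliency map
#'
#' Computes per-layer NormGrad maps with identical virtual identity
#' layers at each of \code{layerIds} (default: the architecture's layer
#' preset) from a single forward/backward pass and combines them with
#' \code{\link{combineMulti}}.
#'
#' @inheritParams normGrad
#' @param layerIds character vector of named layers (J >= 1).
#' @return a \linkS4class{SaliencyMap}.
#' @export
normGradMulti <- function(model, image, layerIds = layerPreset(model),
                          targetClass = 1L, vil = vilSpec("scaling")) {
  validObject(vil)
  if (!length(layerIds)) stop("layerIds must be non-empty")
  caps <- .captureAll(model, image, layerIds, targetClass)
  maps <- lapply(caps, function(cp)
    toSaliency(.vilContribution(cp, vil), model@inputShape[2:3],
               method = "normgrad", vil = vil, layers = cp@layerId))
  combineMulti(maps)
}
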