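#' Train a fixture classifier with momentum SGD
#'
#' Per-sample stochastic gradient descent with momentum on the
#' cross-entropy loss, with a fresh shuffle of the training split each
#' epoch. All randomness (shuffling) flows from \code{seed}, so two runs
#' with the same seed produce bit-identical final weights. With
#' \code{epochs = 0} the model is returned untouched.
#'
#' @param model a \linkS4class{ToyClassifier}.
#' @param dataset a \linkS4class{SyntheticDataset} (train/val splits are
#'   used) or a list with elements \code{train} and \code{val} of
#'   \linkS4class{AnnotatedImage}s.
#' @param epochs number of passes over the training split.
#' @param learningRate SGD step size.
#' @param momentum momentum coefficient.
#' @param seed shuffle seed.
#' @param metrics evaluate train/val accuracy after every epoch (adds
#'   forward passes; disable for large repeated-trial runs).
#' @param clipNorm clip the global parameter-gradient norm of each step
#'   to this value (single-sample steps occasionally explode late in
#'   training otherwise); \code{Inf} disables clipping.
#' @return list with elements \code{model} (the trained
#'   \linkS4class{ToyClassifier}) and \code{metrics} (data.frame with
#'   per-epoch \code{train_acc}, \code{val_acc}, \code{train_loss}).
#' @export
trainFixture <- function(model, dataset, epochs = 5L, learningRate = 0.003,
                         momentum = 0.9, seed = 1L, metrics = TRUE,
                         clipNorm = 5) {
  train <- if (is(dataset, "SyntheticDataset")) dataset@train
           else dataset$train
  val <- if (is(dataset, "SyntheticDataset")) dataset@val else dataset$val
  if (!length(train)) stop("empty training split")
  layers <- model@layers
  vel <- lapply(layers, function(l)
    if (l$type %in% c("conv", "dwconv", "fc"))
      list(W = l$W * 0, b = l$b * 0))
  xs <- lapply(train, function(im) .coerceImage(model, im@pixels))
  ys <- vapply(train, function(im) im@label, 0L)
  metricsTab <- data.frame(epoch = integer(), train_acc = numeric(),
                           val_acc = numeric(), train_loss = numeric())
  if (epochs >= 1L) .withSeed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample(length(xs))
      lossSum <- 0
      for (i in ord) {
        fw <- .netForward(layers, xs[[i]])
        loss <- .crossEntropy(fw$logits, ys[i])
        if (!is.finite(loss))
          stop("training diverged (non-finite loss) at epoch ", ep)
        lossSum <- lossSum + loss
        bw <- .netBackward(layers, fw, ys[i], wantParams = TRUE)
        if (is.finite(clipNorm)) {
          gn <- sqrt(sum(vapply(bw$pgrads, function(g)
            if (is.null(g)) 0 else sum(g$dW^2) + sum(g$db^2), 0)))
          if (gn > clipNorm)
            bw$pgrads <- lapply(bw$pgrads, function(g)
              if (is.null(g)) NULL
              else list(dW = g$dW * (clipNorm / gn),
                        db = g$db * (clipNorm / gn)))
        }
        for (j in seq_along(layers)) {
          g <- bw$pgrads[[j]]
          if (is.null(g)) next
          vel[[j]]$W <- momentum * vel[[j]]$W - learningRate * g$dW
          vel[[j]]$b <- momentum * vel[[j]]$b - learningRate * g$db
          layers[[j]]$W <- layers[[j]]$W + vel[[j]]$W
          layers[[j]]$b <- layers[[j]]$b + vel[[j]]$b
        }
      }
      if (metrics) {
        tmp <- initialize(model, layers = layers)
        metricsTab[ep, ] <- list(ep, .splitAccuracy(tmp, train),
                                 .splitAccuracy(tmp, val),
                                 lossSum / length(xs))
      } else {
        metricsTab[ep, ] <- list(ep, NA_real_, NA_real_,
                                 lossSum / length(xs))
      }
    }
  })
  list(model = initialize(model, layers = layers), metrics = metricsTab)
}

.splitAccuracy <- function(model, images) {
  if (!length(images)) return(NA_real_)
  ok <- vapply(images, function(im) {
    p <- classifierLogits(model, im@pixels)
    (which.max(p) - 1L) == im@label
  }, TRUE)
  mean(ok)
}

#' Classification accuracy on a dataset split
#'
#' @param model a \linkS4class{ToyClassifier}.
#' @param images list of \linkS4class{AnnotatedImage}s.
#' @return fraction of correctly predicted labels.
#' @export
classificationAccuracy <- function(model, images) .splitAccuracy(model, images)
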