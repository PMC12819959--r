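#' Row-major argmax of a saliency matrix
#'
#' Returns the 0-based \code{(row, col)} of the maximum value; ties are
#' broken by the first maximum in row-major scan order (smallest row,
#' then smallest column). Deterministic on degenerate (e.g. constant)
#' maps.
#'
#' @param values numeric matrix.
#' @return integer vector \code{c(row, col)}, 0-based.
#' @export
saliencyArgmax <- function(values) {
  idx <- which(values == max(values))
  r <- (idx - 1L) %% nrow(values)
  cc <- (idx - 1L) %/% nrow(values)
  o <- order(r, cc)[1L]
  c(row = r[o], col = cc[o])
}

## Reflect (half-sample symmetric) 1-D Gaussian convolution indices:
## position i outside [1, n] folds back as (d c b a | a b c d).
.reflectIndex <- function(i, n) {
  period <- 2L * n
  i <- (i - 1L) %% period
  i <- ifelse(i < 0L, i + period, i)
  ifelse(i < n, i + 1L, period - i)
}

.gaussKernel <- function(sigma) {
  r <- as.integer(ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

.gaussSmooth <- function(m, sigma) {
  if (sigma == 0) return(m)
  k <- .gaussKernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  tmp <- matrix(0, H, W)
  for (j in -r:r)
    tmp <- tmp + k[j + r + 1L] * m[.reflectIndex(seq_len(H) + j, H), ,
                                   drop = FALSE]
  out <- matrix(0, H, W)
  for (j in -r:r)
    out <- out + k[j + r + 1L] * tmp[, .reflectIndex(seq_len(W) + j, W),
                                     drop = FALSE]
  out
}

#' @rdname smoothMap
#' @export
setMethod("smoothMap", "SaliencyMap", function(map, sigma = 1.0) {
  if (sigma < 0) stop("sigma must be >= 0")
  initialize(map, values = .gaussSmooth(map@values, sigma),
             smoothed = map@smoothed || sigma > 0)
})

#' Pointing Game hit decision for one saliency map
#'
#' The map scores a hit if its maximum (row-major tie-break) lies in any
#' ground-truth box dilated by \code{tau} pixels on all four sides
#' (clipped to the image). Images without boxes cannot be scored and
#' raise a condition; exclude them upstream.
#'
#' @param map a \linkS4class{SaliencyMap} at image resolution.
#' @param boxes data.frame with 0-based half-open columns
#'   \code{x_min, y_min, x_max, y_max}.
#' @param tau tolerance in pixels (default 15).
#' @return list with elements \code{hit} (logical) and \code{argmax}
#'   (0-based \code{c(row, col)}).
#' @export
pointingGameHit <- function(map, boxes, tau = 15L) {
  v <- if (is(map, "SaliencyMap")) map@values else map
  if (is.null(boxes) || nrow(boxes) == 0L)
    stop("image has no ground-truth boxes; excluded from scoring")
  am <- saliencyArgmax(v)
  H <- nrow(v); W <- ncol(v)
  x0 <- pmax(boxes$x_min - tau, 0L)
  x1 <- pmin(boxes$x_max + tau, W)
  y0 <- pmax(boxes$y_min - tau, 0L)
  y1 <- pmin(boxes$y_max + tau, H)
  hit <- any(am["col"] >= x0 & am["col"] < x1 &
             am["row"] >= y0 & am["row"] < y1)
  list(hit = hit, argmax = am)
}

#' Aggregate hit/miss decisions into a Pointing Game accuracy
#'
#' @param decisions logical vector (or list of \code{pointingGameHit}
#'   results) of per-image hits.
#' @param tau the tolerance the decisions were taken at (metadata).
#' @param perImage optional data.frame of per-image records.
#' @return a \linkS4class{PointingGameResult} with
#'   \eqn{A = T/(T+F)}.
#' @export
pointingGameAccuracy <- function(decisions, tau = 15L,
                                 perImage = data.frame()) {
  if (is.list(decisions))
    decisions <- vapply(decisions, function(d) isTRUE(d$hit), TRUE)
  if (!length(decisions)) stop("no decisions to aggregate")
  T_ <- sum(decisions)
  F_ <- sum(!decisions)
  new("PointingGameResult", hits = as.integer(T_), misses = as.integer(F_),
      tau = as.integer(tau), perImage = perImage)
}

#' Mean and standard deviation of repeated-trial accuracies
#'
#' Arithmetic mean and sample (n-1) standard deviation of the Pointing
#' Game accuracies across independently trained models; the standard
#' deviation is 0 when only one trial is available.
#'
#' @param trials a \linkS4class{TrialAccuracySet} or numeric vector.
#' @return named numeric \code{c(mean, std)}.
#' @export
repeatedAccuracy <- function(trials) {
  a <- if (is(trials, "TrialAccuracySet")) trials@accuracies else trials
  if (!length(a)) stop("empty trial set")
  s <- if (length(a) > 1L) stats::sd(a) else 0
  c(mean = mean(a), std = s)
}

#' @rdname domConsistency
#' @export
setMethod("domConsistency", signature("TrialAccuracySet", "TrialAccuracySet"),
          function(a, b) {
  domConsistency(a@accuracies, b@accuracies)
})

#' @rdname domConsistency
#' @export
setMethod("domConsistency", signature("numeric", "numeric"), function(a, b) {
  if (!length(a) || !length(b)) stop("empty accuracy set")
  ma <- mean(a); mb <- mean(b)
  new("DoMResult", meanA = ma, meanB = mb, dom = abs(ma - mb))
})
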