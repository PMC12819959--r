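#' Construct a synthetic benchmark specification
#'
#' Desk-scale stand-ins for the two localized-quality-defect settings:
#' chest-X-ray-like frames with zero or more high-contrast foreign
#' objects, and cardiac-MR-like frames with zero or one small soft-edged
#' blob near the image center (the outflow-tract regime). Backgrounds are
#' drawn from one shared process for positives and negatives — a vertical
#' intensity gradient, large-scale blurred noise, anatomy-like distractor
#' bands and a lateral vignette, plus pixel noise — so a classifier can
#' only discriminate through the stamped defects.
#'
#' @param mode \code{"foreign_object"} or \code{"lvot"}.
#' @param nImages total number of images.
#' @param imageSize integer \code{(H, W)}; default 64 x 64.
#' @param positiveFraction fraction of defect-carrying images.
#' @param objectsPerPositive integer range \code{(lo, hi)} of objects per
#'   positive image (foreign_object mode).
#' @param objectSizePx integer range of object diameters, pixels.
#' @param contrast peak defect intensity above the local background, in
#'   \eqn{[0,1]} units.
#' @param noiseSd pixel noise standard deviation.
#' @param centerJitterPx maximal blob offset from the image center
#'   (lvot mode).
#' @param seed generator seed.
#' @return a \linkS4class{SyntheticSpec}.
#' @export
syntheticSpec <- function(mode = c("foreign_object", "lvot"),
                          nImages = 100L, imageSize = c(64L, 64L),
                          positiveFraction = 0.5,
                          objectsPerPositive = c(1L, 2L),
                          objectSizePx = c(6L, 12L), contrast = 0.6,
                          noiseSd = 0.05, centerJitterPx = 6L, seed = 1L) {
  mode <- match.arg(mode)
  new("SyntheticSpec", mode = mode, nImages = as.integer(nImages),
      imageSize = as.integer(imageSize),
      positiveFraction = positiveFraction,
      objectsPerPositive = as.integer(objectsPerPositive),
      objectSizePx = as.integer(objectSizePx), contrast = contrast,
      noiseSd = noiseSd, centerJitterPx = as.integer(centerJitterPx),
      seed = as.integer(seed))
}

## Shared background process for positives and negatives alike: vertical
## intensity gradient, large-scale blurred noise, rib-like distractor
## bands and a lateral vignette (the anatomy-like structure that makes
## randomised-model saliency non-trivial), plus pixel noise. Band peaks
## are comparable in brightness to a stamped defect, but elongated rather
## than compact, so the defect class is separable by shape and local
## peak, not by the mere presence of contrast.
.renderBackground <- function(spec) {
  H <- spec@imageSize[1L]; W <- spec@imageSize[2L]
  y <- matrix(seq_len(H) / H, H, W)
  x <- matrix(rep(seq_len(W) / W, each = H), H, W)
  lowfreq <- .gaussSmooth(matrix(rnorm(H * W), H, W), sigma = H / 8)
  rng <- range(lowfreq)
  lowfreq <- (lowfreq - rng[1L]) / max(rng[2L] - rng[1L], 1e-12)
  bg <- 0.10 + 0.10 * y + 0.08 * lowfreq
  nBands <- sample(3:5, 1L)
  for (b in seq_len(nBands)) {
    yc <- runif(1L, 0.1, 0.9) * H
    amp <- runif(1L, 2, 6)
    phase <- runif(1L, 0, 2 * pi)
    strength <- runif(1L, 0.3, 0.6)
    center <- yc + amp * sin(pi * (seq_len(W) / W) + phase)
    dy2 <- (matrix(seq_len(H), H, W) -
              matrix(rep(center, each = H), H, W))^2
    bg <- bg + strength * exp(-dy2 / (2 * 1.8^2))
  }
  ## lateral vignette (bright flanks, as in a lung field)
  bg <- bg + 0.15 * (2 * abs(x - 0.5))^2
  bg <- bg + rnorm(H * W, sd = spec@noiseSd)
  pmin(pmax(bg, 0.02), 0.92)
}

## Binary profile of one foreign object; returns the full-image profile
## matrix in [0,1] (1 inside the object).
.stampForeignObject <- function(H, W, sizePx) {
  shape <- sample(c("disk", "bar", "ring"), 1L)
  d <- sizePx
  margin <- ceiling(d / 2) + 1L
  cy <- sample(seq(margin, H - margin), 1L)
  cx <- sample(seq(margin, W - margin), 1L)
  yy <- matrix(seq_len(H), H, W) - cy
  xx <- matrix(rep(seq_len(W), each = H), H, W) - cx
  r2 <- yy^2 + xx^2
  prof <- switch(shape,
    disk = (r2 <= (d / 2)^2) * 1,
    ring = (r2 <= (d / 2)^2 & r2 >= (d / 4)^2) * 1,
    bar = {
      horiz <- sample(c(TRUE, FALSE), 1L)
      wd <- max(2, round(d / 4))
      if (horiz) (abs(xx) <= d / 2 & abs(yy) <= wd / 2) * 1
      else (abs(yy) <= d / 2 & abs(xx) <= wd / 2) * 1
    })
  prof
}

## Soft-edged Gaussian blob near the image center (lvot regime).
.stampBlob <- function(H, W, sizePx, jitter) {
  cy <- round(H / 2) + sample(seq(-jitter, jitter), 1L)
  cx <- round(W / 2) + sample(seq(-jitter, jitter), 1L)
  sb <- sizePx / 4
  yy <- matrix(seq_len(H), H, W) - cy
  xx <- matrix(rep(seq_len(W), each = H), H, W) - cx
  prof <- exp(-(yy^2 + xx^2) / (2 * sb^2))
  prof[prof < 0.05] <- 0
  prof
}

.tightBox <- function(mask) {
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  data.frame(x_min = min(cols) - 1L, y_min = min(rows) - 1L,
             x_max = max(cols), y_max = max(rows))
}

## Render one image (assumes the RNG is already positioned); internal but
## reused by the generator invariant tests.
.renderImage <- function(spec, positive) {
  H <- spec@imageSize[1L]; W <- spec@imageSize[2L]
  bg <- .renderBackground(spec)
  img <- bg
  bx <- data.frame(x_min = integer(), y_min = integer(),
                   x_max = integer(), y_max = integer())
  if (positive) {
    nObj <- if (spec@mode == "foreign_object")
      sample(seq(spec@objectsPerPositive[1L], spec@objectsPerPositive[2L]),
             1L)
    else 1L
    for (k in seq_len(nObj)) {
      sizePx <- sample(seq(spec@objectSizePx[1L], spec@objectSizePx[2L]),
                       1L)
      prof <- if (spec@mode == "foreign_object")
        .stampForeignObject(H, W, sizePx)
      else .stampBlob(H, W, sizePx, spec@centerJitterPx)
      ## A defect occludes what lies beneath it: the background under the
      ## stamp is capped at 1 - contrast so the stamped peak always sits
      ## a full `contrast` above the pre-stamp field without clipping.
      sup <- prof > 0
      img[sup] <- pmin(img[sup], 1 - spec@contrast)
      img <- img + spec@contrast * prof
      bx <- rbind(bx, .tightBox(sup))
    }
    img <- pmin(img, 1)
  }
  list(pixels = img, boxes = bx, background = bg)
}

#' Generate a synthetic annotated dataset
#'
#' Renders \code{nImages} images (exactly
#' \code{round(nImages * positiveFraction)} positives), each with the
#' tightest axis-aligned bounding box of every stamped defect, and
#' partitions them into disjoint train/val/test splits. Fully
#' reproducible from \code{spec@seed}.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param splitFractions named numeric \code{c(train, val, test)} summing
#'   to 1.
#' @return a \linkS4class{SyntheticDataset}.
#' @examples
#' ds <- generateDataset(syntheticSpec(nImages = 10, seed = 3))
#' ds
#' @export
generateDataset <- function(spec,
                            splitFractions = c(train = 0.6, val = 0.2,
                                               test = 0.2)) {
  validObject(spec)
  n <- spec@nImages
  nPos <- round(n * spec@positiveFraction)
  labels <- c(rep(1L, nPos), rep(0L, n - nPos))
  images <- .withSeed(spec@seed, {
    labels <- sample(labels)  # interleave classes before splitting
    lapply(seq_len(n), function(i) {
      r <- .renderImage(spec, labels[i] == 1L)
      new("AnnotatedImage",
          inputId = sprintf("%s_%04d", spec@mode, i),
          pixels = r$pixels, label = labels[i], boxes = r$boxes)
    })
  })
  nTrain <- round(n * splitFractions[["train"]])
  nVal <- round(n * splitFractions[["val"]])
  idxTrain <- seq_len(nTrain)
  idxVal <- seq_len(nVal) + nTrain
  idxTest <- setdiff(seq_len(n), c(idxTrain, idxVal))
  new("SyntheticDataset", train = images[idxTrain], val = images[idxVal],
      test = images[idxTest], spec = spec)
}
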