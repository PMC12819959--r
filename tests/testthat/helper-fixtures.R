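## Shared fixtures and independent reference implementations (oracles).
## Oracles are written as naive loops / direct formulas, deliberately not
## sharing code with the package internals they check.

randomCapture <- function(H = 4L, W = 4L, K = 3L, seed = 1L,
                          layerId = "conv.0") {
  set.seed(seed)
  new("LayerCapture", layerId = layerId,
      activations = array(rnorm(H * W * K), dim = c(H, W, K)),
      gradients = array(rnorm(H * W * K), dim = c(H, W, K)),
      targetClass = 1L, inputId = sprintf("cap%d", seed))
}

captureFrom <- function(acts, grads, layerId = "conv.0") {
  new("LayerCapture", layerId = layerId, activations = acts,
      gradients = grads, targetClass = 1L, inputId = "manual")
}

## scaling-VIL oracle: per-position loop, sqrt(sum_k (g * x)^2)
oracleScaling <- function(g, x) {
  d <- dim(g)
  out <- matrix(0, d[1L], d[2L])
  for (i in seq_len(d[1L])) for (j in seq_len(d[2L]))
    out[i, j] <- sqrt(sum((g[i, j, ] * x[i, j, ])^2))
  out
}

## conv-VIL oracle: materialise every outer product g_u %o% patch_u and
## take its Frobenius norm (zero padding, stride 1).
oracleConv <- function(g, x, N) {
  d <- dim(x)
  r <- (N - 1L) %/% 2L
  out <- matrix(0, d[1L], d[2L])
  for (i in seq_len(d[1L])) for (j in seq_len(d[2L])) {
    patch <- c()
    for (dy in -r:r) for (dx in -r:r) {
      yy <- i + dy; xx <- j + dx
      v <- if (yy >= 1L && yy <= d[1L] && xx >= 1L && xx <= d[2L])
        x[yy, xx, ] else rep(0, d[3L])
      patch <- c(patch, v)
    }
    op <- g[i, j, ] %o% patch
    out[i, j] <- sqrt(sum(op^2))
  }
  out
}

## direct center-aligned bilinear interpolation, scalar per output pixel
oracleBilinear <- function(m, outH, outW) {
  inH <- nrow(m); inW <- ncol(m)
  out <- matrix(0, outH, outW)
  for (i in seq_len(outH)) for (j in seq_len(outW)) {
    sy <- (i - 0.5) * inH / outH - 0.5
    sx <- (j - 0.5) * inW / outW - 0.5
    y0 <- floor(sy); x0 <- floor(sx)
    wy <- sy - y0; wx <- sx - x0
    cl <- function(v, n) min(max(v, 0), n - 1) + 1
    out[i, j] <-
      (1 - wy) * (1 - wx) * m[cl(y0, inH), cl(x0, inW)] +
      (1 - wy) * wx * m[cl(y0, inH), cl(x0 + 1, inW)] +
      wy * (1 - wx) * m[cl(y0 + 1, inH), cl(x0, inW)] +
      wy * wx * m[cl(y0 + 1, inH), cl(x0 + 1, inW)]
  }
  out
}

## direct (non-separable) Gaussian convolution with half-sample-symmetric
## reflection, kernel truncated at radius ceiling(4 * sigma)
oracleGaussSmooth <- function(m, sigma) {
  r <- as.integer(ceiling(4 * sigma))
  k1 <- exp(-((-r:r)^2) / (2 * sigma^2)); k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  H <- nrow(m); W <- ncol(m)
  refl <- function(i, n) {
    i <- (i - 1L) %% (2L * n)
    if (i < 0L) i <- i + 2L * n
    if (i < n) i + 1L else 2L * n - i
  }
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    s <- 0
    for (dy in -r:r) for (dx in -r:r)
      s <- s + k2[dy + r + 1L, dx + r + 1L] *
        m[refl(i + dy, H), refl(j + dx, W)]
    out[i, j] <- s
  }
  out
}

## linear-kernel MMD between 1-D samples, from the kernel-mean-embedding
## double sums (biased V-statistic form, which is exact for the mean map)
oracleLinearMMD <- function(a, b) {
  kaa <- mean(outer(a, a))
  kbb <- mean(outer(b, b))
  kab <- mean(outer(a, b))
  sqrt(max(kaa + kbb - 2 * kab, 0))
}

## a map whose unique maximum sits at 0-based (row, col)
deltaMap <- function(H, W, row, col, method = "test") {
  v <- matrix(0, H, W)
  v[row + 1L, col + 1L] <- 1
  new("SaliencyMap", values = v, method = method, vil = NULL,
      layers = character(), smoothed = FALSE)
}

box <- function(x_min, y_min, x_max, y_max) {
  data.frame(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max)
}

## small shared dataset/model fixtures (built once per test session)
tinySpec <- function(n = 24L, seed = 5L, mode = "foreign_object") {
  syntheticSpec(mode, nImages = n, imageSize = c(64L, 64L),
                positiveFraction = 0.5, contrast = 0.6, noiseSd = 0.05,
                seed = seed)
}
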