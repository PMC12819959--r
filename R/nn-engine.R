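## Minimal CNN engine: im2col convolution, depthwise-separable blocks,
## ReLU / global average pooling / fully-connected head, exact backward
## passes, He initialisation. All tensors are H x W x K arrays (channels
## last); everything is plain double arithmetic, so repeated evaluation on
## the same machine is bit-identical.

## Evaluate expr under a temporary RNG state; the caller's stream is
## untouched.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Deterministic child seeds (kept under 2^31 - 1, never 0).
.deriveSeed <- function(seed, ...) {
  k <- c(...)
  s <- as.double(seed) %% 2147483647
  for (x in k) s <- (s * 48271 + as.double(x) * 9973 + 1) %% 2147483647
  as.integer(max(1, s))
}

## im2col gather indices for a k x k convolution. Returns an integer
## matrix (k*k*inC) x (outH*outW); entries index into c(as.vector(x), 0),
## the extra slot standing for zero padding. Rows are ordered
## (ky fastest, then kx, then channel); columns enumerate output positions
## column-major (row index fastest), matching R array layout.
.im2colIndex <- function(inH, inW, inC, k, stride, pad) {
  outH <- (inH + 2L * pad - k) %/% stride + 1L
  outW <- (inW + 2L * pad - k) %/% stride + 1L
  oy <- rep(seq_len(outH), times = outW)
  ox <- rep(seq_len(outW), each = outH)
  top <- (oy - 1L) * stride - pad
  left <- (ox - 1L) * stride - pad
  npix <- inH * inW * inC
  idx <- matrix(0L, nrow = k * k * inC, ncol = outH * outW)
  r <- 0L
  for (ch in seq_len(inC)) for (kx in seq_len(k)) for (ky in seq_len(k)) {
    r <- r + 1L
    iy <- top + ky
    ix <- left + kx
    valid <- iy >= 1L & iy <= inH & ix >= 1L & ix <= inW
    lin <- iy + (ix - 1L) * inH + (ch - 1L) * (inH * inW)
    lin[!valid] <- npix + 1L
    idx[r, ] <- lin
  }
  list(idx = idx, outH = outH, outW = outW, npix = npix)
}

.convLayer <- function(id, inC, outC, k, stride, pad, inH, inW) {
  geo <- .im2colIndex(inH, inW, inC, k, stride, pad)
  list(type = "conv", id = id, inC = inC, outC = outC, k = k,
       stride = stride, pad = pad, inH = inH, inW = inW,
       outH = geo$outH, outW = geo$outW, geo = geo,
       W = matrix(0, outC, k * k * inC), b = numeric(outC))
}

## Depthwise k x k convolution: one filter per channel. Uses the
## single-channel gather pattern shifted per channel.
.dwLayer <- function(id, C, k, stride, pad, inH, inW) {
  geo <- .im2colIndex(inH, inW, 1L, k, stride, pad)
  list(type = "dwconv", id = id, inC = C, outC = C, k = k,
       stride = stride, pad = pad, inH = inH, inW = inW,
       outH = geo$outH, outW = geo$outW, geo = geo,
       W = matrix(0, C, k * k), b = numeric(C))
}

.reluLayer <- function(id) list(type = "relu", id = id)
.gapLayer <- function(id = NULL) list(type = "gap", id = id)
.fcLayer <- function(id, inN, outN)
  list(type = "fc", id = id, inN = inN, outN = outN,
       W = matrix(0, outN, inN), b = numeric(outN))

.heFanIn <- function(layer) {
  switch(layer$type,
         conv = layer$k * layer$k * layer$inC,
         dwconv = layer$k * layer$k,
         fc = layer$inN,
         stop("layer has no parameters"))
}

## He initialisation, fan-in normal variant; biases zeroed. Draw order is
## fixed (layer order, column-major within each weight matrix) so a seed
## fully determines the parameters.
.heInitLayer <- function(layer) {
  if (!layer$type %in% c("conv", "dwconv", "fc")) return(layer)
  sd <- sqrt(2 / .heFanIn(layer))
  layer$W[] <- rnorm(length(layer$W), sd = sd)
  layer$b[] <- 0
  layer
}

.convForward <- function(layer, x) {
  cols <- matrix(c(x, 0)[layer$geo$idx], nrow = nrow(layer$geo$idx))
  outMat <- layer$W %*% cols + layer$b
  list(out = array(t(outMat), dim = c(layer$outH, layer$outW, layer$outC)),
       cols = cols)
}

.convBackward <- function(layer, cache, dout, wantParams = FALSE) {
  L <- layer$outH * layer$outW
  doutMat <- t(matrix(dout, nrow = L, ncol = layer$outC))
  dcols <- crossprod(layer$W, doutMat)
  acc <- rowsum(as.vector(dcols), group = as.vector(layer$geo$idx))
  dxAug <- numeric(layer$geo$npix + 1L)
  dxAug[as.integer(rownames(acc))] <- acc
  dx <- array(dxAug[seq_len(layer$geo$npix)],
              dim = c(layer$inH, layer$inW, layer$inC))
  grads <- NULL
  if (wantParams)
    grads <- list(dW = doutMat %*% t(cache$cols), db = rowSums(doutMat))
  list(dx = dx, grads = grads)
}

.dwForward <- function(layer, x) {
  C <- layer$inC
  out <- array(0, dim = c(layer$outH, layer$outW, C))
  cols <- vector("list", C)
  idx <- layer$geo$idx
  for (ch in seq_len(C)) {
    xc <- c(x[, , ch], 0)
    cc <- matrix(xc[idx], nrow = nrow(idx))
    cols[[ch]] <- cc
    out[, , ch] <- layer$W[ch, ] %*% cc + layer$b[ch]
  }
  list(out = out, cols = cols)
}

.dwBackward <- function(layer, cache, dout, wantParams = FALSE) {
  C <- layer$inC
  dx <- array(0, dim = c(layer$inH, layer$inW, C))
  dW <- if (wantParams) matrix(0, C, layer$k^2) else NULL
  db <- if (wantParams) numeric(C) else NULL
  idxv <- as.vector(layer$geo$idx)
  npix <- layer$geo$npix
  for (ch in seq_len(C)) {
    dc <- as.vector(dout[, , ch])
    dcols <- outer(layer$W[ch, ], dc)
    acc <- rowsum(as.vector(dcols), group = idxv)
    dxAug <- numeric(npix + 1L)
    dxAug[as.integer(rownames(acc))] <- acc
    dx[, , ch] <- dxAug[seq_len(npix)]
    if (wantParams) {
      dW[ch, ] <- cache$cols[[ch]] %*% dc
      db[ch] <- sum(dc)
    }
  }
  list(dx = dx, grads = if (wantParams) list(dW = dW, db = db))
}

## Forward pass; returns logits plus per-layer caches (inputs for the
## backward pass and outputs for capture). x is an H x W x C array.
.netForward <- function(layers, x) {
  caches <- vector("list", length(layers))
  cur <- x
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv") {
      fw <- .convForward(l, cur)
      caches[[i]] <- list(cols = fw$cols, out = fw$out)
      cur <- fw$out
    } else if (l$type == "dwconv") {
      fw <- .dwForward(l, cur)
      caches[[i]] <- list(cols = fw$cols, out = fw$out)
      cur <- fw$out
    } else if (l$type == "relu") {
      out <- pmax(cur, 0)
      caches[[i]] <- list(mask = cur > 0, out = out)
      cur <- out
    } else if (l$type == "gap") {
      d <- dim(cur)
      out <- colMeans(matrix(cur, d[1L] * d[2L], d[3L]))
      caches[[i]] <- list(inDim = d, out = out)
      cur <- out
    } else if (l$type == "fc") {
      out <- as.vector(l$W %*% cur + l$b)
      caches[[i]] <- list(x = cur, out = out)
      cur <- out
    }
  }
  list(logits = cur, caches = caches)
}

.softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

## Backward pass of the cross-entropy loss against targetClass (0-based).
## Returns gradients w.r.t. every layer OUTPUT (list parallel to layers),
## the input gradient, and (optionally) parameter gradients.
## guided = TRUE replaces every ReLU backward rule by the guided-backprop
## rule: pass the upstream gradient only where the forward input was
## positive AND the upstream gradient is positive.
.netBackward <- function(layers, fw, targetClass, guided = FALSE,
                         wantParams = FALSE) {
  n <- length(layers)
  p <- .softmax(fw$logits)
  d <- p
  d[targetClass + 1L] <- d[targetClass + 1L] - 1
  dacts <- vector("list", n)
  pgrads <- if (wantParams) vector("list", n)
  for (i in rev(seq_len(n))) {
    l <- layers[[i]]
    dacts[[i]] <- d
    cache <- fw$caches[[i]]
    if (l$type == "fc") {
      if (wantParams)
        pgrads[[i]] <- list(dW = d %o% cache$x, db = d)
      d <- as.vector(crossprod(l$W, d))
    } else if (l$type == "gap") {
      dd <- cache$inDim
      d <- array(rep(d / (dd[1L] * dd[2L]), each = dd[1L] * dd[2L]),
                 dim = dd)
    } else if (l$type == "relu") {
      d <- if (guided) d * cache$mask * (d > 0) else d * cache$mask
    } else if (l$type == "conv") {
      bw <- .convBackward(l, cache, d, wantParams)
      if (wantParams) pgrads[[i]] <- bw$grads
      d <- bw$dx
    } else if (l$type == "dwconv") {
      bw <- .dwBackward(l, cache, d, wantParams)
      if (wantParams) pgrads[[i]] <- bw$grads
      d <- bw$dx
    }
  }
  list(dacts = dacts, dinput = d, pgrads = pgrads, probs = p)
}

## Continue the forward pass from the output of a named layer; used by the
## finite-difference oracles in the test suite.
.netForwardFrom <- function(layers, layerId, acts) {
  ids <- vapply(layers, function(l) l$id %||% NA_character_, "")
  at <- match(layerId, ids)
  stopifnot(!is.na(at))
  cur <- acts
  if (at < length(layers)) for (i in (at + 1L):length(layers)) {
    l <- layers[[i]]
    cur <- switch(l$type,
                  conv = .convForward(l, cur)$out,
                  dwconv = .dwForward(l, cur)$out,
                  relu = pmax(cur, 0),
                  gap = {
                    d <- dim(cur)
                    colMeans(matrix(cur, d[1L] * d[2L], d[3L]))
                  },
                  fc = as.vector(l$W %*% cur + l$b))
  }
  cur
}

.crossEntropy <- function(logits, targetClass) {
  z <- logits - max(logits)
  -(z[targetClass + 1L] - log(sum(exp(z))))
}
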