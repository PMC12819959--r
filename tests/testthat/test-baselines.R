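## A hand-wired 2x2 single-conv classifier whose backward pass can be
## followed on paper: conv 1x1 (two channels), ReLU, GAP, FC.
manualNet <- function(convW = c(0.5, 0.8), convB = 0.1,
                      fcW = rbind(c(1, 1), c(0, 0))) {
  cv <- normgradiqa:::.convLayer(NULL, 1L, 2L, 1L, 1L, 0L, 2L, 2L)
  cv$W <- matrix(convW, 2L, 1L)
  cv$b <- rep(convB, 2L)
  fc <- normgradiqa:::.fcLayer(NULL, 2L, 2L)
  fc$W <- fcW
  layers <- list(cv, normgradiqa:::.reluLayer("conv1.0"),
                 normgradiqa:::.gapLayer(), fc)
  new("ToyClassifier", architectureId = "toy_a", layers = layers,
      namedLayers = "conv1.0", numClasses = 2L,
      inputShape = c(1L, 2L, 2L), seed = 0L)
}

test_that("input x gradient matches a finite-difference oracle", {
  m <- buildClassifier("toy_a", inputShape = c(1L, 16L, 16L), seed = 6L)
  set.seed(3)
  img <- matrix(runif(256, 0.2, 0.9), 16, 16)
  map <- saliencyValues(inputXGrad(m, img, 1L))
  lossOf <- function(im)
    normgradiqa:::.crossEntropy(classifierLogits(m, im), 1L)
  eps <- 1e-5
  for (k in sample(256L, 20L)) {
    ip <- img; ip[k] <- ip[k] + eps
    im_ <- img; im_[k] <- im_[k] - eps
    num <- (lossOf(ip) - lossOf(im_)) / (2 * eps)
    expect_lt(abs(abs(img[k] * num) - map[k]),
              1e-3 * max(abs(img[k] * num), 1e-4))
  }

  ## multiplication by the input: zero image gives a zero map
  expect_equal(saliencyValues(inputXGrad(m, matrix(0, 16, 16), 1L)),
               matrix(0, 16, 16))
})

test_that("guided backprop applies both ReLU masks", {
  ## pixels above mid-gray, so the centred model input stays positive
  img <- matrix(c(0.6, 0.8, 0.7, 0.9), 2, 2)

  ## all forward inputs and upstream gradients positive: the guard never
  ## fires and the guided gradient equals the vanilla gradient
  m <- manualNet(fcW = rbind(c(1, 1), c(0, 0)))
  van <- normgradiqa:::.inputSpaceMap(m, img, 1L, guided = FALSE)
  gbp <- saliencyValues(guidedBackprop(m, img, 1L))
  expect_equal(gbp, abs(van$dinput[, , 1L]), tolerance = 1e-12)

  ## forward input below zero blocks everything regardless of upstream
  mneg <- manualNet(convW = c(-0.5, -0.8), convB = -0.1)
  expect_equal(saliencyValues(guidedBackprop(mneg, img, 1L)),
               matrix(0, 2, 2))

  ## one negative upstream gradient channel: hand-computed chain rule
  mmix <- manualNet(fcW = rbind(c(1, -1), c(0, 0)))
  z <- classifierLogits(mmix, img)
  p1 <- exp(z[1L]) / sum(exp(z))
  ## target class 1: upstream into GAP channels is (p1, -p1); guided
  ## drops the negative channel, leaving d/draw = 2 * (p1/4) * w1
  expected <- matrix(abs(2 * (p1 / 4) * 0.5), 2, 2)
  expect_equal(saliencyValues(guidedBackprop(mmix, img, 1L)), expected,
               tolerance = 1e-10)

  noRelu <- new("ToyClassifier", architectureId = "toy_a",
                layers = list(normgradiqa:::.gapLayer("g"),
                              normgradiqa:::.fcLayer(NULL, 1L, 2L)),
                namedLayers = "g", numClasses = 2L,
                inputShape = c(1L, 2L, 2L), seed = 0L)
  expect_error(guidedBackprop(noRelu, img, 1L), "ReLU")
})

test_that("grad-CAM equals the explicit channel-weighting loop", {
  m <- buildClassifier("toy_a", seed = 12L)
  set.seed(9)
  img <- matrix(runif(64 * 64), 64, 64)
  for (id in c("conv3.0", "conv4.2")) {
    got <- saliencyValues(gradCAM(m, img, id, 1L))
    cap <- captureLayer(m, img, id, 1L)
    a <- activations(cap); g <- gradients(cap)
    d <- dim(a)
    cam <- matrix(0, d[1L], d[2L])
    for (k in seq_len(d[3L])) {
      alpha <- mean(g[, , k])
      cam <- cam + alpha * a[, , k]
    }
    cam[cam < 0] <- 0
    expect_lt(max(abs(got - oracleBilinear(cam, 64L, 64L))), 1e-6)
  }
})

test_that("guided grad-CAM is the exact pointwise product of its parts", {
  m <- buildClassifier("toy_a", seed = 13L)
  set.seed(10)
  img <- matrix(runif(64 * 64), 64, 64)
  gg <- saliencyValues(guidedGradCAM(m, img, "conv4.2", 1L))
  gc <- saliencyValues(gradCAM(m, img, "conv4.2", 1L))
  gb <- saliencyValues(guidedBackprop(m, img, 1L))
  expect_identical(gg, gc * gb)
})

test_that("all detectors return non-negative finite maps, deterministically", {
  m <- buildClassifier("toy_b", seed = 14L)
  set.seed(11)
  img <- matrix(runif(64 * 64), 64, 64)
  for (meth in saliencyMethods()) {
    s1 <- saliencyValues(computeSaliency(m, img, meth))
    expect_identical(dim(s1), c(64L, 64L))
    expect_true(all(is.finite(s1)) && all(s1 >= 0))
    s2 <- saliencyValues(computeSaliency(m, img, meth))
    expect_identical(s1, s2)
  }
  expect_error(computeSaliency(m, img, "rise"), "unknown saliency method")
})
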