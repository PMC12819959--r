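test_that("scaling contribution matches the per-position norm formula", {
  ## 1x1 single channel: |g * x| = |2 * 3| = 6
  cap <- captureFrom(array(3, c(1, 1, 1)), array(2, c(1, 1, 1)))
  expect_equal(contributionScaling(cap), matrix(6, 1, 1))

  ## zero gradients annihilate
  cap0 <- captureFrom(array(rnorm(12), c(2, 2, 3)), array(0, c(2, 2, 3)))
  expect_equal(contributionScaling(cap0), matrix(0, 2, 2))

  ## brute-force per-position loop oracle
  for (s in 1:5) {
    cp <- randomCapture(H = 4L, W = 4L, K = 3L, seed = s)
    expect_lt(max(abs(contributionScaling(cp) -
                        oracleScaling(gradients(cp), activations(cp)))),
              1e-6)
  }
})

test_that("conv contribution equals outer-product Frobenius norms", {
  ## N = 1, single channel reduces to |g| * |x|
  cap <- captureFrom(array(3, c(1, 1, 1)), array(2, c(1, 1, 1)))
  expect_equal(contributionConv(cap, 1L), matrix(6, 1, 1))

  ## zero activations: every patch norm vanishes
  capz <- captureFrom(array(0, c(3, 3, 2)), array(rnorm(18), c(3, 3, 2)))
  expect_equal(contributionConv(capz, 3L), matrix(0, 3, 3))

  ## explicit outer-product oracle, |g_u (x_{u,NxN})^T|_F = |g_u||x_u|
  cp <- randomCapture(H = 5L, W = 5L, K = 2L, seed = 7)
  expect_lt(max(abs(contributionConv(cp, 3L) -
                      oracleConv(gradients(cp), activations(cp), 3L))),
            1e-6)

  expect_error(contributionConv(cp, 2L), "odd")
})

test_that("conv contribution agrees with the oracle on many random captures", {
  for (s in 1:100) {
    H <- sample(2:6, 1L); W <- sample(2:6, 1L); K <- sample(1:4, 1L)
    N <- sample(c(1L, 3L), 1L)
    cp <- randomCapture(H, W, K, seed = 1000L + s)
    expect_lt(max(abs(contributionConv(cp, N) -
                        oracleConv(gradients(cp), activations(cp), N))),
              1e-6)
  }
})

test_that("conv N=1 equals the scaling map on single-channel captures", {
  for (s in 1:10) {
    cp <- randomCapture(H = 4L, W = 5L, K = 1L, seed = 50L + s)
    expect_lt(max(abs(contributionConv(cp, 1L) - contributionScaling(cp))),
              1e-6)
  }
})

test_that("upsampling is center-aligned bilinear and shape-safe", {
  m <- matrix(runif(16), 4, 4)
  same <- toSaliency(m, c(4L, 4L))
  expect_equal(saliencyValues(same), m)

  const <- toSaliency(matrix(0.7, 3, 3), c(12L, 12L))
  expect_equal(saliencyValues(const), matrix(0.7, 12, 12))

  m2 <- matrix(c(0, 0, 0, 1), 2, 2)
  up <- toSaliency(m2, c(4L, 4L))
  expect_lt(max(abs(saliencyValues(up) - oracleBilinear(m2, 4L, 4L))), 1e-6)

  m3 <- matrix(runif(30), 5, 6)
  up3 <- toSaliency(m3, c(17L, 13L))
  expect_lt(max(abs(saliencyValues(up3) - oracleBilinear(m3, 17L, 13L))),
            1e-6)
  expect_true(all(saliencyValues(up3) >= 0))

  expect_error(toSaliency(matrix(NaN, 2, 2), c(4L, 4L)), "non-finite")
  expect_error(toSaliency(matrix(1, 8, 8), c(4L, 4L)), ">=")
})

test_that("geometric-mean combination behaves per the aggregation rule", {
  mk <- function(v) new("SaliencyMap", values = v, method = "normgrad",
                        vil = vilSpec("scaling"), layers = "l1",
                        smoothed = FALSE)
  ## J = 1: the normalised map itself
  v <- matrix(runif(16), 4, 4)
  got <- combineMulti(list(mk(v)))
  expect_equal(saliencyValues(got),
               (v - min(v)) / (max(v) - min(v)) + 1e-12)

  ## idempotence on identical maps
  two <- combineMulti(list(mk(v), mk(v)))
  expect_equal(saliencyValues(two),
               (v - min(v)) / (max(v) - min(v)) + 1e-12,
               tolerance = 1e-9)

  ## closed form with zero-annihilation bounded by eps:
  ## normalised maps [[0,1]] and [[1,0]] -> sqrt((0+e)(1+e)) each pixel
  m1 <- mk(matrix(c(0.25, 1), 1, 2))
  m2 <- mk(matrix(c(1, 0.25), 1, 2))
  gm <- combineMulti(list(m1, m2))
  expect_equal(saliencyValues(gm),
               matrix(sqrt((0 + 1e-12) * (1 + 1e-12)), 1, 2),
               tolerance = 1e-6)

  ## order invariance
  v2 <- matrix(runif(16), 4, 4); v3 <- matrix(runif(16), 4, 4)
  ab <- combineMulti(list(mk(v), mk(v2), mk(v3)))
  ba <- combineMulti(list(mk(v3), mk(v), mk(v2)))
  expect_equal(saliencyValues(ab), saliencyValues(ba), tolerance = 1e-12)

  ## all-constant map normalises to zero evidence
  cz <- combineMulti(list(mk(matrix(2, 2, 2))))
  expect_equal(saliencyValues(cz), matrix(1e-12, 2, 2))

  ## incompatible inputs
  expect_error(combineMulti(list(mk(v), mk(matrix(1, 2, 2)))), "shape")
  other <- new("SaliencyMap", values = v, method = "normgrad",
               vil = vilSpec("conv", 3L), layers = "l2", smoothed = FALSE)
  expect_error(combineMulti(list(mk(v), other)), "identity layer")
  expect_error(combineMulti(list()), "at least one")
})

test_that("single- and multi-layer NormGrad compose deterministically", {
  m <- buildClassifier("toy_a", seed = 4L)
  set.seed(8)
  img <- matrix(runif(64 * 64), 64, 64)

  s1 <- normGrad(m, img, "conv4.2", 1L, vilSpec("scaling"))
  expect_identical(dim(saliencyValues(s1)), c(64L, 64L))
  expect_true(all(saliencyValues(s1) >= 0))
  s1b <- normGrad(m, img, "conv4.2", 1L, vilSpec("scaling"))
  expect_identical(saliencyValues(s1), saliencyValues(s1b))

  ## J = 1 multi equals normalised single
  one <- normGradMulti(m, img, "conv4.2", 1L, vilSpec("scaling"))
  v <- saliencyValues(s1)
  expect_equal(saliencyValues(one),
               (v - min(v)) / (max(v) - min(v)) + 1e-12,
               tolerance = 1e-9)

  ## preset runs and is order-invariant
  mm <- normGradMulti(m, img, layerPreset(m), 1L, vilSpec("conv", 3L))
  expect_identical(dim(saliencyValues(mm)), c(64L, 64L))
  mm2 <- normGradMulti(m, img, rev(layerPreset(m)), 1L, vilSpec("conv", 3L))
  expect_equal(saliencyValues(mm), saliencyValues(mm2), tolerance = 1e-12)
})

test_that("positive homogeneity: scaling the gradient scales the map", {
  cp <- randomCapture(H = 4L, W = 4L, K = 3L, seed = 77)
  for (vil in list(vilSpec("scaling"), vilSpec("conv", 3L))) {
    f <- if (vil@kind == "scaling") contributionScaling
         else function(x) contributionConv(x, vil@N)
    base <- f(cp)
    scaled <- captureFrom(activations(cp), 3.5 * gradients(cp))
    expect_equal(f(scaled), 3.5 * base, tolerance = 1e-12)
  }
})
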