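test_that("Gaussian smoothing matches a direct convolution reference", {
  mk <- function(v) new("SaliencyMap", values = v, method = "test",
                        vil = NULL, layers = character(), smoothed = FALSE)
  ## constants are preserved under reflect boundaries
  const <- smoothMap(mk(matrix(0.4, 8, 8)), 1.0)
  expect_equal(saliencyValues(const), matrix(0.4, 8, 8), tolerance = 1e-12)
  expect_true(const@smoothed)

  ## a centred delta keeps its argmax under a symmetric unimodal kernel
  d <- deltaMap(17L, 17L, 8L, 8L)
  expect_identical(unname(argmaxRC(smoothMap(d, 1.0))), c(8L, 8L))

  ## direct-convolution oracle on a random map
  set.seed(21)
  v <- matrix(runif(256), 16, 16)
  got <- saliencyValues(smoothMap(mk(v), 1.0))
  expect_lt(max(abs(got - oracleGaussSmooth(v, 1.0))), 1e-6)
  got2 <- saliencyValues(smoothMap(mk(v), 2.5))
  expect_lt(max(abs(got2 - oracleGaussSmooth(v, 2.5))), 1e-6)

  ## sigma = 0 is the identity
  expect_identical(saliencyValues(smoothMap(mk(v), 0)), v)
  expect_error(smoothMap(mk(v), -1), "sigma")
})

test_that("pointing game hit follows the tau box-dilation rule", {
  b <- box(40L, 40L, 60L, 60L)
  expect_true(pointingGameHit(deltaMap(100L, 100L, 50L, 50L), b, 15L)$hit)
  expect_false(pointingGameHit(deltaMap(100L, 100L, 0L, 0L), b, 15L)$hit)
  expect_true(pointingGameHit(deltaMap(100L, 100L, 30L, 30L), b, 15L)$hit)
  expect_false(pointingGameHit(deltaMap(100L, 100L, 24L, 50L), b, 15L)$hit)
  expect_true(pointingGameHit(deltaMap(100L, 100L, 25L, 50L), b, 15L)$hit)
  ## half-open upper edge: row 74 is the last dilated row (60 + 15 - 1)
  expect_true(pointingGameHit(deltaMap(100L, 100L, 74L, 50L), b, 15L)$hit)
  expect_false(pointingGameHit(deltaMap(100L, 100L, 75L, 50L), b, 15L)$hit)

  ## any-box rule
  two <- rbind(box(0L, 0L, 5L, 5L), box(80L, 80L, 90L, 90L))
  expect_true(pointingGameHit(deltaMap(100L, 100L, 85L, 85L), two, 0L)$hit)

  ## ties resolve to the first maximum in row-major order
  flat <- new("SaliencyMap", values = matrix(1, 10, 10), method = "t",
              vil = NULL, layers = character(), smoothed = FALSE)
  expect_identical(unname(argmaxRC(flat)), c(0L, 0L))
  v <- matrix(0, 10, 10); v[3, 7] <- 2; v[5, 2] <- 2
  expect_identical(unname(saliencyArgmax(v)), c(2L, 6L))

  expect_error(pointingGameHit(deltaMap(10L, 10L, 1L, 1L),
                               box(1L, 1L, 2L, 2L)[0L, ]),
               "no ground-truth boxes")
})

test_that("hits are monotone in tau and accuracy follows T/(T+F)", {
  set.seed(31)
  for (r in 1:25) {
    H <- 60L; W <- 60L
    b <- box(sample(0:40, 1L), sample(0:40, 1L), 0L, 0L)
    b$x_max <- b$x_min + sample(5:15, 1L)
    b$y_max <- b$y_min + sample(5:15, 1L)
    m <- deltaMap(H, W, sample(0:(H - 1L), 1L), sample(0:(W - 1L), 1L))
    hits <- vapply(c(0L, 5L, 15L, 30L),
                   function(tau) pointingGameHit(m, b, tau)$hit, TRUE)
    expect_true(all(diff(hits) >= 0))  # hit at tau1 implies hit at tau2
  }

  pg <- pointingGameAccuracy(c(rep(TRUE, 7L), rep(FALSE, 3L)))
  expect_identical(pg@hits, 7L)
  expect_identical(pg@misses, 3L)
  expect_equal(accuracy(pg), 0.7)
  expect_equal(accuracy(pointingGameAccuracy(rep(TRUE, 5L))), 1)
  expect_equal(accuracy(pointingGameAccuracy(rep(FALSE, 4L))), 0)
  expect_error(pointingGameAccuracy(logical(0L)), "no decisions")

  ## conservation: T + F equals the number of scored decisions, exactly
  dec <- runif(37L) > 0.5
  pg2 <- pointingGameAccuracy(dec)
  expect_identical(pg2@hits + pg2@misses, 37L)
  expect_equal(accuracy(pg2) * 37L, as.numeric(pg2@hits),
               tolerance = 1e-12)
})

test_that("repeated-trial aggregation uses mean and n-1 standard deviation", {
  ms <- repeatedAccuracy(c(0.5, 0.6, 0.7))
  expect_equal(unname(ms), c(0.6, 0.1), tolerance = 1e-12)
  expect_equal(unname(repeatedAccuracy(0.852)), c(0.852, 0))
  expect_equal(repeatedAccuracy(c(0.3, 0.3, 0.3))[["std"]], 0)
  expect_error(repeatedAccuracy(numeric(0L)), "empty")
})

test_that("difference of means is a linear-kernel MMD", {
  ## identity, symmetry
  a <- trialAccuracySet(c(0.5, 0.6, 0.7), "toy_a", "m")
  expect_equal(domConsistency(a, a)@dom, 0)
  b <- trialAccuracySet(c(0.4, 0.9), "toy_b", "m")
  expect_equal(domConsistency(a, b)@dom, domConsistency(b, a)@dom,
               tolerance = 1e-15)

  ## worked examples from the published per-architecture means
  expect_equal(domConsistency(0.851, 0.850)@dom, 0.001, tolerance = 1e-12)
  expect_equal(domConsistency(0.602, 0.607)@dom, 0.005, tolerance = 1e-12)

  set.seed(41)
  for (r in 1:100) {
    x <- runif(sample(2:6, 1L))
    y <- runif(sample(2:6, 1L))
    d <- domConsistency(x, y)@dom
    ## exact agreement with the kernel-mean-embedding formula
    expect_equal(d, oracleLinearMMD(x, y), tolerance = 1e-9)
    ## triangle inequality through a third set
    z <- runif(3L)
    expect_lte(domConsistency(x, z)@dom,
               domConsistency(x, y)@dom + domConsistency(y, z)@dom + 1e-12)
    ## invariance to permuting trials within a set
    expect_equal(d, domConsistency(sample(x), y)@dom,
                 tolerance = 1e-12)
  }
  expect_error(domConsistency(numeric(0L), 0.5), "empty")
})
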