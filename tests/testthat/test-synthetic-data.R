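test_that("the generator honors counts, labels and reproducibility", {
  spec <- tinySpec(n = 10L, seed = 3L)
  ds <- generateDataset(spec)
  all_ <- c(ds@train, ds@val, ds@test)
  expect_length(all_, 10L)
  labs <- vapply(all_, function(i) i@label, 0L)
  nbox <- vapply(all_, function(i) nrow(boxes(i)), 0L)
  expect_identical(sum(labs), 5L)
  expect_identical(labs == 1L, nbox > 0L)  # label 1 <=> at least one box

  ## byte-identical regeneration from the same spec
  ds2 <- generateDataset(spec)
  for (k in seq_along(all_)) {
    expect_identical(pixels(all_[[k]]), pixels(c(ds2@train, ds2@val,
                                                 ds2@test)[[k]]))
    expect_identical(boxes(all_[[k]]), boxes(c(ds2@train, ds2@val,
                                               ds2@test)[[k]]))
  }

  ## disjoint splits by input id
  ids <- lapply(list(ds@train, ds@val, ds@test),
                function(s) vapply(s, function(i) i@inputId, ""))
  expect_identical(anyDuplicated(unlist(ids)), 0L)

  ## pixels stay in [0,1]; boxes lie inside the image
  for (im in all_) {
    expect_true(all(pixels(im) >= 0 & pixels(im) <= 1))
    b <- boxes(im)
    if (nrow(b)) {
      expect_true(all(b$x_min < b$x_max & b$y_min < b$y_max))
      expect_true(all(b$x_min >= 0 & b$y_min >= 0 &
                        b$x_max <= 64 & b$y_max <= 64))
    }
  }
})

test_that("lvot blobs sit near the image center within the jitter bound", {
  spec <- syntheticSpec("lvot", nImages = 30L, imageSize = c(64L, 64L),
                        objectSizePx = c(8L, 14L), centerJitterPx = 6L,
                        seed = 9L)
  ds <- generateDataset(spec)
  for (im in c(ds@train, ds@val, ds@test)) {
    b <- boxes(im)
    if (!nrow(b)) next
    expect_identical(nrow(b), 1L)  # zero or one blob per frame
    cx <- (b$x_min + b$x_max) / 2
    cy <- (b$y_min + b$y_max) / 2
    expect_lte(abs(cx - 32), 6 + 1)
    expect_lte(abs(cy - 32), 6 + 1)
  }
})

test_that("stamped defects clear the pre-stamp background by the margin", {
  spec <- tinySpec(n = 2L, seed = 13L)
  set.seed(101)
  for (r in 1:10) {
    rec <- normgradiqa:::.renderImage(spec, positive = TRUE)
    pre <- pmin(rec$background, 1 - spec@contrast)  # defect occludes
    for (k in seq_len(nrow(rec$boxes))) {
      b <- rec$boxes[k, ]
      ys <- (b$y_min + 1L):b$y_max
      xs <- (b$x_min + 1L):b$x_max
      lift <- max(rec$pixels[ys, xs] - pre[ys, xs])
      expect_gte(lift, spec@contrast - 3 * spec@noiseSd)
    }
  }
  ## an object larger than the image is rejected
  expect_error(syntheticSpec(objectSizePx = c(70L, 80L)), "smaller")
})

test_that("training is a seeded no-op at zero epochs and reproducible", {
  ds <- generateDataset(tinySpec(n = 24L, seed = 5L))
  m <- buildClassifier("toy_a", seed = 2L)
  f0 <- trainFixture(m, ds, epochs = 0L, seed = 1L)
  expect_identical(modelParameters(f0$model), modelParameters(m))
  expect_identical(nrow(f0$metrics), 0L)

  f1 <- trainFixture(m, ds, epochs = 1L, seed = 4L)
  f2 <- trainFixture(m, ds, epochs = 1L, seed = 4L)
  expect_identical(modelParameters(f1$model), modelParameters(f2$model))
  expect_false(identical(modelParameters(f1$model), modelParameters(m)))
  expect_identical(names(f1$metrics),
                   c("epoch", "train_acc", "val_acc", "train_loss"))
})

test_that("backgrounds alone carry no label signal", {
  ## positives and negatives share one background process: training on
  ## images whose pixels were shuffled across records (labels kept) can
  ## do no better than chance on the real validation split
  ds <- generateDataset(syntheticSpec("foreign_object", nImages = 300L,
                                      contrast = 0.6, noiseSd = 0.05,
                                      seed = 17L))
  tr <- ds@train
  set.seed(23)
  perm <- sample(length(tr))
  shuffled <- lapply(seq_along(tr), function(i) {
    im <- tr[[i]]
    initialize(im, pixels = pixels(tr[[perm[i]]]))
  })
  fit <- trainFixture(buildClassifier("toy_a", seed = 3L),
                      list(train = shuffled, val = ds@val),
                      epochs = 3L, seed = 3L)
  final <- fit$metrics$val_acc[3L]
  expect_gte(final, 0.4)
  expect_lte(final, 0.6)
})
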