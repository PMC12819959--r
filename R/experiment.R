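#' Compute a saliency map by method name
#'
#' Dispatcher used by the experiment harness and the command-line
#' interface. Canonical method names: \code{input_x_grad},
#' \code{guided_backprop}, \code{grad_cam}, \code{guided_grad_cam},
#' \code{normgrad_scaling}, \code{normgrad_conv1x1},
#' \code{normgrad_conv3x3}, each NormGrad variant also with a
#' \code{_multi} suffix (layer-preset aggregation).
#'
#' @param model a \linkS4class{ToyClassifier}.
#' @param image grayscale matrix.
#' @param method canonical method name.
#' @param targetClass class the loss gradient is taken against.
#' @param layerId target layer for single-layer CAM/NormGrad methods.
#' @param layerIds layers for the \code{_multi} variants.
#' @return a \linkS4class{SaliencyMap}.
#' @export
computeSaliency <- function(model, image, method,
                            targetClass = 1L,
                            layerId = penultimateLayer(model),
                            layerIds = layerPreset(model)) {
  vil <- switch(sub("_multi$", "", method),
                normgrad_scaling = vilSpec("scaling"),
                normgrad_conv1x1 = vilSpec("conv", 1L),
                normgrad_conv3x3 = vilSpec("conv", 3L),
                NULL)
  if (!is.null(vil)) {
    if (grepl("_multi$", method))
      return(normGradMulti(model, image, layerIds, targetClass, vil))
    return(normGrad(model, image, layerId, targetClass, vil))
  }
  switch(method,
         input_x_grad = inputXGrad(model, image, targetClass),
         guided_backprop = guidedBackprop(model, image, targetClass),
         grad_cam = gradCAM(model, image, layerId, targetClass),
         guided_grad_cam = guidedGradCAM(model, image, layerId, targetClass),
         stop("unknown saliency method: ", method))
}

#' All canonical saliency method names
#' @export
saliencyMethods <- function() {
  c("input_x_grad", "guided_backprop", "grad_cam", "guided_grad_cam",
    "normgrad_scaling", "normgrad_scaling_multi", "normgrad_conv1x1",
    "normgrad_conv1x1_multi", "normgrad_conv3x3", "normgrad_conv3x3_multi")
}

#' Pointing Game evaluation of one model over a set of images
#'
#' Scores every image that carries at least one box: the method's map is
#' computed, optionally smoothed, and judged by the Pointing Game with
#' tolerance \code{tau}. Images without boxes are excluded (and counted
#' in \code{n_excluded}).
#'
#' @param model a \linkS4class{ToyClassifier}.
#' @param images list of \linkS4class{AnnotatedImage}s.
#' @param method canonical saliency method name.
#' @param tau Pointing Game tolerance in pixels.
#' @param sigma Gaussian smoothing standard deviation (0 = unsmoothed).
#' @param targetClass class the loss gradient is taken against (the
#'   defect class).
#' @return a \linkS4class{PointingGameResult}.
#' @export
evaluatePointingGame <- function(model, images, method = "normgrad_scaling",
                                 tau = 15L, sigma = 1.0, targetClass = 1L) {
  scored <- Filter(function(im) nrow(im@boxes) > 0L, images)
  if (!length(scored)) stop("no annotated images to score")
  rows <- lapply(scored, function(im) {
    map <- computeSaliency(model, im@pixels, method, targetClass)
    if (sigma > 0) map <- smoothMap(map, sigma)
    h <- pointingGameHit(map, im@boxes, tau)
    data.frame(input_id = im@inputId, row = h$argmax[["row"]],
               col = h$argmax[["col"]], hit = h$hit)
  })
  per <- do.call(rbind, rows)
  pointingGameAccuracy(per$hit, tau = tau, perImage = per)
}

.expDefaults <- function() {
  list(architectures = "toy_a", methods = "normgrad_scaling_multi",
       scheme = "trained", n_trials = 3L, tau = 15L, sigma = 1.0,
       epochs = 5L, learning_rate = 0.003, momentum = 0.9, seed = 1L)
}

#' Run a full randomisation / repeatability / reproducibility experiment
#'
#' For each architecture and trial a model is prepared according to the
#' scheme — \code{"trained"}: trained from a distinct seed;
#' \code{"FR"}: all parameters He-re-drawn; \code{"SR"}: the trained
#' reference backbone with a re-drawn head — and every annotated test
#' image is scored with the (smoothed) map of each method by the Pointing
#' Game. Per-trial accuracies are aggregated to mean +/- std, and when two
#' or more architectures are run, the Difference of Means between the
#' first architecture pair is reported per method. Every random draw is
#' derived from \code{config$seed}; rerunning the same config reproduces
#' the tables exactly.
#'
#' @param config list: \code{data} (a \linkS4class{SyntheticSpec} or
#'   \linkS4class{SyntheticDataset}), \code{architectures},
#'   \code{methods}, \code{scheme} (\code{trained|FR|SR}),
#'   \code{n_trials}, \code{tau}, \code{sigma}, \code{epochs},
#'   \code{learning_rate}, \code{momentum}, \code{seed}.
#' @param quiet suppress per-trial progress messages.
#' @return list of data.frames: \code{results} (architecture, method,
#'   scheme, trial, accuracy), \code{summary} (mean, std per
#'   architecture/method), \code{dom} (per method, when >= 2
#'   architectures).
#' @export
runExperiment <- function(config, quiet = TRUE) {
  cfg <- utils::modifyList(.expDefaults(), config)
  known <- c(names(.expDefaults()), "data")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) stop("unknown config keys: ", paste(extra, collapse = ", "))
  if (is.null(cfg$data)) stop("config$data is required")
  ds <- if (is(cfg$data, "SyntheticSpec")) generateDataset(cfg$data)
        else cfg$data
  if (!cfg$scheme %in% c("trained", "FR", "SR"))
    stop("scheme must be one of trained, FR, SR")
  results <- data.frame()
  for (ai in seq_along(cfg$architectures)) {
    arch <- cfg$architectures[ai]
    base <- buildClassifier(arch, numClasses = 2L,
                            inputShape = c(1L, ds@spec@imageSize),
                            seed = .deriveSeed(cfg$seed, ai))
    ref <- NULL
    if (cfg$scheme == "SR") {
      ref <- trainFixture(base, ds, epochs = cfg$epochs,
                          learningRate = cfg$learning_rate,
                          momentum = cfg$momentum,
                          seed = .deriveSeed(cfg$seed, ai, 0L),
                          metrics = FALSE)$model
    }
    for (trial in seq_len(cfg$n_trials)) {
      tseed <- .deriveSeed(cfg$seed, ai, trial)
      model <- switch(cfg$scheme,
        trained = trainFixture(
          buildClassifier(arch, numClasses = 2L,
                          inputShape = c(1L, ds@spec@imageSize),
                          seed = tseed),
          ds, epochs = cfg$epochs, learningRate = cfg$learning_rate,
          momentum = cfg$momentum, seed = tseed, metrics = FALSE)$model,
        FR = randomiseModel(base, "FR", tseed),
        SR = randomiseModel(ref, "SR", tseed))
      for (method in cfg$methods) {
        pg <- evaluatePointingGame(model, ds@test, method,
                                   tau = cfg$tau, sigma = cfg$sigma)
        if (!quiet)
          message(sprintf("%s %s %s trial %d: A=%.3f", arch, method,
                          cfg$scheme, trial, accuracy(pg)))
        results <- rbind(results,
                         data.frame(architecture = arch, method = method,
                                    scheme = cfg$scheme, trial = trial,
                                    accuracy = accuracy(pg)))
      }
    }
  }
  summary <- do.call(rbind, lapply(
    split(results, list(results$architecture, results$method), drop = TRUE),
    function(d) {
      ms <- repeatedAccuracy(d$accuracy)
      data.frame(architecture = d$architecture[1L], method = d$method[1L],
                 scheme = d$scheme[1L], n_trials = nrow(d),
                 mean = ms[["mean"]], std = ms[["std"]])
    }))
  summary <- summary[order(summary$architecture, summary$method), ]
  rownames(summary) <- NULL
  dom <- NULL
  if (length(cfg$architectures) >= 2L) {
    a1 <- cfg$architectures[1L]; a2 <- cfg$architectures[2L]
    dom <- do.call(rbind, lapply(unique(results$method), function(m) {
      sa <- results$accuracy[results$architecture == a1 &
                               results$method == m]
      sb <- results$accuracy[results$architecture == a2 &
                               results$method == m]
      d <- domConsistency(sa, sb)
      data.frame(method = m, arch_a = a1, arch_b = a2,
                 mean_a = d@meanA, mean_b = d@meanB, dom = d@dom)
    }))
  }
  list(results = results, summary = summary, dom = dom, config = cfg)
}
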