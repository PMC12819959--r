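#' Write / read a saliency map as TSV plus JSON sidecar
#'
#' The heat map is stored as a plain TSV numeric matrix at \code{path};
#' the provenance metadata (method, virtual identity layer, layers,
#' smoothed flag, argmax) goes to \code{<path>.json}. The round trip
#' reproduces values to full printed precision and metadata exactly.
#'
#' @param map a \linkS4class{SaliencyMap}.
#' @param path output TSV path.
#' @return \code{writeSaliency} returns \code{path} invisibly;
#'   \code{readSaliency} returns the \linkS4class{SaliencyMap}.
#' @export
writeSaliency <- function(map, path) {
  stopifnot(is(map, "SaliencyMap"))
  utils::write.table(format(map@values, digits = 17L, trim = TRUE,
                            scientific = TRUE),
                     path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  am <- saliencyArgmax(map@values)
  meta <- list(method = map@method,
               vil = if (is.null(map@vil)) NULL
                     else list(kind = map@vil@kind, N = map@vil@N),
               layers = as.list(map@layers), smoothed = map@smoothed,
               argmax_rc = c(am[["row"]], am[["col"]]),
               shape = dim(map@values))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname writeSaliency
#' @export
readSaliency <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("saliency sidecar missing: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  v <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(v) <- NULL
  if (!identical(dim(v), as.integer(meta$shape)))
    stop("saliency matrix shape does not match sidecar")
  if (any(v < 0)) stop("negative saliency values in file")
  vil <- if (is.null(meta$vil)) NULL else vilSpec(meta$vil$kind, meta$vil$N)
  new("SaliencyMap", values = v, method = meta$method, vil = vil,
      layers = as.character(unlist(meta$layers)),
      smoothed = isTRUE(meta$smoothed))
}

.boxesToString <- function(b) {
  if (!nrow(b)) return("")
  paste(apply(b[, c("x_min", "y_min", "x_max", "y_max")], 1L, paste,
              collapse = " "), collapse = ";")
}

.stringToBoxes <- function(s) {
  s <- trimws(s)
  if (is.na(s) || !nzchar(s))
    return(data.frame(x_min = integer(), y_min = integer(),
                      x_max = integer(), y_max = integer()))
  parts <- strsplit(strsplit(s, ";")[[1L]], "[[:space:]]+")
  do.call(rbind, lapply(parts, function(p) {
    v <- as.integer(p)
    if (length(v) != 4L || anyNA(v))
      stop("malformed box string: '", s, "'")
    data.frame(x_min = v[1L], y_min = v[2L], x_max = v[3L], y_max = v[4L])
  }))
}

#' Write an annotated dataset to disk
#'
#' Images are written as 8-bit grayscale PNGs under \code{dir/images/};
#' annotations go to \code{dir/annotations.csv} with columns
#' \code{input_id, label, boxes} (boxes a semicolon-separated list of
#' \code{"x_min y_min x_max y_max"}, half-open, 0-based) plus a
#' \code{split} column; \code{dir/manifest.json} records the generator
#' spec and seed.
#'
#' @param dataset a \linkS4class{SyntheticDataset}.
#' @param dir output directory (created).
#' @return \code{dir}, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  rows <- list()
  for (split in c("train", "val", "test")) {
    for (im in slot(dataset, split)) {
      png::writePNG(im@pixels, file.path(dir, "images",
                                         paste0(im@inputId, ".png")))
      rows[[length(rows) + 1L]] <-
        data.frame(input_id = im@inputId, label = im@label,
                   boxes = .boxesToString(im@boxes), split = split)
    }
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "annotations.csv"),
                   row.names = FALSE)
  sp <- dataset@spec
  jsonlite::write_json(
    list(mode = sp@mode, n_images = sp@nImages, image_size = sp@imageSize,
         positive_fraction = sp@positiveFraction,
         objects_per_positive = sp@objectsPerPositive,
         object_size_px = sp@objectSizePx, contrast = sp@contrast,
         noise_sd = sp@noiseSd, center_jitter_px = sp@centerJitterPx,
         seed = sp@seed),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read annotated images from a dataset directory
#'
#' Reads \code{annotations.csv} (and the PNGs it references), validating
#' every row: missing image files, inverted boxes and out-of-bounds boxes
#' are reported with their row number.
#'
#' @param dir dataset directory written by \code{\link{writeDataset}}.
#' @return a \linkS4class{SyntheticDataset} when the manifest is present,
#'   otherwise a plain list of \linkS4class{AnnotatedImage}s.
#' @export
readDataset <- function(dir) {
  csv <- file.path(dir, "annotations.csv")
  if (!file.exists(csv)) stop("annotations.csv not found in ", dir)
  ann <- utils::read.csv(csv, stringsAsFactors = FALSE,
                         colClasses = c(boxes = "character"))
  images <- lapply(seq_len(nrow(ann)), function(i) {
    row <- ann[i, ]
    f <- file.path(dir, "images", paste0(row$input_id, ".png"))
    if (!file.exists(f))
      stop("row ", i, ": missing image file ", f)
    px <- png::readPNG(f)
    if (length(dim(px)) == 3L) px <- px[, , 1L]
    bx <- tryCatch(.stringToBoxes(row$boxes),
                   error = function(e) stop("row ", i, ": ",
                                            conditionMessage(e)))
    tryCatch(new("AnnotatedImage", inputId = row$input_id, pixels = px,
                 label = as.integer(row$label), boxes = bx),
             error = function(e) stop("row ", i, ": ",
                                      conditionMessage(e)))
  })
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf) || !"split" %in% names(ann)) return(images)
  m <- jsonlite::read_json(mf, simplifyVector = TRUE)
  spec <- syntheticSpec(m$mode, m$n_images, m$image_size,
                        m$positive_fraction, m$objects_per_positive,
                        m$object_size_px, m$contrast, m$noise_sd,
                        m$center_jitter_px, m$seed)
  new("SyntheticDataset",
      train = images[ann$split == "train"],
      val = images[ann$split == "val"],
      test = images[ann$split == "test"], spec = spec)
}

#' Render a saliency map to an 8-bit PNG for inspection
#'
#' Min-max scaled heat map, optionally blended over the image with
#' ground-truth box outlines burned in.
#'
#' @param map a \linkS4class{SaliencyMap}.
#' @param path output PNG path.
#' @param image optional underlying grayscale image for overlay.
#' @param boxes optional data.frame of boxes to outline.
#' @export
renderSaliencyPNG <- function(map, path, image = NULL, boxes = NULL) {
  v <- .minMaxNorm(map@values)
  if (!is.null(image)) v <- 0.5 * v + 0.5 * image
  rgb <- array(v, dim = c(nrow(v), ncol(v), 3L))
  if (!is.null(map@values)) rgb[, , 1L] <- .minMaxNorm(map@values)
  if (!is.null(boxes) && nrow(boxes)) {
    for (i in seq_len(nrow(boxes))) {
      b <- boxes[i, ]
      ys <- (b$y_min + 1L):b$y_max
      xs <- (b$x_min + 1L):b$x_max
      rgb[range(ys), xs, 1L] <- 1; rgb[range(ys), xs, 2:3] <- 0
      rgb[ys, range(xs), 1L] <- 1; rgb[ys, range(xs), 2:3] <- 0
    }
  }
  png::writePNG(pmin(pmax(rgb, 0), 1), path)
  invisible(path)
}
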