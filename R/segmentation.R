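#' Segment nuclei (or cells) from an intensity channel
#'
#' Intensity-based object detection: global threshold (Otsu on the image
#' histogram by default, or a fixed value), hole filling, connected-
#' component labeling (8-connected in 2D, 26-connected in 3D), removal of
#' objects below a minimum size and, optionally, of objects touching the
#' image border. Designed for DAPI-stained nuclei but works for any
#' bright-on-dark channel.
#'
#' @param image single-channel [image_stack] (axes `y, x` or `y, x, z`) or
#'   a plain matrix / 3D array.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold intensity threshold when `method = "fixed"`.
#' @param min_area minimum object size in pixels (2D) or voxels (3D).
#' @param max_area optional maximum size; larger objects (e.g. merged,
#'   touching nuclei) are removed and counted in the `excluded` attribute.
#' @param exclude_border drop objects touching the y/x image border.
#' @param fill_holes fill interior holes (per z-slice in 3D).
#' @param connectivity see [label_components]; `NULL` = default.
#' @return integer label array (class `label_mask`) with attributes
#'   `threshold` and `excluded` (named counts of objects removed by each
#'   rule). An all-zero image yields an empty mask, not an error.
#' @export
segment_objects <- function(image, method = c("otsu", "fixed"), threshold = NULL,
                            min_area = 50, max_area = NULL,
                            exclude_border = FALSE, fill_holes = TRUE,
                            connectivity = NULL) {
  method <- match.arg(method)
  img <- if (inherits(image, "image_stack")) image$data else image
  if (anyNA(img) || !all(is.finite(img))) stop("non-finite pixels", call. = FALSE)
  d <- dim(img)
  if (length(d) == 2) img <- matrix(img, d[1], d[2])

  if (method == "fixed") {
    if (is.null(threshold)) stop("fixed method needs `threshold`", call. = FALSE)
    thr <- threshold
  } else {
    rng <- range(img)
    if (rng[2] <= rng[1]) {
      # constant image: nothing to detect
      lab <- array(0L, dim = d)
      class(lab) <- c("label_mask", class(lab))
      attr(lab, "threshold") <- rng[2]
      attr(lab, "excluded") <- c(small = 0L, border = 0L, large = 0L)
      return(lab)
    }
    # Otsu on the pooled histogram, computed on the [0,1]-rescaled image
    # and mapped back to intensity units.
    sc <- (img - rng[1]) / (rng[2] - rng[1])
    thr01 <- EBImage::otsu(EBImage::Image(matrix(sc, ncol = 1)), range = c(0, 1))
    thr <- rng[1] + thr01 * (rng[2] - rng[1])
  }

  bin <- (img > thr) * 1
  if (fill_holes) {
    if (length(d) == 2) {
      bin <- as.matrix(EBImage::fillHull(bin))
    } else {
      for (k in seq_len(d[3])) bin[, , k] <- as.matrix(EBImage::fillHull(bin[, , k]))
    }
  }
  lab <- label_components(array(bin, dim = d), connectivity = connectivity)

  excluded <- c(small = 0L, border = 0L, large = 0L)
  sizes <- label_sizes(lab)
  if (length(sizes)) {
    drop_small <- as.integer(names(sizes)[sizes < min_area])
    excluded["small"] <- length(drop_small)
    if (length(drop_small)) lab[lab %in% drop_small] <- 0L
    if (!is.null(max_area)) {
      sizes <- label_sizes(lab)
      drop_large <- as.integer(names(sizes)[sizes > max_area])
      excluded["large"] <- length(drop_large)
      if (length(drop_large)) lab[lab %in% drop_large] <- 0L
    }
    if (exclude_border) {
      border <- if (length(d) == 2) {
        unique(c(lab[1, ], lab[d[1], ], lab[, 1], lab[, d[2]]))
      } else {
        unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ]))
      }
      border <- setdiff(border, 0L)
      excluded["border"] <- length(border)
      if (length(border)) lab[lab %in% border] <- 0L
    }
  }
  # relabel sequentially, preserving raster order
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids)) lab <- array(match(lab, c(0L, ids), nomatch = 1L) - 1L, dim = d)
  lab <- array(as.integer(lab), dim = d)
  class(lab) <- c("label_mask", class(lab))
  attr(lab, "threshold") <- as.numeric(thr)
  attr(lab, "excluded") <- excluded
  lab
}

#' Partition one object into a rim band and a nucleoplasm core
#'
#' Computes the Euclidean distance of every object pixel to the background
#' (image border counts as background) and splits the object at fixed
#' pixel distances: the rim band is the set of pixels with distance in
#' `(rim_distance_px, rim_distance_px + rim_width_px]`, the nucleoplasm
#' core the pixels with distance strictly greater than
#' `rim_distance_px + rim_width_px`. With the default
#' `rim_distance_px = 0` the band starts at the object boundary. Pixels at
#' distance `<= rim_distance_px` form an excluded collar, so
#' rim + core + collar tile the object exactly.
#'
#' @param mask label matrix (a `label_mask` or plain integer matrix).
#' @param object_id label of the object to partition.
#' @param rim_distance_px inward offset of the band from the boundary, px.
#' @param rim_width_px band width, px.
#' @return object of class `region_partition`: list with `object_id`,
#'   `rim` and `nucleoplasm` (linear pixel indices), `collar`, `shape`,
#'   `rim_distance_px`, `rim_width_px`.
#' @seealso [measure_ne_ratio]
#' @export
partition_rim_nucleoplasm <- function(mask, object_id, rim_distance_px = 0,
                                      rim_width_px = 3) {
  stopifnot(rim_distance_px >= 0, rim_width_px >= 1)
  m <- (unclass(mask) == object_id)
  if (!any(m)) stop(sprintf("object %s not found in mask", object_id), call. = FALSE)
  if (length(dim(m)) != 2) stop("partition requires a 2D mask", call. = FALSE)
  dist <- distance_to_background(m)
  lo <- rim_distance_px
  hi <- rim_distance_px + rim_width_px
  rim <- which(m & dist > lo & dist <= hi)
  core <- which(m & dist > hi)
  if (length(rim) == 0 || length(core) == 0) {
    stop(sprintf("degenerate partition for object %s: rim %d px, nucleoplasm %d px",
                 object_id, length(rim), length(core)), call. = FALSE)
  }
  structure(list(object_id = object_id, rim = rim, nucleoplasm = core,
                 collar = which(m & dist <= lo), shape = dim(m),
                 rim_distance_px = rim_distance_px, rim_width_px = rim_width_px),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat("<region_partition> object", x$object_id,
      "| rim", length(x$rim), "px | nucleoplasm", length(x$nucleoplasm), "px",
      "| band (", x$rim_distance_px, ",", x$rim_distance_px + x$rim_width_px, "] px\n")
  invisible(x)
}

#' Partition every object of a label mask
#'
#' Applies [partition_rim_nucleoplasm] to each label; objects too small
#' for the requested distances are skipped and reported.
#'
#' @inheritParams partition_rim_nucleoplasm
#' @return list with `partitions` (named list) and `degenerate` (integer
#'   vector of skipped object ids).
#' @export
partition_all <- function(mask, rim_distance_px = 0, rim_width_px = 3) {
  ids <- sort(unique(as.vector(unclass(mask))))
  ids <- ids[ids > 0]
  parts <- list(); degenerate <- integer(0)
  for (id in ids) {
    p <- tryCatch(partition_rim_nucleoplasm(mask, id, rim_distance_px, rim_width_px),
                  error = function(e) NULL)
    if (is.null(p)) degenerate <- c(degenerate, id) else parts[[as.character(id)]] <- p
  }
  list(partitions = parts, degenerate = degenerate)
}

#' Rigid drift correction of a time-lapse by translation registration
#'
#' Estimates the integer translation of every frame relative to the first
#' frame by cross-correlation (computed via FFT on mean-subtracted
#' frames) and shifts each frame back. When the normalized correlation
#' peak of a frame falls below `min_confidence`, its offset is still
#' reported but a low-confidence warning is raised.
#'
#' @param series [image_stack] with axes `y, x, time` (or a 3D array with
#'   time last).
#' @param min_confidence normalized cross-correlation peak below which a
#'   warning is emitted.
#' @return list with `series` (registered [image_stack]), `offsets`
#'   (tibble `frame, dy, dx, confidence`: the estimated displacement of
#'   each frame relative to frame 1), and `low_confidence` (frame ids).
#' @export
register_translation <- function(series, min_confidence = 0.2) {
  arr <- if (inherits(series, "image_stack")) {
    if (!identical(series$axes, c("y", "x", "time"))) {
      stop("series must have axes y, x, time", call. = FALSE)
    }
    series$data
  } else series
  d <- dim(arr)
  if (length(d) != 3 || d[3] < 2) stop("need a y-x-time series with >= 2 frames", call. = FALSE)

  ref <- arr[, , 1]
  Fref <- stats::fft(ref - mean(ref))
  n <- prod(d[1:2])
  offs <- matrix(0L, d[3], 2)
  conf <- numeric(d[3]); conf[1] <- 1
  out <- arr
  for (j in 2:d[3]) {
    fr <- arr[, , j]
    Ffr <- stats::fft(fr - mean(fr))
    cc <- Re(stats::fft(Fref * Conj(Ffr), inverse = TRUE)) / n
    pk <- which.max(cc)
    pc <- arrayInd(pk, d[1:2])
    dy <- pc[1] - 1; dx <- pc[2] - 1
    if (dy > d[1] / 2) dy <- dy - d[1]
    if (dx > d[2] / 2) dx <- dx - d[2]
    denom <- sqrt(sum((ref - mean(ref))^2) * sum((fr - mean(fr))^2))
    conf[j] <- if (denom > 0) max(cc) / denom else 0
    # cc peaks at the displacement of `fr` relative to `ref`
    offs[j, ] <- c(-dy, -dx)
    out[, , j] <- shift_matrix(fr, dy, dx, fill = stats::median(fr))
  }
  low <- which(conf < min_confidence)
  if (length(low)) {
    warning(sprintf("low registration confidence for %d frame(s): %s",
                    length(low), paste(utils::head(low, 5), collapse = ", ")),
            call. = FALSE)
  }
  res <- image_stack(out, axes = c("y", "x", "time"),
                     calibration = if (inherits(series, "image_stack"))
                       series$calibration else NULL)
  list(series = res,
       offsets = tibble::tibble(frame = seq_len(d[3]), dy = offs[, 1],
                                dx = offs[, 2], confidence = conf),
       low_confidence = low)
}
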