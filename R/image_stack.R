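#' Multi-dimensional intensity image with explicit axis semantics
#'
#' An `image_stack` wraps a non-negative intensity array together with
#' ordered axis labels drawn from `time`, `z`, `channel`, `y`, `x` and an
#' optional physical calibration (size of one pixel/voxel/frame step per
#' axis). The spatial axes `y` and `x` are always present; everything in
#' this package indexes images as `(row, column) = (y, x)`, 0-based
#' distances, Euclidean metric.
#'
#' @param data numeric array (or matrix) of finite, non-negative
#'   intensities in arbitrary units.
#' @param axes character vector naming each dimension of `data`, a unique
#'   subset of `c("time", "z", "channel", "y", "x")`.
#' @param calibration optional named numeric vector giving the physical
#'   step per axis (e.g. `c(y = 0.075, x = 0.075, z = 0.029)`); purely
#'   descriptive, never applied to pixel arithmetic.
#' @return an object of class `image_stack`.
#' @examples
#' img <- image_stack(matrix(runif(64), 8, 8), axes = c("y", "x"))
#' dim(img$data)
#' @export
image_stack <- function(data, axes, calibration = NULL) {
  if (is.matrix(data)) data <- array(data, dim = dim(data))
  if (!is.array(data) || !is.numeric(data)) {
    stop("`data` must be a numeric array or matrix", call. = FALSE)
  }
  axes <- as.character(axes)
  if (length(axes) != length(dim(data))) {
    stop("`axes` must name every dimension of `data`", call. = FALSE)
  }
  if (anyDuplicated(axes) || !all(axes %in% c("time", "z", "channel", "y", "x"))) {
    stop("`axes` must be unique labels from {time, z, channel, y, x}", call. = FALSE)
  }
  if (!all(c("y", "x") %in% axes)) {
    stop("axes `y` and `x` are required", call. = FALSE)
  }
  if (anyNA(data) || !all(is.finite(data))) {
    stop("intensities must be finite", call. = FALSE)
  }
  if (min(data) < 0) stop("intensities must be non-negative", call. = FALSE)
  if (!is.null(calibration)) {
    if (is.null(names(calibration)) || !all(names(calibration) %in% axes)) {
      stop("`calibration` must be named by axes present in the stack", call. = FALSE)
    }
  }
  structure(list(data = data, axes = axes, calibration = calibration),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat("<image_stack> ", paste(x$axes, dim(x$data), sep = "=", collapse = " "),
      "\n  intensity range [", format(min(x$data)), ", ",
      format(max(x$data)), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

axis_index <- function(stack, axis) {
  i <- match(axis, stack$axes)
  if (is.na(i)) stop(sprintf("stack has no `%s` axis", axis), call. = FALSE)
  i
}

#' Extract a 2D plane or sub-stack along named axes
#'
#' Indexes an [image_stack] by axis name, dropping each axis that is
#' reduced to a single coordinate. `get_plane()` is a convenience wrapper
#' that checks the result is a single `y` by `x` matrix.
#'
#' @param stack an [image_stack].
#' @param ... named scalar indices, e.g. `channel = 2`, `time = 5`.
#' @return `slice_stack()` an [image_stack]; `get_plane()` a numeric matrix.
#' @export
slice_stack <- function(stack, ...) {
  idx <- list(...)
  if (length(idx) == 0) return(stack)
  if (is.null(names(idx)) || any(names(idx) == "")) {
    stop("slice indices must be named by axis", call. = FALSE)
  }
  sel <- lapply(dim(stack$data), seq_len)
  drop_axes <- character(0)
  for (ax in names(idx)) {
    i <- axis_index(stack, ax)
    if (length(idx[[ax]]) != 1) stop("slice indices must be scalars", call. = FALSE)
    sel[[i]] <- idx[[ax]]
    drop_axes <- c(drop_axes, ax)
  }
  out <- do.call(`[`, c(list(stack$data), sel, list(drop = FALSE)))
  keep <- !(stack$axes %in% drop_axes)
  out <- array(out, dim = dim(stack$data)[keep])
  cal <- stack$calibration
  if (!is.null(cal)) cal <- cal[names(cal) %in% stack$axes[keep]]
  if (!is.null(cal) && length(cal) == 0) cal <- NULL
  image_stack(out, stack$axes[keep], cal)
}

#' @rdname slice_stack
#' @export
get_plane <- function(stack, ...) {
  s <- slice_stack(stack, ...)
  if (!identical(s$axes, c("y", "x"))) {
    stop("slice does not reduce to a single y-x plane", call. = FALSE)
  }
  matrix(s$data, nrow = dim(s$data)[1], ncol = dim(s$data)[2])
}

#' Write and read image stacks as multi-page 16-bit TIFF
#'
#' Intensities are stored as 16-bit TIFF pages. Because TIFF holds values
#' in `[0, 1]`, intensities are divided by `scale` on write and multiplied
#' back on read; the scale, axis order and page layout are recorded in a
#' JSON sidecar (`<path>.json`) so a round trip restores the stack (up to
#' 16-bit quantization). Pages enumerate all non-spatial axes in
#' column-major order.
#'
#' @param stack an [image_stack].
#' @param path output TIFF file path.
#' @param scale intensity corresponding to the 16-bit ceiling; defaults to
#'   the smallest power of two not below the data maximum (min 1).
#' @return `write_stack_tiff()` returns `path` invisibly;
#'   `read_stack_tiff()` returns an [image_stack].
#' @export
write_stack_tiff <- function(stack, path, scale = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(scale)) scale <- max(1, 2^ceiling(log2(max(stack$data, 1e-12))))
  d <- stack$data
  yi <- axis_index(stack, "y"); xi <- axis_index(stack, "x")
  other <- setdiff(seq_along(dim(d)), c(yi, xi))
  perm <- c(yi, xi, other)
  d <- aperm(d, perm)
  npage <- prod(dim(d)[-(1:2)], 1)
  dim(d) <- c(dim(d)[1], dim(d)[2], npage)
  pages <- lapply(seq_len(npage), function(k) pmin(d[, , k] / scale, 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(axes = stack$axes, dim = dim(stack$data), scale = scale,
               page_axes = stack$axes[other],
               calibration = as.list(stack$calibration))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  d <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  axes <- meta$axes
  yi <- match("y", axes); xi <- match("x", axes)
  other <- setdiff(seq_along(axes), c(yi, xi))
  dim(d) <- c(meta$dim[yi], meta$dim[xi], meta$dim[other])
  d <- aperm(d, order(c(yi, xi, other)))
  cal <- meta$calibration
  if (!is.null(cal)) cal <- unlist(cal)
  if (length(cal) == 0) cal <- NULL
  image_stack(d * meta$scale, axes, cal)
}
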