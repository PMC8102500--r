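#' Configuration for foci segmentation
#'
#' Percentile-threshold + size-filter parameters for punctate object
#' counting. Defaults follow the chromocenter settings: threshold at the
#' 99.5th percentile of the within-nucleus stack histogram and a voxel
#' volume window of `[7, 2000]` (both bounds inclusive), with an opaque
#' voxel calibration `(x = 0.075, y = 0.075, z = 0.029)` used only to
#' report calibrated volumes alongside raw voxel counts — the volume
#' filter itself is applied in voxels.
#'
#' @param threshold_percentile percentile of the intensity histogram, in
#'   `(0, 100)`.
#' @param min_volume,max_volume inclusive voxel-volume window.
#' @param voxel_calibration named numeric `(x, y, z)` scale factors.
#' @param connectivity 26 (default) or 6 for 3D; 8 or 4 for 2D spots.
#' @param histogram `"nucleus"` (percentile over within-nucleus voxels,
#'   default) or `"stack"` (whole stack).
#' @return object of class `foci_config`.
#' @export
foci_config <- function(threshold_percentile = 99.5, min_volume = 7,
                        max_volume = 2000,
                        voxel_calibration = c(x = 0.075, y = 0.075, z = 0.029),
                        connectivity = 26,
                        histogram = c("nucleus", "stack")) {
  if (threshold_percentile <= 0 || threshold_percentile >= 100) {
    stop("threshold_percentile must be in (0, 100)", call. = FALSE)
  }
  if (min_volume <= 0 || min_volume > max_volume) {
    stop("need 0 < min_volume <= max_volume", call. = FALSE)
  }
  structure(list(threshold_percentile = threshold_percentile,
                 min_volume = min_volume, max_volume = max_volume,
                 voxel_calibration = voxel_calibration,
                 connectivity = connectivity,
                 histogram = match.arg(histogram)),
            class = "foci_config")
}

#' Segment chromocenters in a 3D stack
#'
#' Within each nucleus: the intensity threshold is the configured
#' percentile of the within-nucleus voxel histogram (or of the whole
#' stack); voxels strictly above the threshold are labeled into connected
#' components (26-neighborhood by default); components whose voxel volume
#' falls outside the inclusive `[min_volume, max_volume]` window are
#' discarded. The percentile threshold is scale-free, so counting is
#' invariant to intensity rescaling.
#'
#' @param stack 3D [image_stack] (axes `y, x, z`) or array.
#' @param nucleus_mask logical or label array congruent with `stack`;
#'   each positive label is one nucleus.
#' @param config a [foci_config].
#' @return tibble, one row per nucleus: `parent_id, foci_count, volumes`
#'   (list column of voxel counts), `volumes_calibrated` (list column,
#'   voxel counts times the product of the calibration factors),
#'   `mean_volume, threshold`. A nucleus smaller than `min_volume` yields
#'   an empty record with a warning.
#' @export
segment_chromocenters <- function(stack, nucleus_mask, config = foci_config()) {
  stopifnot(inherits(config, "foci_config"))
  arr <- if (inherits(stack, "image_stack")) stack$data else stack
  if (length(dim(arr)) != 3) stop("stack must be 3D", call. = FALSE)
  nm <- unclass(nucleus_mask)
  if (is.logical(nm)) nm <- nm * 1L
  if (!identical(dim(arr), dim(nm))) stop("stack and mask are not congruent", call. = FALSE)
  ids <- sort(unique(as.vector(nm))); ids <- ids[ids > 0]
  if (length(ids) == 0) stop("nucleus mask is empty", call. = FALSE)
  vox_scale <- prod(config$voxel_calibration)
  rows <- lapply(ids, function(id) {
    inside <- nm == id
    n_inside <- sum(inside)
    if (n_inside < config$min_volume) {
      warning(sprintf("nucleus %d smaller than min_volume; empty record", id),
              call. = FALSE)
      return(tibble::tibble(parent_id = id, foci_count = 0L,
                            volumes = list(integer(0)),
                            volumes_calibrated = list(numeric(0)),
                            mean_volume = NA_real_, threshold = NA_real_))
    }
    hist_vox <- if (config$histogram == "nucleus") arr[inside] else as.vector(arr)
    thr <- stats::quantile(hist_vox, config$threshold_percentile / 100,
                           names = FALSE)
    fg <- inside & arr > thr
    lab <- label_components(fg, connectivity = config$connectivity)
    vols <- label_sizes(lab)
    keep <- vols >= config$min_volume & vols <= config$max_volume
    vols <- unname(vols[keep])
    tibble::tibble(parent_id = id, foci_count = length(vols),
                   volumes = list(as.integer(vols)),
                   volumes_calibrated = list(vols * vox_scale),
                   mean_volume = if (length(vols)) mean(vols) else NA_real_,
                   threshold = thr)
  })
  dplyr::bind_rows(rows)
}

#' Count proximity-ligation (PLA) foci per cell
#'
#' Counts punctate spots in a 2D image (or the maximum projection of a
#' thin z-stack) within each cell of a label mask segmented from the
#' reporter channel. Spots are connected components strictly above the
#' configured percentile of the within-cell histogram, filtered by an
#' inclusive 2D area window. Two spots closer than the resolution of the
#' connectivity merge into one component and are counted once.
#'
#' @param spot_image 2D [image_stack]/matrix, or 3D stack (max-projected
#'   over `z` first).
#' @param cell_mask 2D label matrix from [segment_objects] on the
#'   reporter channel.
#' @param config a [foci_config]; `min_volume`/`max_volume` are read as
#'   pixel areas, 2D connectivity 8 unless `config$connectivity` is 4.
#' @return tibble: `cell_id, foci_count, areas` (list column),
#'   `threshold`.
#' @export
count_pla_foci <- function(spot_image, cell_mask,
                           config = foci_config(min_volume = 2, max_volume = 500)) {
  arr <- if (inherits(spot_image, "image_stack")) spot_image$data else spot_image
  if (length(dim(arr)) == 3) arr <- apply(arr, c(1, 2), max)
  arr <- as.matrix(arr)
  cm <- unclass(cell_mask)
  if (!identical(dim(arr), dim(cm))) stop("image and cell mask are not congruent", call. = FALSE)
  ids <- sort(unique(as.vector(cm))); ids <- ids[ids > 0]
  if (length(ids) == 0) stop("no cells detected", call. = FALSE)
  conn2d <- if (config$connectivity %in% c(4, 8)) config$connectivity else 8
  rows <- lapply(ids, function(id) {
    inside <- cm == id
    hist_px <- if (config$histogram == "nucleus") arr[inside] else as.vector(arr)
    thr <- stats::quantile(hist_px, config$threshold_percentile / 100,
                           names = FALSE)
    fg <- inside & arr > thr
    lab <- label_components(fg, connectivity = conn2d)
    areas <- label_sizes(lab)
    keep <- areas >= config$min_volume & areas <= config$max_volume
    areas <- unname(areas[keep])
    tibble::tibble(cell_id = id, foci_count = length(areas),
                   areas = list(as.integer(areas)), threshold = thr)
  })
  dplyr::bind_rows(rows)
}

#' Normalize foci counts to a control condition
#'
#' Divides every per-cell count by the mean count of the control
#' condition (e.g. cells incubated with a single antibody), so the
#' control's mean fold is exactly 1.
#'
#' @param counts tibble with columns `condition` and `foci_count`.
#' @param control name of the control condition present in `counts`.
#' @return list with `per_cell` (counts plus `fold`) and `summary`
#'   (per-condition mean fold ± s.e.m. and n).
#' @export
normalize_foci <- function(counts, control) {
  stopifnot(all(c("condition", "foci_count") %in% names(counts)))
  ctrl <- counts$foci_count[counts$condition == control]
  if (length(ctrl) == 0) stop("control condition not found", call. = FALSE)
  m <- mean(ctrl)
  if (!is.finite(m) || m <= 0) {
    stop("control mean count must be positive", call. = FALSE)
  }
  per_cell <- dplyr::mutate(counts, fold = .data$foci_count / m)
  summary <- per_cell |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(n = dplyr::n(), mean_fold = mean(.data$fold),
                     sem = sem(.data$fold), .groups = "drop")
  list(per_cell = per_cell, summary = summary, control_mean = m)
}
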