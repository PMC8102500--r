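#' Per-nucleus nuclear-envelope : nucleoplasm intensity ratio
#'
#' The headline readout for inner-nuclear-membrane protein redistribution:
#' the arithmetic mean of the marker intensity over the rim band divided
#' by the mean over the nucleoplasm core of the same nucleus. No
#' background subtraction is applied unless `background` is given (then it
#' is subtracted from both means before the ratio).
#'
#' @param intensity single-channel image: matrix or 2D [image_stack],
#'   congruent with the partition's source mask.
#' @param partition a [partition_rim_nucleoplasm] result.
#' @param condition condition label carried into downstream summaries.
#' @param background optional scalar background estimate to subtract.
#' @param threshold enrichment classification threshold (ratio above it =
#'   NE enriched).
#' @return one-row tibble: `object_id, rim_mean, nucleoplasm_mean, ratio,
#'   category, valid, condition`. A non-positive nucleoplasm mean flags
#'   the measurement invalid (`valid = FALSE`, `ratio = NA`) instead of
#'   erroring, so callers can count exclusions.
#' @export
measure_ne_ratio <- function(intensity, partition, condition = NA_character_,
                             background = 0, threshold = 1.2) {
  img <- if (inherits(intensity, "image_stack")) {
    get_plane(intensity)
  } else intensity
  stopifnot(inherits(partition, "region_partition"))
  if (!identical(dim(img), partition$shape)) {
    stop("intensity image and partition mask are not congruent", call. = FALSE)
  }
  rim_mean <- mean(img[partition$rim]) - background
  np_mean <- mean(img[partition$nucleoplasm]) - background
  valid <- is.finite(np_mean) && np_mean > 0
  ratio <- if (valid) rim_mean / np_mean else NA_real_
  tibble::tibble(object_id = partition$object_id,
                 rim_mean = rim_mean, nucleoplasm_mean = np_mean,
                 ratio = ratio,
                 category = if (valid) classify_enrichment(ratio, threshold)
                            else NA_character_,
                 valid = valid, condition = condition)
}

#' Classify nuclear-envelope enrichment from the rim:nucleoplasm ratio
#'
#' Ratios strictly above the threshold (default 1.2) are classified
#' `"Nuclear envelope enriched"`; everything else — including a ratio of
#' exactly 1.2 — is `"diffuse in the nucleus"`.
#'
#' @param ratio numeric vector of finite, positive ratios.
#' @param threshold classification cutoff.
#' @return character vector with the two category labels.
#' @export
classify_enrichment <- function(ratio, threshold = 1.2) {
  if (anyNA(ratio) || !all(is.finite(ratio))) {
    stop("ratio must be finite", call. = FALSE)
  }
  ifelse(ratio > threshold, "Nuclear envelope enriched", "diffuse in the nucleus")
}

#' Summarize enrichment fractions per condition
#'
#' Aggregates per-cell measurements to per-replicate enriched fractions,
#' then reports, per condition, the pooled cell count, the mean fraction
#' across replicates and its standard error (n = replicates, not cells —
#' the dispersion reported is biological, across independent
#' experiments).
#'
#' @param measurements tibble from [measure_ne_ratio] rows, with added
#'   `replicate` column; invalid measurements are dropped and counted.
#' @return list with `summary` (per-condition tibble: `condition, n_cells,
#'   n_replicates, fraction_enriched, sem`), `per_replicate` tibble and
#'   `n_excluded`.
#' @export
summarize_condition <- function(measurements) {
  stopifnot(all(c("condition", "replicate", "category", "valid") %in%
                  names(measurements)))
  n_excluded <- sum(!measurements$valid)
  ok <- dplyr::filter(measurements, .data$valid)
  if (nrow(ok) == 0) {
    stop(sprintf("no valid measurements (%d excluded)", n_excluded), call. = FALSE)
  }
  per_rep <- ok |>
    dplyr::group_by(.data$condition, .data$replicate) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     fraction_enriched = mean(.data$category == "Nuclear envelope enriched"),
                     .groups = "drop")
  summary <- per_rep |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(n_cells = sum(.data$n_cells),
                     n_replicates = dplyr::n(),
                     sem = sem(.data$fraction_enriched),
                     fraction_enriched = mean(.data$fraction_enriched),
                     .groups = "drop") |>
    dplyr::select("condition", "n_cells", "n_replicates",
                  "fraction_enriched", "sem")
  list(summary = summary, per_replicate = per_rep, n_excluded = n_excluded)
}

#' Measure every nucleus of a segmented image
#'
#' Convenience wrapper: partitions each label of `mask` and measures the
#' NE:nucleoplasm ratio on the marker channel.
#'
#' @param marker marker-channel matrix or 2D [image_stack].
#' @param mask label matrix from [segment_objects].
#' @inheritParams partition_rim_nucleoplasm
#' @inheritParams measure_ne_ratio
#' @return tibble of per-nucleus measurements; degenerate objects are
#'   reported in the `degenerate` attribute.
#' @export
measure_all_nuclei <- function(marker, mask, rim_distance_px = 0, rim_width_px = 3,
                               condition = NA_character_, threshold = 1.2) {
  parts <- partition_all(mask, rim_distance_px, rim_width_px)
  rows <- lapply(parts$partitions, function(p) {
    measure_ne_ratio(marker, p, condition = condition, threshold = threshold)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "degenerate") <- parts$degenerate
  out
}
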