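#' Pearson correlation between two channels within a mask
#'
#' Sample Pearson correlation over the pixel pairs selected by `mask`.
#' Invariant under positive affine rescaling of either channel; flips
#' sign under negation.
#'
#' @param ch1,ch2 congruent single-channel matrices (or 2D
#'   [image_stack]s).
#' @param mask logical matrix or vector of linear pixel indices.
#' @param min_pixels minimum mask size (default 50) to bound the
#'   coefficient's sampling variance.
#' @return the correlation coefficient (length-1 numeric).
#' @export
compute_pcc <- function(ch1, ch2, mask, min_pixels = 50) {
  m1 <- if (inherits(ch1, "image_stack")) get_plane(ch1) else ch1
  m2 <- if (inherits(ch2, "image_stack")) get_plane(ch2) else ch2
  if (!identical(dim(m1), dim(m2))) stop("channels are not congruent", call. = FALSE)
  px <- if (is.logical(mask)) which(mask) else as.integer(mask)
  if (length(px) < min_pixels) {
    stop(sprintf("mask has %d pixels; minimum is %d", length(px), min_pixels),
         call. = FALSE)
  }
  v1 <- m1[px]; v2 <- m2[px]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    stop("correlation undefined: a channel is constant within the mask",
         call. = FALSE)
  }
  stats::cor(v1, v2)
}

#' Pearson correlation under a 90-degree rotation null
#'
#' Destroys the spatial registration of the second channel while
#' preserving its marginal intensity distribution: channel 2 is cropped to
#' the mask's bounding box, rotated by a multiple of 90 degrees about the
#' box center (a pure index permutation — no interpolation), recomposed
#' into the frame, and the correlation is recomputed over the
#' intersection of the original mask with the rotated crop's footprint.
#' Four successive 90-degree rotations (or `angle = 0`) restore the
#' observed coefficient exactly.
#'
#' @inheritParams compute_pcc
#' @param angle rotation in degrees; must be a multiple of 90 (clockwise).
#' @return list with `pcc` and `n_pixels` (size of the overlap used).
#' @export
rotation_null_pcc <- function(ch1, ch2, mask, angle = 90, min_pixels = 50) {
  m1 <- if (inherits(ch1, "image_stack")) get_plane(ch1) else ch1
  m2 <- if (inherits(ch2, "image_stack")) get_plane(ch2) else ch2
  if (!identical(dim(m1), dim(m2))) stop("channels are not congruent", call. = FALSE)
  if (angle %% 90 != 0) stop("angle must be a multiple of 90 degrees", call. = FALSE)
  k <- (as.integer(angle / 90)) %% 4L
  mm <- if (is.logical(mask)) mask else {
    z <- matrix(FALSE, nrow(m1), ncol(m1)); z[as.integer(mask)] <- TRUE; z
  }
  if (!any(mm)) stop("empty mask", call. = FALSE)
  rr <- range(which(rowSums(mm) > 0))
  cc <- range(which(colSums(mm) > 0))
  sub <- m2[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  rot <- sub
  for (i in seq_len(k)) rot <- rot90_cw(rot)
  # place the rotated crop so its center coincides with the bbox center
  r1 <- rr[1] + floor((nrow(sub) - nrow(rot)) / 2)
  c1 <- cc[1] + floor((ncol(sub) - ncol(rot)) / 2)
  canvas <- matrix(NA_real_, nrow(m2), ncol(m2))
  ys <- r1:(r1 + nrow(rot) - 1)
  xs <- c1:(c1 + ncol(rot) - 1)
  yok <- ys >= 1 & ys <= nrow(m2)
  xok <- xs >= 1 & xs <= ncol(m2)
  canvas[ys[yok], xs[xok]] <- rot[which(yok), which(xok), drop = FALSE]
  valid <- which(mm & !is.na(canvas))
  if (length(valid) < min_pixels) {
    stop(sprintf("rotation overlap has %d pixels; minimum is %d",
                 length(valid), min_pixels), call. = FALSE)
  }
  v1 <- m1[valid]; v2 <- canvas[valid]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    stop("correlation undefined: a channel is constant within the overlap",
         call. = FALSE)
  }
  list(pcc = stats::cor(v1, v2), n_pixels = length(valid))
}

#' Observed and rotation-null colocalization for one cell
#'
#' @inheritParams rotation_null_pcc
#' @param cell_id identifier carried into the output row.
#' @return one-row tibble: `cell_id, pcc_observed, pcc_rotated, n_pixels,
#'   n_pixels_rotated`.
#' @export
measure_coloc <- function(ch1, ch2, mask, cell_id = 1, angle = 90,
                          min_pixels = 50) {
  obs <- compute_pcc(ch1, ch2, mask, min_pixels)
  rot <- rotation_null_pcc(ch1, ch2, mask, angle, min_pixels)
  px <- if (is.logical(mask)) sum(mask) else length(mask)
  tibble::tibble(cell_id = cell_id, pcc_observed = obs, pcc_rotated = rot$pcc,
                 n_pixels = px, n_pixels_rotated = rot$n_pixels)
}

#' Paired comparison of observed versus rotation-null correlations
#'
#' Paired two-tailed t test of per-cell `pcc_observed` against
#' `pcc_rotated`, with per-group means and s.e.m. When every pair is
#' identical the test statistic is undefined; the p value is reported as
#' `NA` with a note rather than an error.
#'
#' @param measurements tibble of [measure_coloc] rows (>= 3 cells).
#' @return list with `test` (tibble: estimate, statistic, p, stars, n)
#'   and `groups` (mean ± s.e.m. per configuration).
#' @export
paired_coloc_test <- function(measurements) {
  stopifnot(all(c("pcc_observed", "pcc_rotated") %in% names(measurements)))
  if (anyNA(measurements$pcc_observed) || anyNA(measurements$pcc_rotated)) {
    stop("mismatched pairs: missing coefficients", call. = FALSE)
  }
  n <- nrow(measurements)
  if (n < 3) stop("need >= 3 cells for the paired comparison", call. = FALSE)
  diffs <- measurements$pcc_observed - measurements$pcc_rotated
  res <- if (stats::sd(diffs) > 0) {
    stats::t.test(measurements$pcc_observed, measurements$pcc_rotated,
                  paired = TRUE, alternative = "two.sided")
  } else NULL
  p <- if (is.null(res)) NA_real_ else unname(res$p.value)
  stat <- if (is.null(res)) NA_real_ else unname(res$statistic)
  note <- if (is.null(res)) "zero variance of paired differences" else NA_character_
  list(test = tibble::tibble(mean_difference = mean(diffs), statistic = stat,
                             p = p, stars = signif_stars(p), n = n,
                             note = note),
       groups = tibble::tibble(
         configuration = c("observed", "rotated"),
         mean_pcc = c(mean(measurements$pcc_observed),
                      mean(measurements$pcc_rotated)),
         sem = c(sem(measurements$pcc_observed), sem(measurements$pcc_rotated))))
}
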