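#' FRAP regions of interest
#'
#' Holds the three pixel sets of a FRAP measurement: the bleached region,
#' the whole fluorescent structure containing it, and a background region
#' (camera offset) outside the structure. Optionally the unbleached
#' remainder is derived (`total` minus `bleach`) for flow accounting.
#'
#' @param bleach,total,background integer vectors of linear pixel indices
#'   into a `y, x` frame of shape `shape`.
#' @param shape frame shape `(ny, nx)`.
#' @return object of class `frap_rois`.
#' @export
frap_rois <- function(bleach, total, background, shape) {
  stopifnot(length(bleach) > 0, length(total) > 0, length(background) > 0)
  npx <- prod(shape)
  if (max(bleach, total, background) > npx || min(bleach, total, background) < 1) {
    stop("ROI indices outside the frame extent", call. = FALSE)
  }
  if (!all(bleach %in% total)) {
    stop("bleach ROI must lie inside the total-structure ROI", call. = FALSE)
  }
  if (length(intersect(background, total)) > 0) {
    stop("background ROI must not intersect the structure", call. = FALSE)
  }
  structure(list(bleach = as.integer(bleach), total = as.integer(total),
                 unbleached = setdiff(as.integer(total), as.integer(bleach)),
                 background = as.integer(background), shape = as.integer(shape)),
            class = "frap_rois")
}

new_frap_trace <- function(df, areas = NULL) {
  stopifnot(all(c("t", "phase", "I_bleach", "I_total", "I_background") %in% names(df)))
  if (is.unsorted(df$t, strictly = TRUE)) {
    stop("time base must be strictly increasing", call. = FALSE)
  }
  structure(tibble::as_tibble(df), class = c("frap_trace", class(tibble::tibble())),
            areas = areas)
}

#' Extract mean-intensity traces from a registered FRAP series
#'
#' Computes the per-frame arithmetic mean over each ROI. Frames with
#' `t < 0` are prebleach; the bleach pulse occupies the gap before
#' `t = 0`, whose first frame is the earliest postbleach frame.
#'
#' @param series registered [image_stack] with axes `y, x, time`.
#' @param rois a [frap_rois].
#' @param times numeric frame times in seconds relative to the end of the
#'   bleach pulse (negative = prebleach). Default: frames at 1 s spacing
#'   with a single prebleach frame is not assumed — `times` is required.
#' @return a `frap_trace` tibble: `t, phase, I_bleach, I_unbleached,
#'   I_total, I_background`, with ROI pixel areas in the `areas`
#'   attribute.
#' @export
extract_traces <- function(series, rois, times) {
  stopifnot(inherits(rois, "frap_rois"))
  arr <- if (inherits(series, "image_stack")) {
    if (!identical(series$axes, c("y", "x", "time"))) {
      stop("series must have axes y, x, time", call. = FALSE)
    }
    series$data
  } else series
  d <- dim(arr)
  if (!identical(as.integer(d[1:2]), rois$shape)) {
    stop("ROIs outside the frame extent", call. = FALSE)
  }
  if (length(times) != d[3]) stop("one time per frame required", call. = FALSE)
  flat <- matrix(arr, nrow = prod(d[1:2]), ncol = d[3])
  roi_mean <- function(px) colMeans(flat[px, , drop = FALSE])
  new_frap_trace(
    tibble::tibble(t = times,
                   phase = ifelse(times < 0, "prebleach", "postbleach"),
                   I_bleach = roi_mean(rois$bleach),
                   I_unbleached = roi_mean(rois$unbleached),
                   I_total = roi_mean(rois$total),
                   I_background = roi_mean(rois$background)),
    areas = c(bleach = length(rois$bleach), unbleached = length(rois$unbleached),
              total = length(rois$total), background = length(rois$background)))
}

#' Double normalization of a FRAP trace
#'
#' Applies the standard double-normalization: the background-subtracted
#' bleach-ROI trace, referenced to its prebleach value, divided by the
#' background-subtracted whole-structure trace referenced to its
#' prebleach value,
#' `N(t) = [(I_bleach - I_bg) / (I_bleach(t0) - I_bg(t0))] /
#'         [(I_total - I_bg) / (I_total(t0) - I_bg(t0))]`.
#' The second factor cancels acquisition bleaching (and, with it, the
#' signal removed by the bleach pulse itself), so `N` is invariant to
#' affine intensity rescaling of the acquisition. The prebleach reference
#' `t0` is either the mean over all prebleach frames (default, lower
#' variance) or the last prebleach frame.
#'
#' @param trace a `frap_trace`.
#' @param t0 `"prebleach_mean"` or `"last_prebleach"`.
#' @return the trace with a `N` column added; frames whose total-signal
#'   denominator is not positive get `N = NA` and are counted in the
#'   `n_excluded_frames` attribute. `N` at the reference is 1 by
#'   construction.
#' @export
double_normalize <- function(trace, t0 = c("prebleach_mean", "last_prebleach")) {
  t0 <- match.arg(t0)
  stopifnot(inherits(trace, "frap_trace"))
  pre <- trace$phase == "prebleach"
  if (!any(pre)) stop("no prebleach frames", call. = FALSE)
  ref <- function(v) {
    if (t0 == "prebleach_mean") mean(v[pre]) else v[pre][sum(pre)]
  }
  b0 <- ref(trace$I_bleach) - ref(trace$I_background)
  T0 <- ref(trace$I_total) - ref(trace$I_background)
  if (b0 <= 0 || T0 <= 0) {
    stop("prebleach reference signal must exceed background", call. = FALSE)
  }
  num <- (trace$I_bleach - trace$I_background) / b0
  den <- (trace$I_total - trace$I_background) / T0
  bad <- !(den > 0)
  N <- num / den
  N[bad] <- NA_real_
  out <- trace
  out$N <- N
  attr(out, "areas") <- attr(trace, "areas")
  attr(out, "t0") <- t0
  attr(out, "n_excluded_frames") <- sum(bad)
  if (any(bad)) {
    message(sum(bad), " frame(s) excluded: non-positive normalization denominator")
  }
  out
}

#' Fit a single-exponential recovery to a normalized FRAP curve
#'
#' Fits `N(t) = D + (plateau - D) * (1 - exp(-k t))` to the postbleach
#' part of a double-normalized trace by bounded nonlinear least squares
#' and reports the mobile fraction `M = (plateau - D) / (1 - D)`, the rate
#' `k` and the half-time `t_half = ln 2 / k`. The postbleach depth `D` is
#' fixed to the first postbleach value (default) or co-fitted.
#'
#' @param trace a `frap_trace` with an `N` column (see
#'   [double_normalize]), or a data frame with columns `t` and `N` whose
#'   `t >= 0` rows are the postbleach curve.
#' @param fix_depth fix `D` at the first postbleach value (`TRUE`) or
#'   co-fit it.
#' @param min_frames minimum number of postbleach frames.
#' @return object of class `frap_fit`: list with `mobile_fraction`,
#'   `rate`, `t_half`, `plateau`, `depth`, `residual_norm`, `n_frames`
#'   and the underlying `fit` object.
#' @examples
#' t <- 0:200
#' N <- 0.4 + 0.5 * (1 - exp(-0.05 * t))
#' fit_recovery(data.frame(t = t, N = N))
#' @export
fit_recovery <- function(trace, fix_depth = TRUE, min_frames = 10) {
  df <- as.data.frame(trace)[, c("t", "N")]
  df <- df[df$t >= 0 & is.finite(df$N), ]
  if (nrow(df) < min_frames) {
    stop(sprintf("need >= %d postbleach frames, got %d", min_frames, nrow(df)),
         call. = FALSE)
  }
  D0 <- df$N[1]
  if (D0 >= 1) {
    stop("first postbleach value is not below 1; nothing was bleached", call. = FALSE)
  }
  if (diff(range(df$N)) < 1e-10) {
    # flat postbleach trace: no recovery, rate unidentifiable
    return(structure(list(mobile_fraction = 0, rate = NA_real_,
                          t_half = NA_real_, plateau = D0, depth = D0,
                          residual_norm = 0, n_frames = nrow(df), fit = NULL),
                     class = "frap_fit"))
  }
  plateau0 <- stats::median(utils::tail(df$N, max(5, nrow(df) %/% 10)))
  plateau0 <- min(max(plateau0, D0 + 1e-3), 1.5)
  # initial rate from the time at which half the recovery is reached
  half <- D0 + (plateau0 - D0) / 2
  i_half <- which(df$N >= half)
  k0 <- if (length(i_half) && df$t[min(i_half)] > 0) log(2) / df$t[min(i_half)] else 0.05
  k0 <- min(max(k0, 1e-4), 10)

  fit <- tryCatch({
    if (fix_depth) {
      minpack.lm::nlsLM(N ~ D0 + (plateau - D0) * (1 - exp(-k * t)),
                        data = df, start = list(plateau = plateau0, k = k0),
                        lower = c(plateau = 0, k = 1e-6),
                        upper = c(plateau = 2, k = 100),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(N ~ D + (plateau - D) * (1 - exp(-k * t)),
                        data = df,
                        start = list(D = D0, plateau = plateau0, k = k0),
                        lower = c(D = 0, plateau = 0, k = 1e-6),
                        upper = c(D = 1, plateau = 2, k = 100),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) {
    stop("recovery fit did not converge: ", conditionMessage(e), call. = FALSE)
  })
  cf <- stats::coef(fit)
  D <- if (fix_depth) D0 else unname(cf["D"])
  plateau <- unname(cf["plateau"])
  k <- unname(cf["k"])
  M <- (plateau - D) / (1 - D)
  if (M < 0) {
    warning("plateau below postbleach depth; mobile fraction clipped to 0",
            call. = FALSE)
    M <- 0
  }
  if (M > 1) M <- 1
  structure(list(mobile_fraction = M, rate = k, t_half = log(2) / k,
                 plateau = plateau, depth = D,
                 residual_norm = sqrt(mean(stats::resid(fit)^2)),
                 n_frames = nrow(df), fit = fit),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("<frap_fit> M = %.4f | k = %.5f /s | t_half = %.2f s | plateau = %.4f | D = %.4f | rms resid = %.3g\n",
              x$mobile_fraction, x$rate, x$t_half, x$plateau, x$depth,
              x$residual_norm))
  invisible(x)
}

#' Average normalized FRAP curves
#'
#' Resamples every curve onto a common time base (by linear
#' interpolation, restricted to the overlap of all series), then reports
#' the pointwise mean and s.e.m., plus a recovery fit of the mean curve.
#'
#' @param traces list of double-normalized `frap_trace`s (or data frames
#'   with `t` and `N`).
#' @param grid optional common time base; default is the first trace's
#'   postbleach-and-prebleach grid clipped to the common time range.
#' @param fit fit the mean curve (logical).
#' @return list with `curve` (tibble `t, mean, sem, n`) and `fit` (a
#'   `frap_fit` or `NULL`). With a single trace the s.e.m. is `NA`.
#' @export
average_curves <- function(traces, grid = NULL, fit = TRUE) {
  stopifnot(length(traces) >= 1)
  dfs <- lapply(traces, function(tr) {
    df <- as.data.frame(tr)[, c("t", "N")]
    df[is.finite(df$N), ]
  })
  if (is.null(grid)) {
    lo <- max(vapply(dfs, function(d) min(d$t), numeric(1)))
    hi <- min(vapply(dfs, function(d) max(d$t), numeric(1)))
    grid <- dfs[[1]]$t[dfs[[1]]$t >= lo & dfs[[1]]$t <= hi]
  }
  vals <- vapply(dfs, function(d) stats::approx(d$t, d$N, xout = grid)$y,
                 numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  curve <- tibble::tibble(t = grid,
                          mean = rowMeans(vals),
                          sem = apply(vals, 1, sem),
                          n = length(dfs))
  fit_obj <- NULL
  if (fit && sum(grid >= 0) >= 10 && any(grid < 0 | curve$mean < 1)) {
    fit_obj <- tryCatch(fit_recovery(data.frame(t = grid, N = curve$mean)),
                        error = function(e) NULL)
  }
  list(curve = curve, fit = fit_obj)
}

#' Bleached-gain versus unbleached-loss flow accounting
#'
#' Quantifies recovery of the bleached region at the cost of the
#' unbleached region. Both ROI traces are background-corrected and
#' divided by the whole-structure bleaching factor
#' `B(t) = (I_total(t) - I_bg(t)) / (I_total(ref) - I_bg(ref))` (ref =
#' first postbleach frame), then converted to total signal units by their
#' pixel areas. The per-frame transfer is the gain of the bleached ROI
#' since the bleach; the conservation residual is gain minus unbleached
#' loss and should vanish when the two ROIs tile the structure.
#'
#' @param trace a `frap_trace` containing `I_unbleached` (see
#'   [extract_traces] / [make_frap_series]); its `areas` attribute must
#'   satisfy bleach + unbleached = total.
#' @return tibble over postbleach frames: `t, gain, loss, transfer,
#'   residual`.
#' @export
flow_metric <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  if (!"I_unbleached" %in% names(trace)) {
    stop("trace must contain an unbleached-ROI column", call. = FALSE)
  }
  areas <- attr(trace, "areas")
  if (is.null(areas) ||
      !isTRUE(all.equal(unname(areas["bleach"] + areas["unbleached"]),
                        unname(areas["total"])))) {
    stop("bleached and unbleached ROIs must partition the structure", call. = FALSE)
  }
  post <- trace$t >= 0
  if (!any(post)) stop("no postbleach frames", call. = FALSE)
  tb <- trace[post, ]
  A_b <- unname(areas["bleach"]); A_u <- unname(areas["unbleached"])
  Ib <- tb$I_bleach - tb$I_background
  Iu <- tb$I_unbleached - tb$I_background
  It <- tb$I_total - tb$I_background
  B <- It / It[1]
  gain <- A_b * (Ib / B - Ib[1])
  loss <- A_u * (Iu[1] - Iu / B)
  tibble::tibble(t = tb$t, gain = gain, loss = loss,
                 transfer = gain, residual = gain - loss)
}
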