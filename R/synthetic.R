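#' Scene specification for synthetic nuclei images
#'
#' Describes a two-channel (DAPI + marker) field of elliptical nuclei on a
#' dark background. Each nucleus carries a rim shell of configurable width
#' whose marker intensity is `rim_contrast` times the nucleoplasm level,
#' emulating nuclear-envelope enrichment of inner-nuclear-membrane
#' proteins. Nuclei are either given explicitly or placed at random
#' without overlap (margin `min_gap` pixels).
#'
#' @param image_shape integer `(ny, nx)` pixels.
#' @param nuclei optional data frame with columns `cy, cx, ry, rx, theta,
#'   intensity` (center, semi-axes in px, orientation in radians, marker
#'   nucleoplasm level a.u.). If `NULL`, `n_nuclei` nuclei are sampled.
#' @param n_nuclei number of nuclei to sample when `nuclei` is `NULL`.
#' @param radius_range semi-axis sampling range in px.
#' @param intensity marker nucleoplasm level a.u. for sampled nuclei.
#' @param dapi_level DAPI intensity inside nuclei a.u.
#' @param rim_width_px rim shell width in px (inner band measured from the
#'   nucleus boundary).
#' @param rim_contrast rim:nucleoplasm contrast factor r >= 0; `r = 1`
#'   means no rim enrichment.
#' @param foci optional list `(count, volume, intensity)` used by
#'   [make_foci_stack].
#' @param background_level camera background a.u.
#' @param noise_sigma additive Gaussian noise s.d. a.u. (0 disables).
#' @param poisson_scale photons per intensity unit for Poisson shot noise
#'   (`NULL` disables).
#' @param min_gap minimum background gap between sampled nuclei, px.
#' @param seed integer RNG seed; identical specs with identical seeds give
#'   bit-identical images.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(image_shape = c(256, 256),
                       nuclei = NULL,
                       n_nuclei = 8,
                       radius_range = c(12, 18),
                       intensity = 100,
                       dapi_level = 200,
                       rim_width_px = 3,
                       rim_contrast = 1.5,
                       foci = NULL,
                       background_level = 10,
                       noise_sigma = 10,
                       poisson_scale = NULL,
                       min_gap = 3,
                       seed = 1L) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 8))
  if (rim_contrast < 0) stop("rim_contrast must be >= 0", call. = FALSE)
  if (background_level < 0 || noise_sigma < 0 || intensity < 0 || dapi_level < 0) {
    stop("intensities and noise must be non-negative", call. = FALSE)
  }
  if (rim_width_px < 1) stop("rim_width_px must be >= 1", call. = FALSE)
  if (!is.null(nuclei)) {
    req <- c("cy", "cx", "ry", "rx", "theta", "intensity")
    if (!all(req %in% names(nuclei))) {
      stop("`nuclei` needs columns ", paste(req, collapse = ", "), call. = FALSE)
    }
    if (any(pmin(nuclei$ry, nuclei$rx) <= rim_width_px)) {
      stop("rim band wider than a nucleus minor semi-axis", call. = FALSE)
    }
  } else if (radius_range[1] <= rim_width_px) {
    stop("rim band wider than the smallest sampled semi-axis", call. = FALSE)
  }
  structure(list(image_shape = as.integer(image_shape), nuclei = nuclei,
                 n_nuclei = n_nuclei, radius_range = radius_range,
                 intensity = intensity, dapi_level = dapi_level,
                 rim_width_px = as.integer(rim_width_px),
                 rim_contrast = rim_contrast, foci = foci,
                 background_level = background_level,
                 noise_sigma = noise_sigma, poisson_scale = poisson_scale,
                 min_gap = min_gap, seed = as.integer(seed)),
            class = "scene_spec")
}

# Sample non-overlapping ellipse parameters by rejection; deterministic
# under the spec seed (caller wraps in with_seed).
sample_nuclei <- function(spec) {
  ny <- spec$image_shape[1]; nx <- spec$image_shape[2]
  out <- NULL
  tries <- 0
  while ((is.null(out) || nrow(out) < spec$n_nuclei) && tries < 5000) {
    tries <- tries + 1
    ry <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
    rx <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
    rmax <- max(ry, rx)
    cy <- stats::runif(1, rmax + 2, ny - rmax - 1)
    cx <- stats::runif(1, rmax + 2, nx - rmax - 1)
    if (!is.null(out)) {
      dd <- sqrt((out$cy - cy)^2 + (out$cx - cx)^2)
      if (any(dd < rmax + pmax(out$ry, out$rx) + spec$min_gap)) next
    }
    row <- data.frame(cy = cy, cx = cx, ry = ry, rx = rx,
                      theta = stats::runif(1, 0, pi),
                      intensity = spec$intensity)
    out <- rbind(out, row)
  }
  if (is.null(out) || nrow(out) < spec$n_nuclei) {
    stop("could not place requested nuclei without overlap", call. = FALSE)
  }
  out
}

# Binary mask of a rotated ellipse on an ny x nx grid (0-based centers).
ellipse_mask <- function(ny, nx, cy, cx, ry, rx, theta = 0) {
  yy <- matrix(seq_len(ny) - 1, ny, nx)
  xx <- matrix(seq_len(nx) - 1, ny, nx, byrow = TRUE)
  dy <- yy - cy; dx <- xx - cx
  u <- cos(theta) * dy + sin(theta) * dx
  v <- -sin(theta) * dy + cos(theta) * dx
  (u / ry)^2 + (v / rx)^2 <= 1
}

apply_noise <- function(img, spec) {
  d <- dim(img)
  if (!is.null(spec$poisson_scale)) {
    img <- stats::rpois(length(img), lambda = pmax(img, 0) * spec$poisson_scale) /
      spec$poisson_scale
  }
  if (spec$noise_sigma > 0) {
    img <- img + stats::rnorm(length(img), 0, spec$noise_sigma)
  }
  img <- pmax(img, 0)
  dim(img) <- d
  img
}

#' Generate a ground-truthed two-channel nuclei scene
#'
#' Renders the scene described by a [scene_spec]: a DAPI channel that is
#' bright inside every nucleus, and a marker channel equal to the
#' background outside, the nucleoplasm level inside the nucleus core, and
#' `rim_contrast` times that level within the rim shell (the band of
#' pixels within `rim_width_px` of the nucleus boundary, measured by
#' Euclidean distance-to-background). Noise is applied last; ground-truth
#' masks are exact and noise-free.
#'
#' @param spec a [scene_spec].
#' @return list with `image` (an [image_stack], axes `y, x, channel`,
#'   channel 1 = DAPI, channel 2 = marker) and `truth` (list: `labels`
#'   nucleus label matrix, `rim`/`core` label matrices, `nuclei` parameter
#'   table, `rim_contrast`, `rim_width_px`, `seed`).
#' @export
make_nucleus_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    ny <- spec$image_shape[1]; nx <- spec$image_shape[2]
    nuclei <- if (is.null(spec$nuclei)) sample_nuclei(spec) else spec$nuclei
    if (any(pmin(nuclei$ry, nuclei$rx) <= spec$rim_width_px)) {
      stop("rim band wider than a nucleus minor semi-axis", call. = FALSE)
    }
    labels <- matrix(0L, ny, nx)
    rim <- matrix(0L, ny, nx)
    core <- matrix(0L, ny, nx)
    dapi <- matrix(spec$background_level, ny, nx)
    marker <- matrix(spec$background_level, ny, nx)
    for (i in seq_len(nrow(nuclei))) {
      nmask <- ellipse_mask(ny, nx, nuclei$cy[i], nuclei$cx[i],
                            nuclei$ry[i], nuclei$rx[i], nuclei$theta[i])
      if (any(labels[nmask] != 0)) {
        stop("nuclei overlap; respecify centers or min_gap", call. = FALSE)
      }
      dist <- distance_to_background(nmask)
      rim_px <- nmask & dist <= spec$rim_width_px
      core_px <- nmask & dist > spec$rim_width_px
      if (!any(core_px)) {
        stop("rim band wider than a nucleus minor semi-axis", call. = FALSE)
      }
      labels[nmask] <- i
      rim[rim_px] <- i
      core[core_px] <- i
      dapi[nmask] <- spec$dapi_level
      marker[core_px] <- nuclei$intensity[i]
      marker[rim_px] <- nuclei$intensity[i] * spec$rim_contrast
    }
    dapi <- apply_noise(dapi, spec)
    marker <- apply_noise(marker, spec)
    img <- image_stack(array(c(dapi, marker), dim = c(ny, nx, 2)),
                       axes = c("y", "x", "channel"))
    list(image = img,
         truth = list(labels = labels, rim = rim, core = core,
                      nuclei = nuclei, rim_contrast = spec$rim_contrast,
                      rim_width_px = spec$rim_width_px, seed = spec$seed))
  })
}

#' FRAP acquisition specification
#'
#' Parameters of a simulated photobleach-and-recovery experiment. The
#' bleached-region signal follows a reaction-limited single-exponential
#' recovery: with prebleach level `P`, immediate postbleach level
#' `D = postbleach_depth * P`, mobile fraction `M` and rate `k`, the true
#' (acquisition-bleaching-corrected) bleach-ROI signal is
#' `S_b(t) = D + M (P - D) (1 - exp(-k t))` for `t >= 0`; the unbleached
#' region loses exactly the signal the bleached region gains, so the total
#' structure signal is conserved. Acquisition bleaching multiplies all
#' fluorescence by `exp(-beta * (t - t_first))`; the camera background is
#' unaffected. Defaults mirror a 300-frame, 1 s-interval confocal
#' acquisition.
#'
#' @param prebleach_level per-pixel prebleach fluorescence `P`, a.u.
#' @param postbleach_depth fraction of `P` remaining in the bleach ROI at
#'   `t = 0+`; must be in `[0, 1]`.
#' @param mobile_fraction mobile fraction `M` in `[0, 1]`.
#' @param rate recovery rate `k` in 1/s, > 0.
#' @param acquisition_bleach_rate imaging bleach rate `beta` in 1/s, >= 0.
#' @param background_level camera offset a.u.
#' @param n_prebleach,n_postbleach frame counts (postbleach frames start
#'   at `t = 0`, immediately after the bleach pulse).
#' @param frame_interval seconds between frames.
#' @param bleach_duration bleach-pulse length in s (excluded from fits; no
#'   frames are acquired during the pulse).
#' @param drift per-frame drift `(dy, dx)` in px, accumulated linearly
#'   over the series (image mode only).
#' @param noise_sigma_frac trace/pixel Gaussian noise s.d. as a fraction
#'   of `prebleach_level`.
#' @param seed integer RNG seed.
#' @return object of class `frap_spec`.
#' @export
frap_spec <- function(prebleach_level = 100,
                      postbleach_depth = 0.3,
                      mobile_fraction = 0.7,
                      rate = 0.05,
                      acquisition_bleach_rate = 0,
                      background_level = 10,
                      n_prebleach = 10,
                      n_postbleach = 300,
                      frame_interval = 1,
                      bleach_duration = 1,
                      drift = c(0, 0),
                      noise_sigma_frac = 0,
                      seed = 1L) {
  if (postbleach_depth > 1 || postbleach_depth < 0) {
    stop("postbleach_depth must be in [0, 1]", call. = FALSE)
  }
  if (mobile_fraction < 0 || mobile_fraction > 1) {
    stop("mobile_fraction must be in [0, 1]", call. = FALSE)
  }
  if (rate <= 0) stop("rate must be > 0", call. = FALSE)
  if (acquisition_bleach_rate < 0) stop("acquisition_bleach_rate must be >= 0", call. = FALSE)
  stopifnot(n_prebleach >= 1, n_postbleach >= 2, frame_interval > 0)
  structure(list(prebleach_level = prebleach_level,
                 postbleach_depth = postbleach_depth,
                 mobile_fraction = mobile_fraction, rate = rate,
                 acquisition_bleach_rate = acquisition_bleach_rate,
                 background_level = background_level,
                 n_prebleach = as.integer(n_prebleach),
                 n_postbleach = as.integer(n_postbleach),
                 frame_interval = frame_interval,
                 bleach_duration = bleach_duration,
                 drift = drift, noise_sigma_frac = noise_sigma_frac,
                 seed = as.integer(seed)),
            class = "frap_spec")
}

#' Generate a ground-truthed FRAP series
#'
#' In trace mode (`geometry = NULL`) returns noisy mean-intensity traces
#' for the bleach ROI, the unbleached remainder, the whole structure and a
#' background ROI, plus the exact noise-free truth. In image mode a
#' time-lapse [image_stack] is rendered from an elliptical "cell" with a
#' square bleach ROI, with optional per-frame drift.
#'
#' Signal bookkeeping: the bleach ROI covers a fraction `f` of the
#' structure. After the pulse the ROI sits at depth `D`; its recovery is
#' fed by the unbleached region, whose per-pixel signal decreases so that
#' the total structure signal is exactly conserved (up to acquisition
#' bleaching, which multiplies everything).
#'
#' @param spec a [frap_spec].
#' @param geometry `NULL` for trace mode, or a list
#'   `(image_shape, cell_center, cell_semiaxes, bleach_center, bleach_halfwidth)`
#'   in pixels for image mode.
#' @param bleach_fraction fraction of the structure area covered by the
#'   bleach ROI (trace mode only).
#' @return list with `trace` (a [frap_trace]), `truth` (noise-free trace
#'   tibble plus the generating parameters), and in image mode `image`
#'   (axes `y, x, time`), `rois` (a [frap_rois]) and `drift` (per-frame
#'   cumulative offsets).
#' @export
make_frap_series <- function(spec, geometry = NULL, bleach_fraction = 0.02) {
  stopifnot(inherits(spec, "frap_spec"))
  P <- spec$prebleach_level
  D <- spec$postbleach_depth * P
  M <- spec$mobile_fraction
  k <- spec$rate
  beta <- spec$acquisition_bleach_rate
  bg <- spec$background_level
  dt <- spec$frame_interval

  t_pre <- -(spec$n_prebleach:1) * dt - spec$bleach_duration
  t_post <- (seq_len(spec$n_postbleach) - 1) * dt
  t <- c(t_pre, t_post)
  phase <- rep(c("prebleach", "postbleach"), c(length(t_pre), length(t_post)))
  bf <- exp(-beta * (t - t[1]))  # acquisition-bleaching factor per frame

  recov <- M * (P - D) * (1 - exp(-k * pmax(t, 0)))
  s_b <- ifelse(t < 0, P, D + recov)          # bleach ROI, bleach-corrected

  if (is.null(geometry)) {
    f <- bleach_fraction
    stopifnot(f > 0, f < 1)
    # per-pixel unbleached signal from exact conservation of the total
    u <- ifelse(t < 0, P, P - f / (1 - f) * (recov))
    if (min(u) < 0) stop("bleach_fraction too large for full conservation", call. = FALSE)
    tot <- f * s_b + (1 - f) * u
    truth <- tibble::tibble(t = t, phase = phase,
                            I_bleach = bf * s_b + bg,
                            I_unbleached = bf * u + bg,
                            I_total = bf * tot + bg,
                            I_background = bg)
    noisy <- with_seed(spec$seed, {
      sd <- spec$noise_sigma_frac * P
      add <- function(v) if (sd > 0) pmax(v + stats::rnorm(length(v), 0, sd), 0) else v
      tibble::tibble(t = t, phase = phase,
                     I_bleach = add(truth$I_bleach),
                     I_unbleached = add(truth$I_unbleached),
                     I_total = add(truth$I_total),
                     I_background = add(truth$I_background))
    })
    trace <- new_frap_trace(noisy, areas = c(bleach = f, unbleached = 1 - f,
                                             total = 1, background = NA))
    return(list(trace = trace,
                truth = c(list(trace = truth), spec[c("prebleach_level",
                  "postbleach_depth", "mobile_fraction", "rate",
                  "acquisition_bleach_rate", "background_level")],
                  list(bleach_fraction = f, seed = spec$seed))))
  }

  ny <- geometry$image_shape[1]; nx <- geometry$image_shape[2]
  cell <- ellipse_mask(ny, nx, geometry$cell_center[1], geometry$cell_center[2],
                       geometry$cell_semiaxes[1], geometry$cell_semiaxes[2])
  hw <- geometry$bleach_halfwidth
  bc <- geometry$bleach_center
  bl <- matrix(FALSE, ny, nx)
  bl[(bc[1] - hw):(bc[1] + hw), (bc[2] - hw):(bc[2] + hw)] <- TRUE
  bl <- bl & cell
  if (!any(bl)) stop("bleach ROI does not intersect the cell", call. = FALSE)
  A_b <- sum(bl); A_cell <- sum(cell); A_u <- A_cell - A_b
  f <- A_b / A_cell
  u <- ifelse(t < 0, P, P - f / (1 - f) * recov)
  if (min(u) < 0) stop("bleach ROI too large for full conservation", call. = FALSE)

  bg_roi <- matrix(FALSE, ny, nx)
  bg_roi[1:4, 1:4] <- TRUE
  if (any(bg_roi & cell)) stop("cell overlaps the background corner ROI", call. = FALSE)

  nT <- length(t)
  frames <- array(0, dim = c(ny, nx, nT))
  drift_tab <- cbind(dy = round((seq_len(nT) - 1) * spec$drift[1]),
                     dx = round((seq_len(nT) - 1) * spec$drift[2]))
  sd <- spec$noise_sigma_frac * P
  frames <- with_seed(spec$seed, {
    for (j in seq_len(nT)) {
      fr <- matrix(bg, ny, nx)
      fr[cell] <- bg + bf[j] * u[j]
      fr[bl] <- bg + bf[j] * s_b[j]
      fr <- shift_matrix(fr, drift_tab[j, 1], drift_tab[j, 2], fill = bg)
      if (sd > 0) fr <- pmax(fr + stats::rnorm(length(fr), 0, sd), 0)
      frames[, , j] <- fr
    }
    frames
  })
  img <- image_stack(frames, axes = c("y", "x", "time"))
  rois <- frap_rois(bleach = which(bl), total = which(cell),
                    background = which(bg_roi), shape = c(ny, nx))
  truth <- tibble::tibble(t = t, phase = phase,
                          I_bleach = bf * s_b + bg,
                          I_unbleached = bf * u + bg,
                          I_total = bf * (f * s_b + (1 - f) * u) + bg,
                          I_background = bg)
  list(image = img, rois = rois, times = t, drift = drift_tab,
       truth = c(list(trace = truth), spec[c("prebleach_level",
         "postbleach_depth", "mobile_fraction", "rate",
         "acquisition_bleach_rate", "background_level")],
         list(bleach_fraction = f, seed = spec$seed)))
}

#' Generate a two-channel image pair with a target Pearson correlation
#'
#' Inside the cell mask, two spatially correlated Gaussian random fields
#' are mixed as `z2' = rho * z1 + sqrt(1 - rho^2) * z2` (for `|rho| = 1`
#' the independent field is unused, making the correlation exact), then
#' each channel is affinely rescaled to non-negative intensities — an
#' affine map, so the within-mask Pearson correlation is preserved
#' exactly. With `anisotropy = TRUE` the fields are smoothed much more
#' strongly along `y` than along `x`, producing elongated streaks so that
#' a 90-degree rotation null decorrelates the pair.
#'
#' @param rho target correlation in `[-1, 1]`.
#' @param image_shape `(ny, nx)` pixels.
#' @param mask optional logical matrix (cell footprint); default centered
#'   ellipse covering most of the frame. Must contain >= 10 pixels.
#' @param anisotropy logical; elongate the pattern along `y`.
#' @param smooth_sigma isotropic smoothing s.d. in px when
#'   `anisotropy = FALSE`.
#' @param seed integer RNG seed.
#' @return list with `image` (axes `y, x, channel`), `mask`, and `truth`
#'   (`rho`, empirical within-mask correlation of the noise-free pair,
#'   `seed`).
#' @export
make_coloc_pair <- function(rho, image_shape = c(96, 96), mask = NULL,
                            anisotropy = FALSE, smooth_sigma = 2, seed = 1L) {
  if (rho < -1 || rho > 1) stop("rho must be in [-1, 1]", call. = FALSE)
  ny <- image_shape[1]; nx <- image_shape[2]
  if (is.null(mask)) {
    mask <- ellipse_mask(ny, nx, (ny - 1) / 2, (nx - 1) / 2,
                         ny * 0.42, nx * 0.42)
  }
  if (sum(mask) < 10) stop("degenerate mask: fewer than 10 pixels", call. = FALSE)
  with_seed(seed, {
    sy <- if (anisotropy) 8 else smooth_sigma
    sx <- if (anisotropy) 0.6 else smooth_sigma
    field <- function() {
      z <- gauss_smooth(matrix(stats::rnorm(ny * nx), ny, nx), sy, sx)
      (z - mean(z[mask])) / stats::sd(z[mask])
    }
    z1 <- field()
    z2 <- if (abs(rho) == 1) sign(rho) * z1 else
      rho * z1 + sqrt(1 - rho^2) * field()
    to_intensity <- function(z) {
      ch <- 30 * z
      ch <- ch - min(ch[mask]) + 10   # affine shift, correlation-preserving
      out <- matrix(0, ny, nx)
      out[mask] <- ch[mask]
      out
    }
    ch1 <- to_intensity(z1); ch2 <- to_intensity(z2)
    img <- image_stack(array(c(ch1, ch2), dim = c(ny, nx, 2)),
                       axes = c("y", "x", "channel"))
    list(image = img, mask = mask,
         truth = list(rho = rho,
                      empirical_rho = stats::cor(ch1[mask], ch2[mask]),
                      anisotropy = anisotropy, seed = seed))
  })
}

#' Generate a ground-truthed 3D foci stack
#'
#' Places bright connected components ("foci") of exactly the requested
#' voxel volumes inside an ellipsoidal nucleus in a 3D stack. Components
#' are grown by breadth-first search from random seed voxels, so each
#' focus is connected under 6-neighbor (hence also 26-neighbor)
#' connectivity; distinct foci are kept at least `gap` voxels apart in
#' Chebyshev distance so they remain separate components.
#'
#' @param volumes integer vector of focus volumes in voxels (all >= 1).
#' @param stack_shape `(ny, nx, nz)` voxels.
#' @param nucleus one of `"ellipsoid"` (centered, filling ~84% of each
#'   axis) or `"full"` (entire stack is nucleus).
#' @param base_level nucleoplasm intensity a.u.
#' @param focus_level focus intensity a.u. (must exceed `base_level`).
#' @param background_level outside-nucleus intensity a.u.
#' @param noise_sigma additive Gaussian noise s.d. a.u.
#' @param gap minimum Chebyshev separation between foci, voxels.
#' @param seed integer RNG seed.
#' @return list with `image` (axes `y, x, z`), `nucleus_mask` (logical
#'   array), `truth` (tibble `focus_id, volume` plus the exact label
#'   array).
#' @export
make_foci_stack <- function(volumes, stack_shape = c(48, 48, 24),
                            nucleus = c("ellipsoid", "full"),
                            base_level = 100, focus_level = 500,
                            background_level = 10, noise_sigma = 0,
                            gap = 2, seed = 1L) {
  nucleus <- match.arg(nucleus)
  volumes <- as.integer(volumes)
  if (length(volumes) > 0 && any(volumes < 1)) {
    stop("focus volumes must be >= 1 voxel", call. = FALSE)
  }
  if (focus_level <= base_level) stop("focus_level must exceed base_level", call. = FALSE)
  ny <- stack_shape[1]; nx <- stack_shape[2]; nz <- stack_shape[3]
  nmask <- if (nucleus == "full") {
    array(TRUE, dim = stack_shape)
  } else {
    yy <- array(rep(seq_len(ny) - 1, times = nx * nz), dim = stack_shape)
    xx <- array(rep(rep(seq_len(nx) - 1, each = ny), times = nz), dim = stack_shape)
    zz <- array(rep(seq_len(nz) - 1, each = ny * nx), dim = stack_shape)
    ((yy - (ny - 1) / 2) / (0.42 * ny))^2 +
      ((xx - (nx - 1) / 2) / (0.42 * nx))^2 +
      ((zz - (nz - 1) / 2) / (0.42 * nz))^2 <= 1
  }
  if (sum(nmask) < sum(volumes) * 2) {
    stop("foci do not fit inside the nucleus mask", call. = FALSE)
  }
  labels <- array(0L, dim = stack_shape)
  with_seed(seed, {
    blocked <- !nmask
    for (i in seq_along(volumes)) {
      grown <- grow_focus(volumes[i], blocked, stack_shape)
      if (is.null(grown)) stop("foci do not fit inside the nucleus mask", call. = FALSE)
      labels[grown] <- i
      blocked <- blocked | dilate_chebyshev(grown, gap, stack_shape)
    }
    img <- array(background_level, dim = stack_shape)
    img[nmask] <- base_level
    img[labels > 0] <- focus_level
    if (noise_sigma > 0) {
      img <- pmax(img + stats::rnorm(length(img), 0, noise_sigma), 0)
    }
    list(image = image_stack(img, axes = c("y", "x", "z")),
         nucleus_mask = nmask,
         truth = list(table = tibble::tibble(focus_id = seq_along(volumes),
                                             volume = volumes),
                      labels = labels, seed = seed))
  })
}

# BFS-grow a connected set of `vol` voxels avoiding `blocked`; returns
# linear indices or NULL if no seed admits the full volume.
grow_focus <- function(vol, blocked, dims) {
  free <- which(!blocked)
  if (length(free) == 0) return(NULL)
  for (attempt in seq_len(200)) {
    seed_vox <- free[sample.int(length(free), 1)]
    sel <- logical(prod(dims))
    sel[seed_vox] <- TRUE
    frontier <- seed_vox
    count <- 1L
    while (count < vol && length(frontier) > 0) {
      nb <- neighbors6(frontier, dims)
      nb <- unique(nb[!sel[nb] & !blocked[nb]])
      if (length(nb) == 0) break
      take <- utils::head(nb, vol - count)
      sel[take] <- TRUE
      count <- count + length(take)
      frontier <- take
    }
    if (count == vol) return(which(sel))
  }
  NULL
}

# 6-neighborhood of linear indices in a 3D array, clipped at the borders.
neighbors6 <- function(lin, dims) {
  co <- arrayInd(lin, dims)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  out <- integer(0)
  for (k in seq_len(nrow(offs))) {
    nc <- sweep(co, 2, offs[k, ], `+`)
    ok <- nc[, 1] >= 1 & nc[, 1] <= dims[1] &
      nc[, 2] >= 1 & nc[, 2] <= dims[2] &
      nc[, 3] >= 1 & nc[, 3] <= dims[3]
    if (any(ok)) {
      out <- c(out, nc[ok, 1] + (nc[ok, 2] - 1) * dims[1] +
                 (nc[ok, 3] - 1) * dims[1] * dims[2])
    }
  }
  out
}

# Chebyshev dilation of a voxel index set by `r` voxels.
dilate_chebyshev <- function(lin, r, dims) {
  out <- array(FALSE, dim = dims)
  co <- arrayInd(lin, dims)
  for (dz in -r:r) for (dyy in -r:r) for (dxx in -r:r) {
    nc <- sweep(co, 2, c(dyy, dxx, dz), `+`)
    ok <- nc[, 1] >= 1 & nc[, 1] <= dims[1] &
      nc[, 2] >= 1 & nc[, 2] <= dims[2] &
      nc[, 3] >= 1 & nc[, 3] <= dims[3]
    if (any(ok)) {
      out[nc[ok, 1] + (nc[ok, 2] - 1) * dims[1] +
            (nc[ok, 3] - 1) * dims[1] * dims[2]] <- TRUE
    }
  }
  out
}

#' Save a generated dataset with its ground truth and run manifest
#'
#' Writes the image as multi-page 16-bit TIFF (plus its JSON sidecar), the
#' ground-truth tables as CSV and a machine-readable manifest (JSON)
#' recording the generating parameters and seed.
#'
#' @param dataset a list returned by one of the generators.
#' @param dir output directory (created if missing).
#' @param name basename for the files.
#' @return invisibly, the manifest path.
#' @export
save_dataset <- function(dataset, dir, name = "dataset") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stack_tiff(dataset$image, file.path(dir, paste0(name, ".tif")))
  tr <- dataset$truth
  tables <- Filter(function(x) is.data.frame(x), tr)
  for (nm in names(tables)) {
    utils::write.csv(tables[[nm]], file.path(dir, paste0(name, "_", nm, ".csv")),
                     row.names = FALSE)
  }
  scalars <- Filter(function(x) is.atomic(x) && length(x) <= 4 && !is.array(x), tr)
  jsonlite::write_json(scalars, file.path(dir, paste0(name, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, paste0(name, "_manifest.json")))
}
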