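make_trace <- function(df, areas = NULL) rimfrap:::new_frap_trace(df, areas)

test_that("trace extraction returns exact ROI means and checks extents", {
  arr <- array(7, c(16, 16, 4))
  rois <- frap_rois(bleach = which(matrix(seq_len(256) <= 16, 16, 16)),
                    total = 1:64, background = 200:220, shape = c(16, 16))
  tr <- extract_traces(image_stack(arr, c("y", "x", "time")), rois,
                       times = c(-1, 0, 1, 2))
  expect_true(all(tr$I_bleach == 7))
  expect_true(all(tr$I_total == 7))
  expect_identical(tr$phase, c("prebleach", rep("postbleach", 3)))

  expect_error(frap_rois(bleach = 1:4, total = 1:300, background = 301:310,
                         shape = c(16, 16)), "outside the frame")
  expect_error(frap_rois(bleach = 1:4, total = 5:40, background = 50:60,
                         shape = c(16, 16)), "inside the total")
  expect_error(frap_rois(bleach = 1:4, total = 1:40, background = 30:60,
                         shape = c(16, 16)), "not intersect")
})

test_that("the double-normalization worked example evaluates to 0.55", {
  tr <- make_trace(tibble::tibble(
    t = c(-1, 5), phase = c("prebleach", "postbleach"),
    I_bleach = c(100, 55), I_total = c(1000, 910), I_background = c(10, 10)))
  dn <- double_normalize(tr, t0 = "last_prebleach")
  expect_equal(dn$N[2], (45 / 90) / (900 / 990), tolerance = 1e-12)
  expect_equal(dn$N[2], 0.55, tolerance = 1e-12)
  # N at the reference frame is exactly 1
  expect_identical(dn$N[1], 1)
})

test_that("proportional bleach and total traces normalize to a constant 1", {
  tt <- seq(-3, 40)
  total <- 1000 * exp(-0.01 * (tt - tt[1]))
  tr <- make_trace(tibble::tibble(
    t = tt, phase = ifelse(tt < 0, "prebleach", "postbleach"),
    I_bleach = 0.1 * total + 10, I_total = total + 10, I_background = 10))
  dn <- double_normalize(tr)
  expect_true(all(abs(dn$N - 1) < 1e-12))
})

test_that("normalization is invariant to affine intensity rescaling", {
  sp <- frap_spec(mobile_fraction = 0.6, rate = 0.08, noise_sigma_frac = 0,
                  acquisition_bleach_rate = 0.001, seed = 2)
  g <- make_frap_series(sp)
  tr <- g$trace
  dn0 <- double_normalize(tr)$N
  gain <- 3.7; offset <- 25
  tr2 <- make_trace(tibble::tibble(
    t = tr$t, phase = tr$phase,
    I_bleach = gain * tr$I_bleach + offset,
    I_total = gain * tr$I_total + offset,
    I_background = gain * tr$I_background + offset),
    areas = attr(tr, "areas"))
  expect_equal(double_normalize(tr2)$N, dn0, tolerance = 1e-12)
})

test_that("double normalization cancels uniform acquisition bleaching", {
  sp <- frap_spec(mobile_fraction = 0, acquisition_bleach_rate = 0.002,
                  noise_sigma_frac = 0, seed = 3)
  g <- make_frap_series(sp)
  dn <- double_normalize(g$trace)
  post <- dn$N[dn$phase == "postbleach"]
  expect_lt(diff(range(post)), 1e-10)
})

test_that("nonpositive denominators exclude frames with a message", {
  tt <- c(-1, 0, 1, 2)
  tr <- make_trace(tibble::tibble(
    t = tt, phase = ifelse(tt < 0, "prebleach", "postbleach"),
    I_bleach = c(100, 40, 45, 50),
    I_total = c(1000, 900, 5, 910), I_background = 10))
  expect_message(dn <- double_normalize(tr), "excluded")
  expect_true(is.na(dn$N[3]))
  expect_identical(attr(dn, "n_excluded_frames"), 1L)
})

test_that("the recovery fit reproduces closed-form parameters", {
  t <- 0:200
  N <- 0.4 + (0.9 - 0.4) * (1 - exp(-0.05 * t))
  f <- fit_recovery(data.frame(t = t, N = N))
  expect_equal(f$mobile_fraction, (0.9 - 0.4) / (1 - 0.4), tolerance = 1e-7)
  expect_equal(f$rate, 0.05, tolerance = 1e-7)
  expect_equal(f$t_half, log(2) / 0.05, tolerance = 1e-5)
  expect_lt(f$residual_norm, 1e-6)
})

test_that("flat and fully recovering traces give M = 0 and M = 1", {
  t <- 0:50
  f0 <- fit_recovery(data.frame(t = t, N = rep(0.4, 51)))
  expect_equal(f0$mobile_fraction, 0, tolerance = 1e-6)
  expect_true(is.na(f0$rate))   # rate unidentifiable without recovery
  N1 <- 0.4 + 0.6 * (1 - exp(-0.1 * t))
  f1 <- fit_recovery(data.frame(t = t, N = N1))
  expect_equal(f1$mobile_fraction, 1, tolerance = 1e-6)
})

test_that("fit preconditions are enforced", {
  expect_error(fit_recovery(data.frame(t = 0:5, N = rep(0.5, 6))), ">= 10")
  expect_error(fit_recovery(data.frame(t = 0:20, N = rep(1.2, 21))),
               "not below 1")
})

test_that("curve averaging matches hand-computed mean and s.e.m.", {
  tr <- lapply(1:5, function(i) data.frame(t = 0:20, N = rep(0.5, 21)))
  av <- average_curves(tr, fit = FALSE)
  expect_true(all(av$curve$sem == 0))
  two <- list(data.frame(t = 0:20, N = rep(0.4, 21)),
              data.frame(t = 0:20, N = rep(0.6, 21)))
  av2 <- average_curves(two, fit = FALSE)
  expect_true(all(abs(av2$curve$mean - 0.5) < 1e-12))
  expect_true(all(abs(av2$curve$sem - 0.1) < 1e-12))
  one <- average_curves(list(data.frame(t = 0:20, N = 0.4 + 0.001 * (0:20))),
                        fit = FALSE)
  expect_true(all(is.na(one$curve$sem)))
})

test_that("averaging on shifted grids matches an interpolation oracle", {
  f <- function(t) 0.3 + 0.6 * (1 - exp(-0.07 * t))
  t1 <- seq(0, 50, by = 1)
  t2 <- seq(0.5, 50, by = 1)
  av <- average_curves(list(data.frame(t = t1, N = f(t1)),
                            data.frame(t = t2, N = f(t2))), fit = FALSE)
  # oracle: linear interpolation of trace 2 onto trace 1's clipped grid
  grid <- av$curve$t
  o2 <- stats::approx(t2, f(t2), xout = grid)$y
  expect_equal(av$curve$mean, (f(grid) + o2) / 2, tolerance = 1e-12)
})

test_that("flow gain equals unbleached loss for conserved series", {
  sp <- frap_spec(mobile_fraction = 0.5, rate = 0.05, noise_sigma_frac = 0,
                  seed = 5)
  g <- make_frap_series(sp, bleach_fraction = 0.04)
  fm <- flow_metric(g$trace)
  expect_lt(max(abs(fm$residual)), 1e-9)
  # immobile series transfers nothing
  g0 <- make_frap_series(frap_spec(mobile_fraction = 0, noise_sigma_frac = 0,
                                   seed = 5))
  fm0 <- flow_metric(g0$trace)
  expect_lt(max(abs(fm0$transfer)), 1e-9)
})

test_that("asymptotic transfer approaches M (P - D) in bleach-ROI units", {
  sp <- frap_spec(mobile_fraction = 0.5, postbleach_depth = 0.3, rate = 0.05,
                  n_postbleach = 400, noise_sigma_frac = 0, seed = 6)
  f_b <- 0.02
  g <- make_frap_series(sp, bleach_fraction = f_b)
  fm <- flow_metric(g$trace)
  # areas are fractions of the structure: expected gain = f_b * M * (P - D)
  expected <- f_b * 0.5 * (100 - 30)
  expect_lt(abs(utils::tail(fm$transfer, 1) - expected) / expected, 0.05)
})

test_that("flow requires a bleached/unbleached partition of the structure", {
  tr <- make_trace(tibble::tibble(
    t = c(-1, 0, 1), phase = c("prebleach", "postbleach", "postbleach"),
    I_bleach = c(100, 30, 40), I_unbleached = c(100, 100, 99),
    I_total = c(100, 98, 98), I_background = 0),
    areas = c(bleach = 10, unbleached = 50, total = 70, background = 5))
  expect_error(flow_metric(tr), "partition")
})

test_that("simulated parameter recovery is accurate for M and k", {
  # 6 series per (M, k) cell at 2% noise; median errors well inside the
  # acceptance bands checked at larger n in the acceptance suite
  conds <- expand.grid(M = c(0.2, 0.5, 0.9), k = c(0.01, 0.05, 0.2))
  errM <- c(); errK <- c()
  for (i in seq_len(nrow(conds))) {
    for (s in 1:6) {
      sp <- frap_spec(mobile_fraction = conds$M[i], rate = conds$k[i],
                      noise_sigma_frac = 0.02,
                      acquisition_bleach_rate = ifelse(s %% 2 == 0, 0.001, 0),
                      seed = 1000 + 37 * i + s)
      g <- make_frap_series(sp)
      f <- fit_recovery(double_normalize(g$trace))
      errM <- c(errM, abs(f$mobile_fraction - conds$M[i]))
      errK <- c(errK, abs(f$rate - conds$k[i]) / conds$k[i])
    }
  }
  expect_lt(stats::median(errM), 0.05)
  expect_lt(stats::median(errK), 0.10)
})
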