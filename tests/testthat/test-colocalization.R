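test_that("PCC is exact under affine dependence and matches the oracle", {
  withr::with_seed(31, {
    ch1 <- matrix(runif(64 * 64, 10, 200), 64, 64)
    noise <- matrix(runif(64 * 64, 0, 50), 64, 64)
  })
  mask <- matrix(TRUE, 64, 64)
  expect_equal(compute_pcc(ch1, 2 * ch1 + 5, mask), 1, tolerance = 1e-12)
  # negation flips the sign (negative values offset to stay intensities)
  expect_equal(compute_pcc(ch1, max(ch1) - ch1, mask), -1, tolerance = 1e-12)
  ch2 <- 0.6 * ch1 + noise
  expect_equal(compute_pcc(ch1, ch2, mask),
               oracle_pcc(ch1[mask], ch2[mask]), tolerance = 1e-12)
})

test_that("independent channels decorrelate at the sampling bound", {
  withr::with_seed(77, {
    ch1 <- matrix(runif(1e4), 100, 100)
    ch2 <- matrix(runif(1e4), 100, 100)
  })
  expect_lt(abs(compute_pcc(ch1, ch2, matrix(TRUE, 100, 100))), 0.05)
})

test_that("constant channels and tiny masks are rejected", {
  ch <- matrix(5, 32, 32)
  v <- matrix(runif(32 * 32), 32, 32)
  expect_error(compute_pcc(ch, v, matrix(TRUE, 32, 32)), "constant")
  m <- matrix(FALSE, 32, 32); m[1:5, 1] <- TRUE
  expect_error(compute_pcc(v, v, m), "minimum")
})

test_that("four 90-degree rotations restore the observed coefficient", {
  cp <- make_coloc_pair(0.7, image_shape = c(70, 90), seed = 9)
  ch1 <- get_plane(cp$image, channel = 1)
  ch2 <- get_plane(cp$image, channel = 2)
  obs <- compute_pcc(ch1, ch2, cp$mask)
  r360 <- rotation_null_pcc(ch1, ch2, cp$mask, angle = 360)
  expect_identical(r360$pcc, obs)
  r0 <- rotation_null_pcc(ch1, ch2, cp$mask, angle = 0)
  expect_identical(r0$pcc, obs)
  expect_error(rotation_null_pcc(ch1, ch2, cp$mask, angle = 45), "multiple of 90")
})

test_that("a radially symmetric pattern is invariant under the rotation null", {
  n <- 41  # odd: the bbox center falls on a pixel
  cy <- 21; cx <- 21
  r2 <- outer(seq_len(n), seq_len(n), function(y, x) (y - cy)^2 + (x - cx)^2)
  mask <- r2 <= 15^2
  ch1 <- exp(-r2 / 60) * 100 + 10
  ch2 <- exp(-r2 / 100) * 80 + 5
  obs <- compute_pcc(ch1, ch2, mask)
  rot <- rotation_null_pcc(ch1, ch2, mask, angle = 90)
  expect_equal(rot$pcc, obs, tolerance = 1e-12)
})

test_that("rotation preserves the marginal histogram of the rotated crop", {
  cp <- make_coloc_pair(0.5, image_shape = c(60, 60), seed = 14)
  ch2 <- get_plane(cp$image, channel = 2)
  mm <- cp$mask
  rr <- range(which(rowSums(mm) > 0)); cc <- range(which(colSums(mm) > 0))
  sub <- ch2[rr[1]:rr[2], cc[1]:cc[2]]
  rot <- rimfrap:::rot90_cw(sub)
  expect_identical(sort(as.vector(rot)), sort(as.vector(sub)))
})

test_that("anisotropic correlated pairs attenuate under the rotation null", {
  att <- vapply(1:15, function(s) {
    cp <- make_coloc_pair(0.8, anisotropy = TRUE, seed = 400 + s)
    ch1 <- get_plane(cp$image, channel = 1)
    ch2 <- get_plane(cp$image, channel = 2)
    obs <- compute_pcc(ch1, ch2, cp$mask)
    rot <- rotation_null_pcc(ch1, ch2, cp$mask, 90)
    obs - abs(rot$pcc)
  }, numeric(1))
  expect_gt(stats::median(att), 0.3)
})

test_that("the paired rotation test behaves at both extremes", {
  # degenerate: observed == rotated -> zero-variance differences
  same <- tibble::tibble(cell_id = 1:5, pcc_observed = rep(0.5, 5),
                         pcc_rotated = rep(0.5, 5))
  res <- paired_coloc_test(same)
  expect_true(is.na(res$test$p))
  expect_identical(res$test$note, "zero variance of paired differences")

  # simulated anisotropic cells reject clearly
  cells <- dplyr::bind_rows(lapply(1:20, function(s) {
    cp <- make_coloc_pair(0.8, anisotropy = TRUE, seed = 600 + s)
    measure_coloc(get_plane(cp$image, channel = 1),
                  get_plane(cp$image, channel = 2), cp$mask, cell_id = s)
  }))
  res2 <- paired_coloc_test(cells)
  expect_lt(res2$test$p, 0.01)
  expect_gt(res2$groups$mean_pcc[1], res2$groups$mean_pcc[2])

  expect_error(paired_coloc_test(same[1:2, ]), ">= 3 cells")
})
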