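test_that("the volume window keeps only mid-sized components", {
  # nucleus = whole stack, large enough that the 99.5th percentile of the
  # within-nucleus histogram sits below the focus intensity
  fk <- make_foci_stack(c(5, 50, 2500), stack_shape = c(100, 100, 60),
                        nucleus = "full", seed = 19)
  rec <- segment_chromocenters(fk$image, fk$nucleus_mask, foci_config())
  expect_identical(rec$foci_count, 1L)
  expect_identical(rec$volumes[[1]], 50L)
})

test_that("volume bounds are inclusive at exactly 7 and 2000 voxels", {
  # stack large enough that foci stay below 0.5% of the histogram
  fk <- make_foci_stack(c(6, 7, 2000, 2001), stack_shape = c(120, 120, 60),
                        nucleus = "full", seed = 23)
  rec <- segment_chromocenters(fk$image, fk$nucleus_mask, foci_config())
  expect_identical(rec$foci_count, 2L)
  expect_setequal(rec$volumes[[1]], c(7L, 2000L))
})

test_that("a uniform nucleus contains no suprathreshold component", {
  arr <- array(10, c(24, 24, 12))
  nm <- array(FALSE, c(24, 24, 12)); nm[5:20, 5:20, 3:10] <- TRUE
  arr[nm] <- 100
  rec <- segment_chromocenters(arr, nm, foci_config())
  expect_identical(rec$foci_count, 0L)
})

test_that("generator foci are recovered with exact counts and volumes", {
  fk <- make_foci_stack(rep(20, 10), stack_shape = c(64, 64, 32), seed = 29)
  rec <- segment_chromocenters(fk$image, fk$nucleus_mask,
                               foci_config(threshold_percentile = 95))
  expect_identical(rec$foci_count, 10L)
  expect_true(all(rec$volumes[[1]] == 20L))
  expect_equal(rec$volumes_calibrated[[1]],
               rep(20 * 0.075 * 0.075 * 0.029, 10), tolerance = 1e-12)
})

test_that("counting is invariant to intensity rescaling", {
  fk <- make_foci_stack(c(30, 60), stack_shape = c(48, 48, 24), seed = 31,
                        noise_sigma = 5)
  cfg <- foci_config(threshold_percentile = 98)
  a <- segment_chromocenters(fk$image, fk$nucleus_mask, cfg)
  b <- segment_chromocenters(fk$image$data * 12.5, fk$nucleus_mask, cfg)
  expect_identical(a$foci_count, b$foci_count)
  expect_identical(a$volumes, b$volumes)
})

test_that("nuclei smaller than the minimum volume give empty records", {
  arr <- array(10, c(8, 8, 4)); nm <- array(0L, c(8, 8, 4))
  nm[4, 4, 2] <- 1L; nm[5, 5, 2] <- 1L   # 2-voxel nucleus
  expect_warning(rec <- segment_chromocenters(arr, nm, foci_config()),
                 "smaller than min_volume")
  expect_identical(rec$foci_count, 0L)
})

test_that("PLA counting finds the generated spots per cell", {
  # one bright reporter cell with 6 well-separated 4-px spots
  img <- matrix(10, 80, 80)
  img[10:70, 10:70] <- 100                      # reporter cell body
  cells <- segment_objects(img, method = "fixed", threshold = 50, min_area = 100)
  spots <- matrix(0, 80, 80)
  pos <- cbind(c(15, 15, 40, 40, 60, 60), c(15, 60, 20, 55, 35, 65))
  for (i in seq_len(nrow(pos))) {
    spots[pos[i, 1] + 0:1, pos[i, 2] + 0:1] <- 300
  }
  rec <- count_pla_foci(spots + img, cells,
                        foci_config(threshold_percentile = 99,
                                    min_volume = 2, max_volume = 50))
  expect_identical(rec$foci_count, 6L)
  expect_true(all(rec$areas[[1]] == 4L))

  blank <- count_pla_foci(img, cells,
                          foci_config(threshold_percentile = 99,
                                      min_volume = 2, max_volume = 50))
  expect_identical(blank$foci_count, 0L)
  expect_error(count_pla_foci(spots, matrix(0L, 80, 80)), "no cells")
})

test_that("two sub-resolution spots merge into a single count", {
  img <- matrix(10, 40, 40)
  img[5:35, 5:35] <- 100
  cells <- segment_objects(img, method = "fixed", threshold = 50, min_area = 50)
  spots <- img
  spots[20, 20:21] <- 300
  spots[21, 22] <- 300   # diagonal touch: same 8-connected component
  rec <- count_pla_foci(spots, cells,
                        foci_config(threshold_percentile = 99,
                                    min_volume = 1, max_volume = 50))
  expect_identical(rec$foci_count, 1L)
})

test_that("fold normalization divides by the control mean", {
  counts <- tibble::tibble(
    condition = rep(c("gfp_only", "test_a", "test_b"), each = 4),
    foci_count = c(2, 2, 2, 2, 6, 6, 5, 7, 1, 2, 3, 2))
  nf <- normalize_foci(counts, control = "gfp_only")
  expect_equal(nf$per_cell$fold[5], 3)
  ctrl_row <- nf$summary[nf$summary$condition == "gfp_only", ]
  expect_equal(ctrl_row$mean_fold, 1)
  expect_error(normalize_foci(tibble::tibble(condition = "c", foci_count = 0),
                              control = "c"), "positive")
  expect_error(normalize_foci(counts, control = "absent"), "not found")
})

test_that("chromocenter counts agree with the flood-fill oracle", {
  withr::with_seed(101, {
    for (rep in 1:6) {
      d <- c(sample(10:32, 1), sample(10:32, 1), sample(6:16, 1))
      m <- array(stats::rbinom(prod(d), 1, 0.18), d)
      expect_identical(label_components(m), oracle_flood_fill(m))
    }
  })
})

test_that("foci_config validates its window and percentile", {
  expect_error(foci_config(threshold_percentile = 100), "percentile")
  expect_error(foci_config(min_volume = 0), "min_volume")
  expect_error(foci_config(min_volume = 10, max_volume = 5), "min_volume")
})
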