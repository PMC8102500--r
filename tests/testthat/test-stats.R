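test_that("Holm adjustment matches hand-worked cases", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04), tolerance = 1e-12)
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.05, 0.05, 0.05)), c(0.15, 0.15, 0.15),
               tolerance = 1e-12)
  expect_error(holm_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(holm_adjust(c(0.1, -0.2)), "\\[0, 1\\]")
})

test_that("Holm agrees with the definition oracle on all permutations <= 5", {
  withr::with_seed(55, {
    for (m in 1:5) {
      p <- round(stats::runif(m), 3)
      for (perm in all_perms(p)) {
        expect_equal(holm_adjust(perm), oracle_holm(perm), tolerance = 1e-12)
      }
    }
  })
})

test_that("adjusted p-values are permutation-invariant and monotone", {
  withr::with_seed(56, {
    p <- stats::runif(5)
    adj <- holm_adjust(p)
    o <- sample(5)
    expect_equal(holm_adjust(p[o]), adj[o], tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    expect_true(!is.unsorted(adj[order(p)]))
  })
})

test_that("two identical groups give t = 0 and p = 1", {
  d <- data.frame(v = c(1, 2, 3, 1, 2, 3), g = rep(c("a", "b"), each = 3))
  res <- compare_groups(d, "v", "g", design = "t_test")
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  expect_identical(res$stars, "ns")
})

test_that("group sizes and degenerate variance are validated", {
  expect_error(compare_groups(data.frame(v = 1:3, g = c("a", "a", "a")),
                              "v", "g"), ">= 2 groups")
  expect_error(compare_groups(data.frame(v = 1:3, g = c("a", "a", "b")),
                              "v", "g"), "n >= 2")
  d0 <- data.frame(v = rep(c(1, 2), each = 3), g = rep(c("a", "b"), each = 3))
  expect_error(compare_groups(d0, "v", "g"), "degenerate")
})

test_that("the ANOVA design reports an omnibus row plus Holm pairwise rows", {
  withr::with_seed(60, {
    d <- data.frame(v = c(rnorm(10, 0), rnorm(10, 0.2), rnorm(10, 3)),
                    g = rep(c("a", "b", "c"), each = 10))
  })
  res <- compare_groups(d, "v", "g", design = "anova_holm")
  expect_identical(res$test[1], "one-way ANOVA")
  expect_identical(nrow(res), 4L)   # omnibus + 3 pairwise
  pair <- res[-1, ]
  expect_equal(pair$p_adj, holm_adjust(pair$p), tolerance = 1e-12)
  expect_true(all(pair$p_adj >= pair$p))
  # the clearly separated group is significant after adjustment
  expect_lt(res$p_adj[res$group1 == "a" & res$group2 == "c"], 0.001)
})

test_that("Kruskal-Wallis runs for non-normal designs", {
  withr::with_seed(61, {
    d <- data.frame(v = c(rexp(12), rexp(12) + 2), g = rep(c("a", "b"), each = 12))
  })
  res <- compare_groups(d, "v", "g", design = "kruskal")
  expect_identical(res$test, "Kruskal-Wallis")
  expect_lt(res$p, 0.01)
})

test_that("a 3-sigma mean shift at n = 30 is detected essentially always", {
  withr::with_seed(62, {
    rej <- vapply(1:400, function(i) {
      d <- data.frame(v = c(stats::rnorm(30), stats::rnorm(30, 3)),
                      g = rep(c("a", "b"), each = 30))
      compare_groups(d, "v", "g")$p < 0.05
    }, logical(1))
  })
  expect_gt(mean(rej), 0.99)
})

test_that("paired t tests respect row alignment", {
  withr::with_seed(63, {
    base <- rnorm(10)
    d <- data.frame(v = c(base, base + 0.5 + rnorm(10, 0, 0.1)),
                    g = rep(c("pre", "post"), each = 10))
  })
  res_p <- compare_groups(d, "v", "g", design = "t_test", paired = TRUE)
  res_u <- compare_groups(d, "v", "g", design = "t_test", paired = FALSE)
  expect_lt(res_p$p, res_u$p)
})

test_that("significance stars follow the declared convention", {
  expect_identical(rimfrap:::signif_stars(c(0.2, 0.04, 0.009, 0.0009, NA)),
                   c("ns", "*", "**", "***", NA))
})

test_that("stat reports are written as CSV plus markdown", {
  d <- data.frame(v = c(1, 2, 3, 4, 2, 3, 4, 5), g = rep(c("a", "b"), each = 4))
  res <- compare_groups(d, "v", "g")
  path <- withr::local_tempfile(fileext = ".csv")
  write_stat_report(res, path, exclusions = c(degenerate_nuclei = 2))
  expect_true(file.exists(path))
  md <- readLines(paste0(path, ".md"))
  expect_true(any(grepl("degenerate_nuclei: 2", md)))
})
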