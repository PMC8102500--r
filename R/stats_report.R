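#' Holm (step-down Bonferroni) adjustment of p-values
#'
#' Sort ascending, multiply the i-th smallest of m p-values by
#' `m - i + 1`, enforce monotonicity of the running maximum, cap at 1 and
#' restore the input order. Delegates to the standard step-down
#' implementation after validating the input.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @examples
#' holm_adjust(c(0.01, 0.04))   # 0.02, 0.04
#' @export
holm_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "holm")
}

#' Group comparisons: t test, one-way ANOVA + Holm, Kruskal-Wallis
#'
#' The three designs used across the package's readouts:
#' `"t_test"` — two-group Student's t (Welch unequal-variance by default,
#' two-tailed, optionally paired); `"anova_holm"` — one-way ANOVA
#' followed by all pairwise Welch t tests with Holm adjustment;
#' `"kruskal"` — Kruskal-Wallis rank test for non-normal data. The caller
#' chooses the design; normality is never auto-tested.
#'
#' @param data data frame with the value and group columns.
#' @param value,group column names (strings).
#' @param design one of `"t_test"`, `"anova_holm"`, `"kruskal"`.
#' @param paired paired t test (two-group design only; rows must be
#'   aligned within groups).
#' @param var_equal assume equal variances in t tests (default `FALSE` =
#'   Welch).
#' @param alpha significance level used only for the star annotation.
#' @return tibble, one row per comparison (ANOVA adds an omnibus row):
#'   `test, group1, group2, n1, n2, mean1, mean2, sem1, sem2, statistic,
#'   p, p_adj, stars`.
#' @export
compare_groups <- function(data, value, group,
                           design = c("t_test", "anova_holm", "kruskal"),
                           paired = FALSE, var_equal = FALSE, alpha = 0.05) {
  design <- match.arg(design)
  v <- data[[value]]; g <- factor(data[[group]])
  if (anyNA(v)) { g <- g[!is.na(v)]; v <- v[!is.na(v)] }
  lev <- levels(droplevels(g)); g <- droplevels(g)
  ns <- table(g)
  if (length(lev) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(ns < 2)) stop("each group needs n >= 2", call. = FALSE)
  if (all(tapply(v, g, stats::sd) == 0)) {
    stop("degenerate test: zero within-group variance in every group", call. = FALSE)
  }
  gstat <- function(l) {
    x <- v[g == l]
    c(n = length(x), mean = mean(x), sem = sem(x))
  }
  row_for <- function(test, l1, l2, statistic, p) {
    s1 <- gstat(l1)
    s2 <- if (is.na(l2)) c(n = NA, mean = NA, sem = NA) else gstat(l2)
    tibble::tibble(test = test, group1 = l1, group2 = l2,
                   n1 = s1["n"], n2 = s2["n"],
                   mean1 = s1["mean"], mean2 = s2["mean"],
                   sem1 = s1["sem"], sem2 = s2["sem"],
                   statistic = statistic, p = p)
  }

  if (design == "t_test") {
    if (length(lev) != 2) stop("t test needs exactly 2 groups", call. = FALSE)
    tt <- stats::t.test(v[g == lev[1]], v[g == lev[2]], paired = paired,
                        var.equal = var_equal, alternative = "two.sided")
    out <- row_for(if (paired) "paired t" else "t", lev[1], lev[2],
                   unname(tt$statistic), unname(tt$p.value))
    out$p_adj <- out$p
  } else if (design == "anova_holm") {
    if (length(lev) < 3) stop("one-way ANOVA design needs >= 3 groups", call. = FALSE)
    if (any(ns < 3)) stop("ANOVA needs n >= 3 per group", call. = FALSE)
    fit <- stats::aov(v ~ g)
    an <- summary(fit)[[1]]
    omni <- row_for("one-way ANOVA", "all", NA_character_,
                    an$`F value`[1], an$`Pr(>F)`[1])
    prs <- utils::combn(lev, 2, simplify = FALSE)
    pair_rows <- lapply(prs, function(pr) {
      tt <- stats::t.test(v[g == pr[1]], v[g == pr[2]], var.equal = var_equal)
      row_for("pairwise t (Holm)", pr[1], pr[2],
              unname(tt$statistic), unname(tt$p.value))
    })
    pair <- dplyr::bind_rows(pair_rows)
    pair$p_adj <- holm_adjust(pair$p)
    omni$p_adj <- omni$p
    out <- dplyr::bind_rows(omni, pair)
  } else {
    kt <- stats::kruskal.test(v, g)
    out <- row_for("Kruskal-Wallis", "all", NA_character_,
                   unname(kt$statistic), unname(kt$p.value))
    out$p_adj <- out$p
  }
  out$stars <- signif_stars(out$p_adj)
  out
}

#' Write a tidy comparison report
#'
#' Emits the comparison table as CSV plus a small markdown run report
#' listing the tests, significance stars and any exclusions.
#'
#' @param results tibble from [compare_groups].
#' @param path CSV output path; the markdown report goes to
#'   `<path>.md`.
#' @param exclusions optional named counts of excluded observations.
#' @return invisibly, `path`.
#' @export
write_stat_report <- function(results, path, exclusions = NULL) {
  utils::write.csv(results, path, row.names = FALSE)
  md <- c("# Group comparison report", "",
          sprintf("- %s: %s vs %s — p = %.3g (adj %.3g) %s",
                  results$test, results$group1,
                  ifelse(is.na(results$group2), "-", results$group2),
                  results$p, results$p_adj, results$stars))
  if (!is.null(exclusions) && length(exclusions)) {
    md <- c(md, "", "## Exclusions",
            sprintf("- %s: %d", names(exclusions), as.integer(exclusions)))
  }
  writeLines(md, paste0(path, ".md"))
  invisible(path)
}
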