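# Group-level distribution statistics on pooled region measures:
# pooled per-group estimator table, Anderson-Darling normality checks, and
# two-sample Kolmogorov-Smirnov comparisons of the control group against
# each treatment group.

#' Pooled per-group estimators
#'
#' Pools all regions of each group (across that group's images, not image
#' means) and reports mean and sample SD of each of the five shape measures:
#' a groups x 10 table in the canonical predictor order.
#'
#' @param regions Per-region descriptor table (from [describe_regions()] or
#'   [describe_dataset()]), with an `image_id` column.
#' @param manifest Data frame mapping `image_id` to `group`.
#' @param groups Group rows to report, in order.
#' @return Data frame: `group`, `n_regions`, then the ten estimator columns.
#'   A group with no regions gets `NA` estimators with a warning.
#' @export
pooled_group_estimators <- function(regions, manifest,
                                    groups = intersect(VQ_GROUPS,
                                                       manifest$group)) {
  grp <- manifest$group[match(regions$image_id, manifest$image_id)]
  out <- lapply(groups, function(g) {
    sub <- regions[!is.na(grp) & grp == g, , drop = FALSE]
    row <- data.frame(group = g, n_regions = nrow(sub))
    if (nrow(sub) == 0L) {
      warning("group ", g, " has no regions; estimators set to NA")
      est <- rep(NA_real_, 10)
    } else {
      est <- unlist(lapply(VQ_MEASURES, function(m)
        c(mean(sub[[m]]), vq_sample_sd(sub[[m]]))))
    }
    names(est) <- VQ_PREDICTORS
    cbind(row, as.data.frame(as.list(est)))
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Statistic `D = sup |F1 - F2|` over the observed points, with the
#' asymptotic Kolmogorov p-value at effective sample size
#' `n1*n2/(n1 + n2)`. Ties are allowed (measures such as area are integer
#' valued); the tie warning from the underlying test is suppressed and the
#' p-value labeled approximate.
#'
#' @param x,y Numeric samples, each nonempty.
#' @return A `vq_test_result`: list with `statistic`, `p_value`, `test`,
#'   `n` (two sample sizes).
#' @export
ks_two_sample <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample", call. = FALSE)
  ht <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  structure(list(statistic = unname(ht$statistic),
                 p_value = unname(ht$p.value),
                 test = "two-sample Kolmogorov-Smirnov (asymptotic)",
                 n = c(length(x), length(y))),
            class = "vq_test_result")
}

#' Anderson-Darling normality test
#'
#' One-sample composite normality test (mean and variance estimated), with
#' the standard small-sample modification
#' `A*^2 = A^2 * (1 + 0.75/n + 2.25/n^2)`.
#'
#' @param x Numeric sample, `length(x) >= 8`.
#' @return A `vq_test_result` with the modified statistic and p-value.
#' @export
anderson_darling_normality <- function(x) {
  if (length(x) < 8L) stop("Anderson-Darling test needs n >= 8",
                           call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate sample: zero variance",
                              call. = FALSE)
  ht <- nortest::ad.test(x)
  structure(list(statistic = unname(ht$statistic),
                 p_value = unname(ht$p.value),
                 test = "Anderson-Darling normality (estimated parameters)",
                 n = length(x)),
            class = "vq_test_result")
}

#' @export
print.vq_test_result <- function(x, ...) {
  cat("<vq_test_result> ", x$test, "\n  statistic = ",
      signif(x$statistic, 6), ", p = ", signif(x$p_value, 4),
      ", n = ", paste(x$n, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Distribution comparison table
#'
#' For each of the five region measures: an Anderson-Darling normality check
#' per group (where the group has at least 8 regions) and a two-sample
#' Kolmogorov-Smirnov comparison of CONTROL against each other group.
#' P-values are raw (no multiple-testing correction applied).
#'
#' @param regions Per-region descriptor table.
#' @param manifest Data frame mapping `image_id` to `group`.
#' @param reference Reference group for the pairwise KS comparisons.
#' @return Data frame: `comparison`, `measure`, `test`, `statistic`,
#'   `p_value`, `n1`, `n2`.
#' @export
distribution_tests <- function(regions, manifest, reference = "CONTROL") {
  grp <- manifest$group[match(regions$image_id, manifest$image_id)]
  groups <- intersect(VQ_GROUPS, unique(grp))
  rows <- list()
  for (m in VQ_MEASURES) {
    for (g in groups) {
      v <- regions[[m]][!is.na(grp) & grp == g]
      if (length(v) >= 8L && stats::sd(v) > 0) {
        t <- anderson_darling_normality(v)
        rows[[length(rows) + 1L]] <- data.frame(
          comparison = g, measure = m, test = "anderson_darling",
          statistic = t$statistic, p_value = t$p_value,
          n1 = t$n, n2 = NA_integer_)
      }
    }
    for (g in setdiff(groups, reference)) {
      x <- regions[[m]][!is.na(grp) & grp == reference]
      y <- regions[[m]][!is.na(grp) & grp == g]
      if (!length(x) || !length(y)) next
      t <- ks_two_sample(x, y)
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = paste0(reference, "-", g), measure = m,
        test = "ks_two_sample", statistic = t$statistic,
        p_value = t$p_value, n1 = t$n[1], n2 = t$n[2])
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
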