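# Exhaustive predictor-subset search with linear discriminants, in five
# classification schemes:
#   ONE_VS_REST        each group against the merged remaining groups
#   COMMON_PREDICTORS  one shared subset scored by the average of the four
#                      one-vs-rest accuracies
#   PAIRED             CONTROL against each treatment group separately
#   VD_PRESENCE        lesion-present vs lesion-free images, all groups merged
#   CONTROL_VS_MERGED  CONTROL vs merged treatments, lesion-present images only

VQ_SCHEMES <- c("ONE_VS_REST", "COMMON_PREDICTORS", "PAIRED",
                "VD_PRESENCE", "CONTROL_VS_MERGED")

#' Enumerate all non-empty predictor subsets
#'
#' @param n_predictors Number of available predictors (1..20).
#' @return Integer vector of bitmasks `1 .. 2^n - 1`, ascending; bit `i-1`
#'   set means predictor `i` is in the subset.
#' @export
enumerate_subsets <- function(n_predictors) {
  stopifnot(n_predictors >= 1, n_predictors <= 20)
  seq_len(2^n_predictors - 1)
}

#' @keywords internal
#' @noRd
vq_subset_columns <- function(bitmask, predictor_set) {
  predictor_set[bitwAnd(bitmask, 2^(seq_along(predictor_set) - 1)) > 0]
}

#' Define a classification scheme over a predictor table
#'
#' Builds the binary classification problem(s) of one scheme: row filter,
#' class labels and class order (the first class wins score ties).
#'
#' @param name One of `"ONE_VS_REST"`, `"COMMON_PREDICTORS"`, `"PAIRED"`,
#'   `"VD_PRESENCE"`, `"CONTROL_VS_MERGED"`.
#' @param predictors Predictor table from [describe_dataset()] (needs
#'   `group` and `vd_present` columns).
#' @return A `vq_scheme`: list with `name` and `problems`, each problem a
#'   list with `label`, `rows` (row indices) and `y` (factor-like character
#'   vector, first class first).
#' @export
make_scheme <- function(name, predictors) {
  name <- match.arg(name, VQ_SCHEMES)
  groups <- intersect(VQ_GROUPS, unique(predictors$group))
  problems <- list()
  add <- function(label, rows, y, classes) {
    counts <- table(factor(y, levels = classes))
    if (any(counts < 2)) {
      stop("scheme ", name, " problem ", label,
           ": each class needs >= 2 rows", call. = FALSE)
    }
    problems[[length(problems) + 1L]] <<- list(label = label, rows = rows,
                                               y = y, classes = classes)
  }
  if (name %in% c("ONE_VS_REST", "COMMON_PREDICTORS")) {
    for (g in groups) {
      rows <- seq_len(nrow(predictors))
      y <- ifelse(predictors$group == g, g, "REST")
      add(g, rows, y, c(g, "REST"))
    }
  } else if (name == "PAIRED") {
    ref <- "CONTROL"
    if (!ref %in% groups) stop("PAIRED scheme needs a CONTROL group",
                               call. = FALSE)
    for (g in setdiff(groups, ref)) {
      rows <- which(predictors$group %in% c(ref, g))
      add(paste0(ref, "-", g), rows, predictors$group[rows], c(ref, g))
    }
  } else if (name == "VD_PRESENCE") {
    rows <- seq_len(nrow(predictors))
    y <- ifelse(predictors$vd_present, "VD", "NO_VD")
    add("VD-NO_VD", rows, y, c("VD", "NO_VD"))
  } else { # CONTROL_VS_MERGED
    rows <- which(predictors$vd_present)
    y <- ifelse(predictors$group[rows] == "CONTROL", "CONTROL", "MERGED")
    add("CONTROL-MERGED", rows, y, c("CONTROL", "MERGED"))
  }
  structure(list(name = name, problems = problems), class = "vq_scheme")
}

#' Exhaustive subset search under one scheme
#'
#' Evaluates a linear discriminant on every non-empty subset of the
#' predictor set, for every binary problem of the scheme. For
#' `COMMON_PREDICTORS` the reported accuracy of a subset is the arithmetic
#' mean of the four one-vs-rest accuracies obtained with that same subset.
#'
#' @param predictors Predictor table from [describe_dataset()].
#' @param scheme A `vq_scheme` or scheme name.
#' @param predictor_set Predictor columns to search over (default all ten;
#'   pass e.g. the five mean predictors for a mean-restricted search).
#' @param eval `"resub"` (resubstitution, default) or `"loocv"`
#'   (leave-one-out).
#' @return Data frame sorted by (`accuracy` desc, `n_predictors` asc,
#'   `subset` asc) within each problem: `scheme`, `class`, `subset`
#'   (bitmask over `predictor_set`), `n_predictors`, `accuracy`, `eval`.
#' @export
subset_search <- function(predictors, scheme,
                          predictor_set = predictor_names(),
                          eval = c("resub", "loocv")) {
  eval <- match.arg(eval)
  if (is.character(scheme)) scheme <- make_scheme(scheme, predictors)
  stopifnot(inherits(scheme, "vq_scheme"),
            all(predictor_set %in% names(predictors)))
  masks <- enumerate_subsets(length(predictor_set))
  nsel <- vapply(masks, function(m) sum(bitwAnd(m, 2^(0:19)) > 0),
                 numeric(1))
  per_problem <- lapply(scheme$problems, function(pb) {
    X <- as.matrix(predictors[pb$rows, predictor_set, drop = FALSE])
    y <- factor(pb$y, levels = pb$classes)
    acc <- vapply(masks, function(m) {
      cols <- vq_subset_columns(m, seq_along(predictor_set))
      vq_subset_accuracy(X[, cols, drop = FALSE], y, eval)
    }, numeric(1))
    data.frame(scheme = scheme$name, class = pb$label, subset = masks,
               n_predictors = nsel, accuracy = acc, eval = eval)
  })
  if (scheme$name == "COMMON_PREDICTORS") {
    acc <- rowMeans(vapply(per_problem, `[[`, numeric(length(masks)),
                           "accuracy"))
    per_problem <- list(data.frame(scheme = scheme$name, class = "COMMON",
                                   subset = masks, n_predictors = nsel,
                                   accuracy = acc, eval = eval))
  }
  res <- do.call(rbind, c(per_problem, make.row.names = FALSE))
  res <- res[order(res$class, -res$accuracy, res$n_predictors, res$subset), ]
  rownames(res) <- NULL
  attr(res, "predictor_set") <- predictor_set
  res
}

#' All subsets tied at the best (accuracy, minimal size)
#'
#' Within each problem of a search result, keeps the subsets reaching the
#' maximum accuracy, and among those the ones of minimal size — all ties are
#' listed, as equal-accuracy alternatives are informative on small samples.
#'
#' @param results Data frame from [subset_search()].
#' @return Filtered data frame with the predictor-flag expansion attached
#'   (columns `uses_<predictor>`).
#' @export
best_subsets <- function(results) {
  predictor_set <- attr(results, "predictor_set")
  out <- lapply(split(results, results$class), function(d) {
    d <- d[d$accuracy == max(d$accuracy), , drop = FALSE]
    d[d$n_predictors == min(d$n_predictors), , drop = FALSE]
  })
  out <- do.call(rbind, c(unname(out), make.row.names = FALSE))
  if (!is.null(predictor_set)) {
    flags <- t(vapply(out$subset, function(m)
      as.integer(bitwAnd(m, 2^(seq_along(predictor_set) - 1)) > 0),
      integer(length(predictor_set))))
    colnames(flags) <- paste0("uses_", predictor_set)
    out <- cbind(out, as.data.frame(flags))
  }
  out
}

#' Pareto front of a search result
#'
#' Non-dominated set under (maximize accuracy, minimize number of
#' predictors): for each subset size on the front, the best accuracy, kept
#' only where it strictly improves on every smaller size.
#'
#' @param results Data frame with `accuracy` and `n_predictors` columns
#'   (one problem; subset the search result by `class` first if needed).
#' @return Data frame of non-dominated rows, ascending `n_predictors`.
#'   Ties at the same (accuracy, size) are all retained.
#' @export
pareto_front <- function(results) {
  stopifnot(nrow(results) > 0)
  keep <- vapply(seq_len(nrow(results)), function(i) {
    dominated <- results$accuracy >= results$accuracy[i] &
      results$n_predictors <= results$n_predictors[i] &
      (results$accuracy > results$accuracy[i] |
         results$n_predictors < results$n_predictors[i])
    !any(dominated)
  }, logical(1))
  out <- results[keep, , drop = FALSE]
  out <- out[order(out$n_predictors, -out$accuracy, out$subset), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Three-predictor separation coordinates
#'
#' For a user-chosen subset of exactly three predictors and one binary
#' problem, returns the case coordinates and the fitted separating plane
#' `w1*x1 + w2*x2 + w3*x3 + b = 0`, for 3-D separability displays.
#'
#' @param predictors Predictor table.
#' @param subset Character vector of three predictor names.
#' @param scheme Scheme name (one with a single problem, e.g.
#'   `"CONTROL_VS_MERGED"` or `"VD_PRESENCE"`), or a `vq_scheme`.
#' @param problem Label of the problem to use (default: the first).
#' @return List with `points` (data frame: the three predictors + `class`),
#'   `weights` (length 3), `intercept`, `accuracy`.
#' @export
separation_3d <- function(predictors, subset, scheme = "CONTROL_VS_MERGED",
                          problem = NULL) {
  stopifnot(length(subset) == 3, all(subset %in% names(predictors)))
  if (is.character(scheme)) scheme <- make_scheme(scheme, predictors)
  labs <- vapply(scheme$problems, `[[`, character(1), "label")
  pb <- scheme$problems[[if (is.null(problem)) 1L else match(problem, labs)]]
  X <- as.matrix(predictors[pb$rows, subset, drop = FALSE])
  y <- factor(pb$y, levels = pb$classes)
  m <- fit_linear(X, y)
  pts <- cbind(as.data.frame(X), class = as.character(y))
  list(points = pts, weights = m$weights, intercept = m$intercept,
       accuracy = model_accuracy(m, X, y))
}

#' Run every applicable scheme and assemble the report bundle
#'
#' Runs the exhaustive search for all five schemes (schemes whose class
#' definition is empty or too small on the given table are skipped with a
#' warning), collects best-subset tables and Pareto fronts per problem, the
#' accuracy histogram data of the common-predictors scheme, and optional
#' 3-D separation coordinates.
#'
#' @param predictors Predictor table from [describe_dataset()].
#' @param out_dir Optional directory; when given, writes
#'   `search_<scheme>.csv`, `best_subsets_<scheme>.csv`,
#'   `pareto_<scheme>.csv`, `common_histogram.csv` and
#'   `separation3d.csv`.
#' @param eval `"resub"` or `"loocv"`.
#' @param schemes Scheme names to run.
#' @param subset3d Optional three predictor names for [separation_3d()].
#' @return List with `results`, `best`, `pareto` (named by scheme),
#'   `common_histogram` and `separation3d`.
#' @export
run_all_schemes <- function(predictors, out_dir = NULL,
                            eval = c("resub", "loocv"),
                            schemes = VQ_SCHEMES, subset3d = NULL) {
  eval <- match.arg(eval)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  results <- list(); best <- list(); pareto <- list()
  for (s in schemes) {
    sch <- tryCatch(make_scheme(s, predictors), error = function(e) {
      warning("skipping scheme ", s, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(sch)) next
    res <- subset_search(predictors, sch, eval = eval)
    results[[s]] <- res
    best[[s]] <- best_subsets(res)
    pf <- lapply(split(res, res$class), pareto_front)
    pareto[[s]] <- do.call(rbind, c(unname(pf), make.row.names = FALSE))
    if (!is.null(out_dir)) {
      utils::write.csv(res, file.path(out_dir, paste0("search_", s, ".csv")),
                       row.names = FALSE)
      utils::write.csv(best[[s]],
                       file.path(out_dir, paste0("best_subsets_", s, ".csv")),
                       row.names = FALSE)
      utils::write.csv(pareto[[s]],
                       file.path(out_dir, paste0("pareto_", s, ".csv")),
                       row.names = FALSE)
    }
  }
  common_histogram <- NULL
  if (!is.null(results$COMMON_PREDICTORS)) {
    common_histogram <- results$COMMON_PREDICTORS[
      order(results$COMMON_PREDICTORS$subset),
      c("subset", "n_predictors", "accuracy")]
    if (!is.null(out_dir)) {
      utils::write.csv(common_histogram,
                       file.path(out_dir, "common_histogram.csv"),
                       row.names = FALSE)
    }
  }
  sep3d <- NULL
  if (!is.null(subset3d)) {
    sep3d <- separation_3d(predictors, subset3d)
    if (!is.null(out_dir)) {
      utils::write.csv(cbind(sep3d$points,
                             w1 = sep3d$weights[1], w2 = sep3d$weights[2],
                             w3 = sep3d$weights[3],
                             intercept = sep3d$intercept),
                       file.path(out_dir, "separation3d.csv"),
                       row.names = FALSE)
    }
  }
  list(results = results, best = best, pareto = pareto,
       common_histogram = common_histogram, separation3d = sep3d)
}
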