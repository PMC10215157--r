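test_that("subset enumeration is exhaustive and deterministically ordered", {
  expect_equal(enumerate_subsets(3), 1:7)
  expect_length(enumerate_subsets(10), 1023L)
  expect_equal(enumerate_subsets(1), 1L)
  expect_error(enumerate_subsets(0))
  expect_error(enumerate_subsets(21))
})

test_that("linear discriminant matches closed-form boundaries", {
  # 1-D separable: boundary between 1 and 10
  X <- matrix(c(0, 1, 10, 11), ncol = 1)
  y <- c("A", "A", "B", "B")
  m <- fit_linear(X, y)
  expect_equal(model_accuracy(m, X, y), 1.0)
  expect_equal(predict(m, matrix(5.4)), "A")
  expect_equal(predict(m, matrix(5.6)), "B")

  # 2-D with a zero-variance coordinate: boundary at x = 2.5
  X2 <- rbind(c(0, 0), c(1, 0), c(4, 0), c(5, 0))
  y2 <- c("A", "A", "B", "B")
  m2 <- fit_linear(X2, y2)
  expect_equal(predict(m2, rbind(c(2.4, 0))), "A")
  expect_equal(predict(m2, rbind(c(2.6, 0))), "B")
  expect_equal(model_accuracy(m2, X2, y2), 1.0)

  # XOR: no linear separator beats 3/4
  X3 <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  y3 <- c("A", "A", "B", "B")
  expect_lte(model_accuracy(fit_linear(X3, y3), X3, y3), 0.75)

  # majority baseline on an uninformative constant feature, 26-vs-6 split
  X4 <- matrix(0, 32, 1)
  y4 <- rep(c("big", "small"), c(26, 6))
  m4 <- fit_linear(X4, y4)
  expect_equal(model_accuracy(m4, X4, y4), 26 / 32)

  expect_error(fit_linear(matrix(1:4, 2), c("A", "A")), "two classes")
})

test_that("discriminant predictions agree with from-scratch and MASS oracles", {
  set.seed(20)
  for (i in 1:10) {
    n <- 24
    p <- sample(1:3, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rep(c("A", "B"), each = n / 2)
    X[y == "B", ] <- X[y == "B", ] + 2.5
    m <- fit_linear(X, y)
    expect_equal(predict(m, X), oracle_lda_predict(X, y))
    expect_equal(model_accuracy(m, X, y),
                 mean(oracle_lda_predict(X, y) == y), tolerance = 1e-9)
  }
  skip_if_not_installed("MASS")
  set.seed(21)
  for (i in 1:5) {
    X <- matrix(rnorm(60), 30, 2)
    y <- rep(c("A", "B"), each = 15)
    X[y == "B", 1] <- X[y == "B", 1] + 3
    df <- data.frame(X, y = y)
    mass_pred <- as.character(predict(MASS::lda(y ~ ., df),
                                      df)$class)
    expect_equal(unname(predict(fit_linear(X, y), X)), mass_pred)
  }
})

test_that("subset search is exhaustive, sorted, and finds planted signal", {
  # groups identical except a 30-sigma mean_mal separation for TMG: a subset
  # with mean_mal reaches accuracy 1 and the best singleton is mean_mal
  tab <- fixture_predictor_table(sep = 30, group_shift = 0)
  res <- subset_search(tab, "PAIRED")
  ct <- res[res$class == "CONTROL-TMG", ]
  expect_equal(nrow(ct), 1023L)
  mal_bit <- 2^(which(predictor_names() == "mean_mal") - 1)
  expect_equal(max(ct$accuracy), 1.0)
  singles <- ct[ct$n_predictors == 1, ]
  expect_equal(singles$subset[which.max(singles$accuracy)], mal_bit)

  # per-class sorting: accuracy desc, then size asc, then bitmask asc
  expect_true(all(diff(ct$accuracy) <= 1e-12))

  # best over all subsets >= best singleton, in every scheme
  for (s in c("ONE_VS_REST", "COMMON_PREDICTORS", "PAIRED", "VD_PRESENCE",
              "CONTROL_VS_MERGED")) {
    r <- subset_search(tab, s)
    for (cl in unique(r$class)) {
      rc <- r[r$class == cl, ]
      expect_gte(max(rc$accuracy), max(rc$accuracy[rc$n_predictors == 1]))
      expect_equal(nrow(rc), 1023L)
    }
  }

  # determinism: identical table, identical result
  expect_identical(subset_search(tab, "VD_PRESENCE"),
                   subset_search(tab, "VD_PRESENCE"))
})

test_that("restricted predictor sets search the reduced space", {
  tab <- fixture_predictor_table()
  means_only <- grep("^mean_", predictor_names(), value = TRUE)
  res <- subset_search(tab, "PAIRED", predictor_set = means_only)
  expect_equal(sort(unique(res$subset)), 1:31)
  expect_equal(nrow(res[res$class == "CONTROL-TMG", ]), 31L)
})

test_that("common-predictors accuracy is the mean of the one-vs-rest four", {
  tab <- fixture_predictor_table()
  ovr <- subset_search(tab, "ONE_VS_REST")
  common <- subset_search(tab, "COMMON_PREDICTORS")
  agg <- tapply(ovr$accuracy, ovr$subset, mean)
  common_by_subset <- common$accuracy[order(common$subset)]
  expect_equal(unname(common_by_subset),
               as.numeric(agg[order(as.integer(names(agg)))]),
               tolerance = 1e-12)
  # and is never above the best of the four
  mx <- tapply(ovr$accuracy, ovr$subset, max)
  expect_true(all(common_by_subset <=
                    as.numeric(mx[order(as.integer(names(mx)))]) + 1e-12))
})

test_that("schemes define the documented class structures", {
  tab <- fixture_predictor_table()
  ovr <- make_scheme("ONE_VS_REST", tab)
  expect_length(ovr$problems, 4L)
  expect_equal(ovr$problems[[1]]$classes[2], "REST")

  paired <- make_scheme("PAIRED", tab)
  expect_equal(vapply(paired$problems, `[[`, character(1), "label"),
               c("CONTROL-TMG", "CONTROL-CMG", "CONTROL-CEG"))

  vdm <- make_scheme("CONTROL_VS_MERGED", tab)
  expect_equal(length(vdm$problems[[1]]$rows), sum(tab$vd_present))

  expect_error(make_scheme("PAIRED", tab[tab$group != "CONTROL", ]),
               "CONTROL")
})

test_that("tie reporting and Pareto front follow the dominance rules", {
  res <- data.frame(scheme = "X", class = "c",
                    subset = c(3L, 5L, 17L, 31L, 127L),
                    n_predictors = c(2, 2, 2, 5, 7),
                    accuracy = c(0.9, 0.9, 0.8, 0.9, 0.95), eval = "resub")
  attr(res, "predictor_set") <- predictor_names()
  best <- best_subsets(res)
  expect_equal(best$subset, 127L)  # unique maximum accuracy
  res2 <- res[1:4, ]
  attr(res2, "predictor_set") <- predictor_names()
  best2 <- best_subsets(res2)
  expect_equal(sort(best2$subset), c(3L, 5L))  # both minimal-size ties listed
  expect_true(all(best2$accuracy == 0.9))
  expect_equal(best2$uses_mean_area, c(1L, 1L))

  front <- pareto_front(res2)
  expect_equal(front$subset, c(3L, 5L))  # (0.8,2) and (0.9,5) dominated
  expect_equal(pareto_front(res[4, , drop = FALSE])$subset, 31L)
  front3 <- pareto_front(data.frame(subset = c(1L, 3L, 7L),
                                    n_predictors = c(1, 2, 3),
                                    accuracy = c(0.8, 0.9, 0.95)))
  expect_equal(front3$n_predictors, c(1, 2, 3))
  # accuracies strictly increase along the front with size
  sizes <- unique(front$n_predictors)
  accs <- vapply(sizes, function(k)
    max(front$accuracy[front$n_predictors == k]), numeric(1))
  expect_true(all(diff(accs) > 0) || length(accs) == 1)
})

test_that("run_all_schemes assembles the full report bundle", {
  tab <- fixture_predictor_table()
  out <- file.path(tempdir(), "vq_search_out")
  unlink(out, recursive = TRUE)
  bundle <- run_all_schemes(tab, out_dir = out,
                            subset3d = c("mean_mal", "sd_mal",
                                         "mean_eccentricity"))
  expect_setequal(names(bundle$results),
                  c("ONE_VS_REST", "COMMON_PREDICTORS", "PAIRED",
                    "VD_PRESENCE", "CONTROL_VS_MERGED"))
  expect_equal(nrow(bundle$common_histogram), 1023L)
  expect_length(bundle$separation3d$weights, 3L)
  expect_true(file.exists(file.path(out, "best_subsets_PAIRED.csv")))
  expect_true(file.exists(file.path(out, "common_histogram.csv")))
  expect_true(file.exists(file.path(out, "separation3d.csv")))

  # leave-one-out protocol is labeled and bounded
  lres <- subset_search(fixture_predictor_table(), "VD_PRESENCE",
                        predictor_set = c("mean_area", "mean_mal"),
                        eval = "loocv")
  expect_true(all(lres$eval == "loocv"))
  expect_true(all(lres$accuracy >= 0 & lres$accuracy <= 1))
})
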