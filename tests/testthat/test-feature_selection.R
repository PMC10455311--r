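test_that("combine_weighted_importance implements the weighted sum", {
  imps <- list(c(f1 = 2, f2 = 1), c(f1 = 0, f2 = 4))
  expect_equal(combine_weighted_importance(imps, c(0.5, 0.25)),
               c(f1 = 1.0, f2 = 1.5))
  expect_equal(combine_weighted_importance(imps, c(0, 0)), c(f1 = 0, f2 = 0))
  # linear in the importances for fixed weights
  scaled <- lapply(imps, `*`, 3)
  expect_equal(combine_weighted_importance(scaled, c(0.5, 0.25)),
               3 * combine_weighted_importance(imps, c(0.5, 0.25)))
})

test_that("weighted importance ranks a planted feature near the top", {
  sm <- get_small_matrix()
  parts <- make_cross_partitions(sm$groups, n_repeats = 2, n_folds = 5,
                                 seed = 14)
  expect_length(parts, 10)
  sc <- weighted_importance(sm$x, sm$y, parts, "regression",
                            params = gbdt_params(n_rounds = 50))
  top5 <- names(sort(sc, decreasing = TRUE))[1:5]
  expect_true(all(c("rsa", "C-score") %in% top5))
})

test_that("select_features recovers planted features and respects max_size", {
  sm <- get_small_matrix()
  trace <- select_features(sm$x, sm$y, sm$groups, "regression",
                           max_size = 8, n_repeats = 2, n_folds = 5,
                           eval_repeats = 1, eval_folds = 5, seed = 15,
                           params = gbdt_params(n_rounds = 50),
                           model_args = list(params = gbdt_params(n_rounds = 50)))
  expect_s3_class(trace, "selection_trace")
  expect_equal(nrow(trace$subset_performance), 8)
  expect_true(all(sm$informative %in%
                    trace$rounds$feature[seq_len(trace$chosen_size)]))
  expect_false(any(duplicated(trace$rounds$feature)))
  # trace reproducibility under the master seed
  trace2 <- select_features(sm$x, sm$y, sm$groups, "regression",
                            max_size = 8, n_repeats = 2, n_folds = 5,
                            eval_repeats = 1, eval_folds = 5, seed = 15,
                            params = gbdt_params(n_rounds = 50),
                            model_args = list(params = gbdt_params(n_rounds = 50)))
  expect_identical(trace$rounds, trace2$rounds)
  expect_identical(trace$chosen_size, trace2$chosen_size)

  # max_size = 1 boundary: a single top-ranked feature
  t1 <- select_features(sm$x[, 1:10], sm$y, sm$groups, "regression",
                        max_size = 1, n_repeats = 1, n_folds = 3,
                        eval_repeats = 1, eval_folds = 3, seed = 16,
                        params = gbdt_params(n_rounds = 30),
                        model_args = list(params = gbdt_params(n_rounds = 30)))
  expect_equal(t1$chosen_size, 1L)
  expect_equal(t1$chosen_features, t1$rounds$feature[1])
  expect_error(select_features(sm$x, sm$y, sm$groups, "regression",
                               max_size = 0), "max_size")
})

test_that("selection trace writes ranking and curve TSVs", {
  sm <- get_small_matrix()
  trace <- select_features(sm$x[, 1:12], sm$labels, sm$groups,
                           "classification", max_size = 3,
                           n_repeats = 1, n_folds = 3,
                           eval_repeats = 1, eval_folds = 3, seed = 17,
                           params = gbdt_params(n_rounds = 25),
                           model_args = list(per_class = 20, seed = 1,
                                             params = gbdt_params(n_rounds = 25)))
  dir <- withr::local_tempdir()
  write_selection_trace(trace, file.path(dir, "rank.tsv"),
                        file.path(dir, "curve.tsv"))
  rank <- read.delim(file.path(dir, "rank.tsv"))
  expect_equal(names(rank), c("rank", "feature", "score"))
  expect_equal(nrow(read.delim(file.path(dir, "curve.tsv"))), 3)
})
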