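test_that("undersample_balanced draws per_class from each class, seeded", {
  set.seed(20)
  labels <- factor(c(rep("decrease", 520), rep("no_effect", 136),
                     rep("increase", 106)), levels = foldvar:::variant_labels())
  idx <- undersample_balanced(labels, per_class = 80, seed = 9)
  expect_length(idx, 240)
  expect_true(all(table(labels[idx]) == 80))
  expect_identical(idx, undersample_balanced(labels, per_class = 80, seed = 9))
  expect_error(undersample_balanced(labels, per_class = 200, seed = 1),
               "increase")
})

test_that("the voting ensemble trains 10 balanced sub-models and separates signal", {
  sm <- get_small_matrix()
  tr_groups <- unique(sm$groups)
  sp <- grouped_split(sm$bench$dataset, 0.3, seed = 2)
  ens <- train_classifier(sm$x[sp$train_indices, ], sm$labels[sp$train_indices],
                          per_class = 25, seed = 4,
                          params = gbdt_params(n_rounds = 40))
  expect_length(ens$sub_models, 10)
  pred <- predict(ens, sm$x[sp$test_indices, ], type = "both")
  expect_equal(rowSums(pred$class_scores), rep(1, length(sp$test_indices)))
  expect_equal(as.character(pred$label),
               colnames(pred$class_scores)[max.col(pred$class_scores,
                                                   ties.method = "first")])
  acc <- mean(pred$label == sm$labels[sp$test_indices])
  expect_gt(acc, 0.6)  # well above the 1/3 chance level
  # retraining with the same master seed reproduces predictions exactly
  ens2 <- train_classifier(sm$x[sp$train_indices, ],
                           sm$labels[sp$train_indices],
                           per_class = 25, seed = 4,
                           params = gbdt_params(n_rounds = 40))
  expect_identical(predict(ens2, sm$x[sp$test_indices, ], type = "prob"),
                   pred$class_scores)
})

test_that("majority voting agrees with soft voting on confident unanimity", {
  sm <- get_small_matrix()
  ens <- train_classifier(sm$x[1:250, ], sm$labels[1:250], per_class = 20,
                          seed = 7, params = gbdt_params(n_rounds = 30))
  probe <- sm$x[251:400, ]
  soft <- predict(ens, probe, type = "class")
  hard <- predict(ens, probe, type = "class", vote = "majority")
  votes <- vapply(ens$sub_models, function(m)
    max.col(predict(m, probe, type = "prob"), ties.method = "first"),
    integer(nrow(probe)))
  top_share <- apply(votes, 1, function(v) max(tabulate(v, 3)))
  conf <- vapply(ens$sub_models, function(m)
    apply(predict(m, probe, type = "prob"), 1, max), numeric(nrow(probe)))
  strong <- top_share == 10 & apply(conf, 1, min) > 0.5
  expect_gt(sum(strong), 0)
  expect_equal(soft[strong], hard[strong])
})

test_that("balanced ensemble beats a single imbalanced model on minority recall", {
  sm <- get_small_matrix()
  sp <- grouped_split(sm$bench$dataset, 0.35, seed = 3)
  tr <- sp$train_indices; te <- sp$test_indices
  ens <- train_classifier(sm$x[tr, ], sm$labels[tr],
                          per_class = min(table(sm$labels[tr])),
                          seed = 5, params = gbdt_params(n_rounds = 40))
  single <- gbdt_fit(sm$x[tr, ], sm$labels[tr], gbdt_params(n_rounds = 40))
  minority <- te[sm$labels[te] == "increase"]
  rec_ens <- mean(predict(ens, sm$x[minority, ]) == "increase")
  rec_single <- mean(predict(single, sm$x[minority, ], type = "class") ==
                       "increase")
  expect_gte(rec_ens, rec_single)
})

test_that("regressor recovers signal; permuted targets carry none", {
  sm <- get_small_matrix()
  tr <- 1:250; te <- 251:400
  m <- train_regressor(sm$x[tr, ], sm$y[tr], gbdt_params(n_rounds = 120))
  expect_gt(cor(predict_delta(m, sm$x[te, ]), sm$y[te]), 0.85)
  yperm <- local({ set.seed(6); sample(sm$y[tr]) })
  mp <- train_regressor(sm$x[tr, ], yperm, gbdt_params(n_rounds = 120))
  r2 <- unname(regression_metrics(predict_delta(mp, sm$x[te, ]),
                                  sm$y[te])$overall["R2"])
  expect_lte(r2, 0.1)
  expect_error(train_regressor(sm$x[1:10, ], sm$y[1:10]), "at least 20")
  expect_error(train_regressor(sm$x[tr, ], c(NA, sm$y[tr][-1])), "non-finite")
})

test_that("model bundles round-trip through the text format with manifest check", {
  sm <- get_small_matrix()
  ens <- train_classifier(sm$x[1:200, ], sm$labels[1:200], per_class = 15,
                          seed = 1, params = gbdt_params(n_rounds = 15))
  dir <- withr::local_tempdir()
  save_model_bundle(ens, file.path(dir, "m"))
  back <- load_model_bundle(file.path(dir, "m"))
  expect_identical(predict(back, sm$x[201:260, ], type = "prob"),
                   predict(ens, sm$x[201:260, ], type = "prob"))

  reg <- train_regressor(sm$x[1:200, ], sm$y[1:200],
                         gbdt_params(n_rounds = 15))
  save_model_bundle(reg, file.path(dir, "r"))
  back_r <- load_model_bundle(file.path(dir, "r"))
  expect_identical(predict_delta(back_r, sm$x[201:260, ]),
                   predict_delta(reg, sm$x[201:260, ]))

  # manifest tampering is detected
  mj <- file.path(dir, "m", "model.json")
  writeLines(c(readLines(mj), " "), mj)
  expect_error(load_model_bundle(file.path(dir, "m")), "manifest mismatch")
})
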