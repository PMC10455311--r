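test_that("classification_metrics matches the per-item tally oracle", {
  set.seed(10)
  classes <- c("decrease", "no_effect", "increase")
  for (i in 1:60) {
    n <- sample(5:200, 1)
    truth <- factor(sample(classes, n, replace = TRUE), levels = classes)
    pred <- factor(sample(classes, n, replace = TRUE), levels = classes)
    rep <- classification_metrics(truth, pred)
    orc <- oracle_metrics(as.character(truth), as.character(pred), classes)
    expect_equal(rep$per_class$SPEC, unname(orc$SPEC))
    expect_equal(rep$per_class$SENS, unname(orc$SENS))
    expect_equal(rep$per_class$F1, unname(orc$F1))
    expect_equal(unname(rep$overall["ACC"]), orc$ACC)
    expect_equal(unname(rep$overall["macro_F1"]), orc$macro_F1)
  }
})

test_that("GC2 attains its limits and the binary phi^2 identity", {
  # perfect diagonal table of any class sizes -> ACC = 1, GC2 = 1, F1 = 1
  z <- diag(c(50, 13, 7))
  rep <- classification_metrics(z)
  expect_equal(unname(rep$overall["ACC"]), 1)
  expect_equal(unname(rep$overall["GC2"]), 1)
  expect_equal(rep$per_class$F1, rep(1, 3))
  # observed == expected -> GC2 = 0
  x <- c(30, 20, 10); y <- c(25, 20, 15)
  z0 <- outer(x, y) / 60
  expect_equal(unname(classification_metrics(z0)$overall["GC2"]), 0)
  # K = 2: GC2 equals the squared phi coefficient
  set.seed(11)
  for (i in 1:20) {
    z2 <- matrix(sample(1:40, 4, replace = TRUE), 2, 2)
    gc2 <- unname(classification_metrics(z2)$overall["GC2"])
    a <- z2[1, 1]; b <- z2[1, 2]; c <- z2[2, 1]; d <- z2[2, 2]
    phi <- (a * d - b * c) /
      sqrt((a + b) * (c + d) * (a + c) * (b + d))
    expect_equal(gc2, phi^2)
  }
  # invariance under simultaneous row/column permutation
  z3 <- matrix(c(30, 5, 2, 8, 20, 4, 1, 3, 10), 3, 3)
  perm <- c(3, 1, 2)
  expect_equal(unname(classification_metrics(z3[perm, perm])$overall["GC2"]),
               unname(classification_metrics(z3)$overall["GC2"]))
})

test_that("zero-denominator metrics are flagged undefined, not zeroed", {
  truth <- factor(c("a", "a", "b"), levels = c("a", "b", "c"))
  pred <- factor(c("a", "b", "b"), levels = c("a", "b", "c"))
  rep <- classification_metrics(truth, pred)
  expect_true(is.na(rep$per_class$SPEC[3]))   # class c never predicted
  expect_true("SPEC" %in% rep$undefined)
})

test_that("regression metrics follow their defining equations", {
  y <- c(1, 2, 3); p <- c(1, 2, 4)
  rep <- regression_metrics(p, y)
  expect_equal(unname(rep$overall["MAE"]), 1 / 3)
  expect_equal(unname(rep$overall["MSE"]), 1 / 3)
  ident <- regression_metrics(y, y)
  expect_equal(unname(ident$overall[c("PCC", "MAE", "MSE", "R2")]),
               c(1, 0, 0, 1))
  # predicting the mean gives R2 = 0 (PCC undefined: constant predictions)
  base <- regression_metrics(rep(mean(y), 3), y)
  expect_equal(unname(base$overall["R2"]), 0)
  expect_true(is.na(base$overall["PCC"]))
  expect_error(regression_metrics(1:3, 1:4), "differ in length")
})

test_that("confusion_from_perclass recovers marginals and flags GC2", {
  counts <- read.delim(system.file("extdata", "blind_confusion_counts.tsv",
                                   package = "foldvar"), comment.char = "#")
  all_feats <- counts[counts$feature_set == "all", ]
  cs <- confusion_from_perclass(setNames(all_feats$TP, all_feats$class),
                                setNames(all_feats$FP, all_feats$class),
                                setNames(all_feats$FN, all_feats$class),
                                N = 190)
  expect_equal(unname(cs$x), c(133, 39, 18))
  expect_equal(unname(cs$y), c(89, 44, 57))
  rep <- classification_metrics(cs)
  expect_true(is.na(rep$overall["GC2"]))      # off-diagonals under-determined
  expect_true("GC2" %in% rep$undefined)
  # inconsistent counts are rejected with the violated identity
  expect_error(confusion_from_perclass(c(10, 10), c(0, 0), c(0, 0), N = 30),
               "sum\\(TP \\+ FN\\)")
})

test_that("metric reports serialise to TSV and JSON", {
  rep <- classification_metrics(diag(c(5, 5, 5)))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_metric_report(rep, tsv)
  write_metric_report(rep, js, format = "json")
  back <- read.delim(tsv)
  expect_true(all(c("ACC", "GC2", "SPEC") %in% back$metric))
  expect_equal(back$value[back$metric == "ACC"], 1)
  expect_silent(jsonlite::read_json(js))
})
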