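# Weighted-importance feature selection over repeated grouped
# cross-divisions: each partition's tree-model importances are weighted by
# that partition's test performance (accuracy for classification, Pearson
# correlation for regression), summed into one ranking, and nested subsets
# of increasing size are scored by repeated cross-validation.

#' Build repeated grouped train/test partitions
#'
#' `n_repeats` x `n_folds` group-disjoint divisions (default 10 x 5 = 50),
#' each returned as a train/test index pair.
#'
#' @param groups group key per record.
#' @param n_repeats,n_folds protocol dimensions.
#' @param seed master seed.
#' @return list of lists with elements `train` and `test`.
#' @export
make_cross_partitions <- function(groups, n_repeats = 10L, n_folds = 5L,
                                  seed = 1L) {
  repeat_seeds <- derive_seeds(seed, n_repeats)
  out <- list()
  for (r in seq_len(n_repeats)) {
    folds <- make_grouped_folds(groups, n_folds, repeat_seeds[r])
    for (f in seq_len(n_folds))
      out[[length(out) + 1L]] <- list(train = which(folds != f),
                                      test = which(folds == f))
  }
  out
}

#' Combine per-partition importances into weighted scores
#'
#' The selection statistic: score(f) = sum_k weight_k * importance_k(f).
#' Linear in the importances for fixed weights.
#'
#' @param importance_list list of named numeric importance vectors (same
#'   names in each).
#' @param weights numeric vector, one weight per partition.
#' @return named numeric score per feature.
#' @export
combine_weighted_importance <- function(importance_list, weights) {
  stopifnot(length(importance_list) == length(weights))
  Reduce(`+`, Map(function(imp, w) w * imp, importance_list, weights))
}

#' Performance-weighted feature importance
#'
#' For every partition: (classification) balance the training side by
#' under-sampling all classes to the smallest class, train one boosted-tree
#' model, and take its feature importances weighted by the partition's test
#' accuracy; (regression) train on the unbalanced side and weight by the
#' test Pearson correlation.  Scores are the sum over partitions.
#' Partitions whose test side holds a single class (classification) or has
#' zero target variance (regression) are skipped with a warning.
#'
#' @param x feature matrix.
#' @param y labels or numeric targets.
#' @param partitions list of train/test index pairs
#'   (see [make_cross_partitions()]).
#' @param task `"classification"` or `"regression"`.
#' @param params [gbdt_params()] for the per-partition models.
#' @param importance `"gain"` (default) or `"count"`.
#' @param balance_seed seed for the per-partition balancing draws.
#' @return named numeric score per feature.
#' @export
weighted_importance <- function(x, y, partitions,
                                task = c("classification", "regression"),
                                params = gbdt_params(n_rounds = 60L),
                                importance = c("gain", "count"),
                                balance_seed = 1L) {
  task <- match.arg(task)
  importance <- match.arg(importance)
  x <- as.matrix(x)
  if (task == "classification") y <- as.factor(y)
  imps <- list()
  weights <- numeric(0)
  part_seeds <- derive_seeds(balance_seed, length(partitions))
  for (i in seq_along(partitions)) {
    tr <- partitions[[i]]$train
    te <- partitions[[i]]$test
    if (task == "classification") {
      if (length(unique(y[te])) < 2) {
        warnf("partition %d skipped: single-class test set", i)
        next
      }
      per_class <- min(table(y[tr]))
      if (per_class < 1) {
        warnf("partition %d skipped: class missing from training side", i)
        next
      }
      idx <- tr[undersample_balanced(droplevels(y[tr]), per_class,
                                     part_seeds[i])]
      model <- gbdt_fit(x[idx, , drop = FALSE], droplevels(y[idx]), params)
      pred <- predict(model, x[te, , drop = FALSE], type = "class")
      w <- mean(as.character(pred) == as.character(y[te]))
    } else {
      if (sd(y[te]) == 0) {
        warnf("partition %d skipped: constant test targets", i)
        next
      }
      model <- gbdt_fit(x[tr, , drop = FALSE], y[tr], params)
      pred <- predict(model, x[te, , drop = FALSE])
      w <- if (sd(pred) == 0) 0 else cor(pred, y[te])
    }
    imps[[length(imps) + 1L]] <- gbdt_importance(model, importance)
    weights <- c(weights, w)
  }
  if (!length(imps)) return(setNames(numeric(ncol(x)), colnames(x)))
  combine_weighted_importance(imps, weights)
}

#' Iterative weighted-importance feature selection
#'
#' Ranks all features by [weighted_importance()] over `n_repeats` x
#' `n_folds` partitions (ties broken lexicographically by feature name for
#' determinism), then evaluates nested subsets of increasing size with
#' repeated grouped cross-validation; the chosen size maximises the CV
#' metric (accuracy or Pearson correlation), preferring the smaller subset
#' on ties.  `mode = "backward"` instead evaluates subsets formed by
#' dropping the lowest-ranked features from the full set.
#'
#' @param x feature matrix.
#' @param y labels or numeric targets.
#' @param groups group key per record.
#' @param task `"classification"` or `"regression"`.
#' @param max_size largest subset size to evaluate.
#' @param n_repeats,n_folds partition protocol for the ranking stage.
#' @param eval_repeats,eval_folds protocol for subset evaluation.
#' @param seed master seed.
#' @param params [gbdt_params()] for ranking and evaluation models.
#' @param model_args extra arguments for the evaluation trainer.
#' @param mode `"forward"` (default) or `"backward"`.
#' @return object of class `selection_trace`: `rounds` (rank, feature,
#'   score), `subset_performance` (size, metric), `chosen_size`,
#'   `chosen_features`.
#' @export
select_features <- function(x, y, groups,
                            task = c("classification", "regression"),
                            max_size = 30L, n_repeats = 10L, n_folds = 5L,
                            eval_repeats = n_repeats, eval_folds = n_folds,
                            seed = 1L, params = gbdt_params(n_rounds = 60L),
                            model_args = list(), mode = c("forward",
                                                          "backward")) {
  task <- match.arg(task)
  mode <- match.arg(mode)
  x <- as.matrix(x)
  if (max_size < 1) stopf("max_size must be >= 1")
  if (max_size > ncol(x)) stopf("max_size exceeds feature count")
  seeds <- derive_seeds(seed, 3L)
  partitions <- make_cross_partitions(groups, n_repeats, n_folds, seeds[1])
  scores <- weighted_importance(x, y, partitions, task, params,
                                balance_seed = seeds[2])
  ranking <- order(-scores, names(scores))
  rounds <- data.frame(rank = seq_along(ranking),
                       feature = names(scores)[ranking],
                       score = unname(scores[ranking]))

  sizes <- seq_len(max_size)
  metric_name <- if (task == "classification") "ACC" else "PCC"
  perf <- vapply(sizes, function(s) {
    keep <- if (mode == "forward") rounds$feature[seq_len(s)]
            else rounds$feature[seq_len(ncol(x) - max_size + s)]
    cv <- run_cv(x[, keep, drop = FALSE], y, groups, task,
                 cv_protocol(eval_repeats, eval_folds, seed = seeds[3]),
                 model_args)
    unname(cv$pooled$overall[metric_name])
  }, numeric(1))
  subset_performance <- data.frame(size = if (mode == "forward") sizes
                                   else ncol(x) - max_size + sizes,
                                   metric = perf)
  best <- which.max(perf)   # first maximum -> smallest size on ties
  chosen_size <- subset_performance$size[best]
  chosen <- rounds$feature[seq_len(chosen_size)]
  structure(list(rounds = rounds, subset_performance = subset_performance,
                 chosen_size = chosen_size, chosen_features = chosen,
                 task = task, metric = metric_name, mode = mode,
                 seed = seed), class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("<selection_trace (%s, %s): chose %d features, best %s = %.3f>\n",
              x$task, x$mode, x$chosen_size, x$metric,
              max(x$subset_performance$metric)))
  print(head(x$rounds, x$chosen_size), row.names = FALSE)
  invisible(x)
}

#' Write a selection trace to TSV files
#'
#' Writes the ranking (rank, feature, score) and the subset-performance
#' curve (size, metric).
#'
#' @param trace a `selection_trace`.
#' @param ranking_path,curve_path output files.
#' @export
write_selection_trace <- function(trace, ranking_path, curve_path) {
  write_tsv(trace$rounds, ranking_path)
  write_tsv(trace$subset_performance, curve_path)
  invisible(ranking_path)
}
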