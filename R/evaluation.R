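# Cross-validation drivers: repeated grouped k-fold evaluation and the
# blind-test protocol, with leakage checks on the (protein, position)
# grouping.

#' Group-disjoint fold assignment
#'
#' Shuffles the unique groups under the seed and assigns each to the fold
#' with the fewest records so far, keeping folds size-balanced while never
#' splitting a group.
#'
#' @param groups character vector of group keys, one per record.
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return integer fold id (1..n_folds) per record.
#' @export
make_grouped_folds <- function(groups, n_folds = 5L, seed = 1L) {
  sizes <- table(groups)
  shuffled <- local_seed(seed, sample(names(sizes)))
  fold_of <- setNames(integer(length(sizes)), shuffled)
  load <- numeric(n_folds)
  for (g in shuffled) {
    f <- which.min(load)
    fold_of[[g]] <- f
    load[f] <- load[f] + sizes[[g]]
  }
  unname(fold_of[groups])
}

#' Cross-validation protocol description
#'
#' @param n_repeats repetitions of the k-fold division (default 10).
#' @param n_folds folds per repetition (default 5).
#' @param balanced train sub-models on balanced under-samples
#'   (classification only).
#' @param seed master seed; each repeat uses a distinct derived seed.
#' @return list of class `cv_protocol`.
#' @export
cv_protocol <- function(n_repeats = 10L, n_folds = 5L, balanced = TRUE,
                        seed = 1L) {
  structure(list(n_repeats = as.integer(n_repeats),
                 n_folds = as.integer(n_folds), balanced = balanced,
                 seed = as.integer(seed)), class = "cv_protocol")
}

# Fit + predict one train/test division for either task.
fit_eval_once <- function(x, y, train_idx, test_idx, task, model_args) {
  if (task == "classification") {
    model <- do.call(train_classifier,
                     c(list(x = x[train_idx, , drop = FALSE],
                            y = y[train_idx]), model_args))
    pred <- predict(model, x[test_idx, , drop = FALSE], type = "class")
    list(pred = pred,
         report = classification_metrics(y[test_idx], pred,
                                         levels = levels(y)))
  } else {
    model <- do.call(train_regressor,
                     c(list(x = x[train_idx, , drop = FALSE],
                            y = y[train_idx]), model_args))
    pred <- predict_delta(model, x[test_idx, , drop = FALSE])
    list(pred = pred, report = regression_metrics(pred, y[test_idx]))
  }
}

#' Repeated grouped cross-validation
#'
#' Runs the n_repeats x n_folds protocol (default 10 x 5 = 50 fold
#' evaluations).  Classification folds whose training side lacks a class
#' are skipped with a warning.  Returns all fold-level reports plus a
#' pooled report: summed confusion counts for classification, concatenated
#' predictions for regression.
#'
#' @param x feature matrix.
#' @param y labels (factor) or numeric targets.
#' @param groups group key per record ((protein, position) style).
#' @param task `"classification"` or `"regression"`.
#' @param protocol a [cv_protocol()].
#' @param model_args list of extra arguments for [train_classifier()] /
#'   [train_regressor()].
#' @return list of class `cv_result`: fold_reports, pooled, predictions.
#' @export
run_cv <- function(x, y, groups, task = c("classification", "regression"),
                   protocol = cv_protocol(), model_args = list()) {
  task <- match.arg(task)
  x <- as.matrix(x)
  if (task == "classification") y <- as.factor(y)
  repeat_seeds <- derive_seeds(protocol$seed, protocol$n_repeats)
  fold_reports <- list()
  all_pred <- list()
  all_truth <- list()
  pooled_confusion <- NULL
  for (r in seq_len(protocol$n_repeats)) {
    folds <- make_grouped_folds(groups, protocol$n_folds, repeat_seeds[r])
    for (f in seq_len(protocol$n_folds)) {
      test_idx <- which(folds == f)
      train_idx <- which(folds != f)
      if (task == "classification" &&
          length(unique(y[train_idx])) < nlevels(y)) {
        warnf("repeat %d fold %d skipped: class missing from training side",
              r, f)
        next
      }
      res <- fit_eval_once(x, y, train_idx, test_idx, task, model_args)
      fold_reports[[length(fold_reports) + 1L]] <- res$report
      all_pred[[length(all_pred) + 1L]] <- res$pred
      all_truth[[length(all_truth) + 1L]] <- y[test_idx]
      if (task == "classification") {
        cm <- confusion_matrix(y[test_idx], res$pred, levels = levels(y))
        pooled_confusion <- if (is.null(pooled_confusion)) unclass(cm)
                            else pooled_confusion + unclass(cm)
      }
    }
  }
  pooled <- if (task == "classification")
    classification_metrics(confusion_summary(pooled_confusion))
  else regression_metrics(unlist(all_pred), unlist(all_truth))
  structure(list(task = task, fold_reports = fold_reports, pooled = pooled,
                 predictions = all_pred, truths = all_truth,
                 protocol = protocol), class = "cv_result")
}

#' Blind-test evaluation
#'
#' Trains on the training set and evaluates once on a held-out set, after
#' verifying that no (protein, position) group occurs on both sides.
#'
#' @param x_train,y_train,groups_train training data.
#' @param x_test,y_test,groups_test held-out data.
#' @param task `"classification"` or `"regression"`.
#' @param model_args extra arguments for the trainer.
#' @return a `metric_report`.
#' @export
run_blind_test <- function(x_train, y_train, groups_train,
                           x_test, y_test, groups_test,
                           task = c("classification", "regression"),
                           model_args = list()) {
  task <- match.arg(task)
  leak <- intersect(unique(groups_train), unique(groups_test))
  if (length(leak))
    stopf("group leakage between train and test sets: %s",
          paste(head(leak, 10), collapse = ", "))
  x <- rbind(as.matrix(x_train), as.matrix(x_test))
  if (task == "classification") {
    y <- factor(c(as.character(y_train), as.character(y_test)),
                levels = levels(as.factor(y_train)))
  } else y <- c(y_train, y_test)
  n_train <- nrow(as.matrix(x_train))
  res <- fit_eval_once(x, y, seq_len(n_train),
                       n_train + seq_len(nrow(as.matrix(x_test))),
                       task, model_args)
  res$report
}
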