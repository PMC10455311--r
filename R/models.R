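# The two predictors: a class-balanced under-sampling voting ensemble for
# the three-class task, and a boosted-tree regressor for the log rate
# change.  Model bundles serialise to a plain-text directory.

#' Balanced under-sample of a labelled index set
#'
#' Draws exactly `per_class` indices from every class without replacement,
#' deterministically for a given seed.
#'
#' @param labels factor of class labels.
#' @param per_class samples per class (default 80).
#' @param seed integer seed.
#' @return sorted integer vector of indices, length K * per_class.
#' @export
undersample_balanced <- function(labels, per_class = 80L, seed = 1L) {
  labels <- as.factor(labels)
  counts <- table(labels)
  deficient <- names(counts)[counts < per_class]
  if (length(deficient))
    stopf("class(es) smaller than per_class = %d: %s", per_class,
          paste(sprintf("%s (%d)", deficient, counts[deficient]),
                collapse = ", "))
  local_seed(seed, {
    idx <- unlist(lapply(levels(labels), function(l)
      sample(which(labels == l), per_class)))
  })
  sort(idx)
}

#' Train the three-class voting ensemble
#'
#' Trains `n_models` boosted-tree sub-classifiers, each on an independent
#' balanced under-sample of `per_class` variants per class (sub-seeds
#' derived from the master seed), and combines them by voting.
#'
#' @param x feature matrix (named columns).
#' @param y factor of labels (decrease / no_effect / increase).
#' @param per_class under-sample size per class (default 80).
#' @param n_models number of sub-classifiers (default 10).
#' @param seed master seed.
#' @param params [gbdt_params()] for the sub-models.
#' @param vote `"probability_sum"` (soft voting, default) or `"majority"`.
#' @return object of class `fold_ensemble`.
#' @export
train_classifier <- function(x, y, per_class = 80L, n_models = 10L,
                             seed = 1L,
                             params = gbdt_params(n_rounds = 60L),
                             vote = c("probability_sum", "majority")) {
  vote <- match.arg(vote)
  x <- as.matrix(x)
  y <- as.factor(y)
  if (all(levels(y) %in% variant_labels()))  # canonical label order
    y <- factor(as.character(y), levels = variant_labels())
  if (length(unique(y)) < 2) stopf("degenerate input: single class")
  sub_seeds <- derive_seeds(seed, n_models)
  sub_models <- lapply(seq_len(n_models), function(i) {
    idx <- undersample_balanced(y, per_class, sub_seeds[i])
    gbdt_fit(x[idx, , drop = FALSE], droplevels(y[idx]), params)
  })
  structure(list(sub_models = sub_models, per_class = as.integer(per_class),
                 feature_names = colnames(x), class_levels = levels(y),
                 vote = vote, seed = as.integer(seed), params = params),
            class = "fold_ensemble")
}

#' Predict with the voting ensemble
#'
#' Soft voting averages the sub-model class probabilities; the label is the
#' argmax.  Majority voting tallies sub-model argmax labels, breaking ties
#' by the fixed class order (decrease, no_effect, increase).
#'
#' @param object a `fold_ensemble`.
#' @param newdata feature matrix.
#' @param type `"class"`, `"prob"`, or `"both"`.
#' @param vote override the ensemble's voting rule.
#' @param ... unused.
#' @return factor of labels, probability matrix, or a list with both.
#' @export
predict.fold_ensemble <- function(object, newdata,
                                  type = c("class", "prob", "both"),
                                  vote = NULL, ...) {
  type <- match.arg(type)
  vote <- vote %||% object$vote
  newdata <- align_features(newdata, object$feature_names)
  probs <- lapply(object$sub_models, function(m) {
    p <- predict(m, newdata, type = "prob")
    full <- matrix(0, nrow(newdata), length(object$class_levels),
                   dimnames = list(NULL, object$class_levels))
    full[, colnames(p)] <- p
    full
  })
  mean_p <- Reduce(`+`, probs) / length(probs)
  if (vote == "probability_sum") {
    lab <- factor(object$class_levels[max.col(mean_p, ties.method = "first")],
                  levels = object$class_levels)
  } else {
    votes <- vapply(probs, function(p)
      max.col(p, ties.method = "first"), integer(nrow(newdata)))
    if (nrow(newdata) == 1) votes <- matrix(votes, nrow = 1)
    lab <- factor(object$class_levels[apply(votes, 1, function(v)
      which.max(tabulate(v, length(object$class_levels))))],
      levels = object$class_levels)
  }
  switch(type, class = lab, prob = mean_p,
         both = list(label = lab, class_scores = mean_p))
}

#' @export
print.fold_ensemble <- function(x, ...) {
  cat(sprintf(
    "<fold_ensemble: %d sub-models, %d/class under-sampling, %s voting>\n",
    length(x$sub_models), x$per_class, x$vote))
  invisible(x)
}

#' Train the regression predictor for the log folding-rate change
#'
#' @param x feature matrix.
#' @param y numeric log rate changes.
#' @param params [gbdt_params()].
#' @param seed kept for interface symmetry; the booster is deterministic.
#' @return object of class `fold_regressor`.
#' @export
train_regressor <- function(x, y, params = gbdt_params(), seed = 1L) {
  x <- as.matrix(x)
  if (nrow(x) < 20) stopf("need at least 20 training examples")
  if (any(!is.finite(y))) stopf("non-finite regression target")
  structure(list(model = gbdt_fit(x, as.numeric(y), params),
                 feature_names = colnames(x), seed = as.integer(seed)),
            class = "fold_regressor")
}

#' Predict log folding-rate changes
#' @param model a `fold_regressor`.
#' @param newdata feature matrix.
#' @return numeric vector of predicted log rate changes.
#' @export
predict_delta <- function(model, newdata) {
  stopifnot(inherits(model, "fold_regressor"))
  predict(model$model, newdata)
}

#' @export
predict.fold_regressor <- function(object, newdata, ...) {
  predict_delta(object, newdata)
}

BUNDLE_FORMAT <- "foldvar-bundle-1"

#' Save a trained model as a plain-text directory bundle
#'
#' Writes config.json (format version, model type, seeds, hyperparameters),
#' feature_names.txt, model.json (the trees) and manifest.json with md5
#' checksums that [load_model_bundle()] validates.
#'
#' @param model a `fold_ensemble` or `fold_regressor`.
#' @param dir target directory (created if needed).
#' @export
save_model_bundle <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  type <- class(model)[1]
  cfg <- list(format = BUNDLE_FORMAT, type = type, seed = model$seed)
  if (type == "fold_ensemble") {
    cfg$per_class <- model$per_class
    cfg$vote <- model$vote
    cfg$class_levels <- model$class_levels
    cfg$params <- unclass(model$params)
    payload <- lapply(model$sub_models, function(m)
      list(fit = m$fit, class_levels = m$class_levels,
           params = unclass(m$params)))
  } else if (type == "fold_regressor") {
    cfg$params <- unclass(model$model$params)
    payload <- list(fit = model$model$fit)
  } else stopf("cannot bundle object of class %s", type)
  writeLines(model$feature_names, file.path(dir, "feature_names.txt"))
  jsonlite::write_json(payload, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = I(17), null = "null")
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = I(17))
  md5 <- as.list(tools::md5sum(file.path(dir,
                                         c("model.json", "feature_names.txt"))))
  names(md5) <- c("model.json", "feature_names.txt")
  jsonlite::write_json(md5, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

rebuild_fit <- function(fit) {
  fit$trees <- lapply(fit$trees, function(t) {
    t$feature <- as.integer(t$feature)
    t$left <- as.integer(t$left)
    t$right <- as.integer(t$right)
    t$threshold <- as.numeric(t$threshold)
    t$value <- as.numeric(t$value)
    t
  })
  fit$n_class <- as.integer(fit$n_class)
  fit
}

#' Load a model bundle, validating its manifest
#'
#' @param dir bundle directory written by [save_model_bundle()].
#' @return the restored model object.
#' @export
load_model_bundle <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  if (!identical(cfg$format, BUNDLE_FORMAT))
    stopf("unsupported bundle format: %s", cfg$format %||% "<missing>")
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  for (f in names(manifest)) {
    got <- unname(tools::md5sum(file.path(dir, f)))
    if (!identical(got, manifest[[f]]))
      stopf("bundle manifest mismatch for %s", f)
  }
  feature_names <- readLines(file.path(dir, "feature_names.txt"))
  payload <- jsonlite::read_json(file.path(dir, "model.json"),
                                 simplifyVector = TRUE, simplifyMatrix = FALSE,
                                 simplifyDataFrame = FALSE)
  params <- do.call(gbdt_params, cfg$params)
  if (cfg$type == "fold_ensemble") {
    subs <- lapply(payload, function(p)
      structure(list(fit = rebuild_fit(p$fit),
                     feature_names = feature_names,
                     class_levels = unlist(p$class_levels),
                     params = params), class = "gbdt"))
    structure(list(sub_models = subs, per_class = cfg$per_class,
                   feature_names = feature_names,
                   class_levels = unlist(cfg$class_levels),
                   vote = cfg$vote, seed = cfg$seed, params = params),
              class = "fold_ensemble")
  } else {
    structure(list(model = structure(list(fit = rebuild_fit(payload$fit),
                                          feature_names = feature_names,
                                          class_levels = NULL,
                                          params = params), class = "gbdt"),
                   feature_names = feature_names, seed = cfg$seed),
              class = "fold_regressor")
  }
}
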