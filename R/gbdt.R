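# R interface to the deterministic gradient-boosted decision tree engine.

#' Gradient boosting hyperparameters
#'
#' All tuning knobs of the tree booster in one place.  The defaults are a
#' small fixed configuration chosen for determinism and desk-scale speed:
#' no stochastic subsampling, no early stopping, modest depth.
#'
#' @param n_rounds number of boosting rounds (trees per class).
#' @param learning_rate shrinkage applied to each leaf weight.
#' @param max_depth maximum tree depth (root = depth 0).
#' @param min_leaf minimum samples per leaf.
#' @param lambda L2 regularisation on leaf weights.
#' @param min_gain minimum split gain.
#' @return a list of class `gbdt_params`.
#' @export
gbdt_params <- function(n_rounds = 100L, learning_rate = 0.1, max_depth = 5L,
                        min_leaf = 5L, lambda = 1.0, min_gain = 1e-7) {
  stopifnot(n_rounds >= 1, learning_rate > 0, max_depth >= 1, min_leaf >= 1,
            lambda >= 0, min_gain >= 0)
  structure(list(n_rounds = as.integer(n_rounds),
                 learning_rate = learning_rate,
                 max_depth = as.integer(max_depth),
                 min_leaf = as.integer(min_leaf),
                 lambda = lambda, min_gain = min_gain),
            class = "gbdt_params")
}

#' Fit a gradient-boosted tree model
#'
#' Newton boosting with exact greedy splits; squared-error regression or
#' softmax multiclass classification.  Fully deterministic: the same
#' (x, y, params) always yields the same model.
#'
#' @param x numeric feature matrix with column names.
#' @param y numeric response (regression) or factor (classification).
#' @param params a [gbdt_params()] object.
#' @return object of class `gbdt`.
#' @export
gbdt_fit <- function(x, y, params = gbdt_params()) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  storage.mode(x) <- "double"
  if (anyNA(x)) stopf("feature matrix contains missing values")
  if (is.factor(y)) {
    levels_ <- levels(y)
    if (length(levels_) < 2) stopf("classification needs >= 2 classes")
    if (length(unique(y)) < 2)
      stopf("degenerate input: only one class present")
    yc <- as.numeric(as.integer(y) - 1L)
    objective <- "multiclass"
    k <- length(levels_)
  } else {
    y <- as.numeric(y)
    if (any(!is.finite(y))) stopf("non-finite regression target")
    levels_ <- NULL
    yc <- y
    objective <- "regression"
    k <- 1L
  }
  if (length(yc) != nrow(x)) stopf("x and y lengths differ")
  fit <- .gbdt_train_cpp(x, yc, objective, as.integer(k), params$n_rounds,
                         params$learning_rate, params$max_depth,
                         params$min_leaf, params$lambda, params$min_gain)
  structure(list(fit = fit, feature_names = colnames(x),
                 class_levels = levels_, params = params),
            class = "gbdt")
}

# Align a prediction matrix to the training feature set; loud failure on
# mismatch, naming what is missing or extra.
align_features <- function(newdata, feature_names) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (is.null(colnames(newdata))) {
    if (ncol(newdata) != length(feature_names))
      stopf("unnamed matrix has %d columns; model expects %d",
            ncol(newdata), length(feature_names))
    colnames(newdata) <- feature_names
    return(newdata)
  }
  missing <- setdiff(feature_names, colnames(newdata))
  if (length(missing))
    stopf("missing feature(s): %s", paste(head(missing, 5), collapse = ", "))
  newdata[, feature_names, drop = FALSE]
}

#' @export
predict.gbdt <- function(object, newdata,
                         type = c("response", "prob", "class"), ...) {
  type <- match.arg(type)
  newdata <- align_features(newdata, object$feature_names)
  raw <- .gbdt_predict_cpp(object$fit, newdata)
  if (object$fit$objective == "regression") return(drop(raw))
  # softmax over raw class scores
  m <- apply(raw, 1, max)
  p <- exp(raw - m)
  p <- p / rowSums(p)
  colnames(p) <- object$class_levels
  if (type == "class" || type == "response") {
    lab <- factor(object$class_levels[max.col(p, ties.method = "first")],
                  levels = object$class_levels)
    if (type == "class") return(lab)
  }
  p
}

#' Feature importances of a boosted model
#'
#' @param model a `gbdt` object.
#' @param type `"gain"` (total split gain, default) or `"count"` (number of
#'   times a feature was used to split).
#' @return named numeric vector over the model's features.
#' @export
gbdt_importance <- function(model, type = c("gain", "count")) {
  type <- match.arg(type)
  v <- if (type == "gain") model$fit$importance_gain
       else model$fit$importance_count
  setNames(as.numeric(v), model$feature_names)
}

#' @export
print.gbdt <- function(x, ...) {
  cat(sprintf("<gbdt %s model: %d features, %d trees>\n",
              x$fit$objective, length(x$feature_names),
              length(x$fit$trees)))
  invisible(x)
}
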