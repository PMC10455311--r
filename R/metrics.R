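# Performance assessment: per-class SPEC/SENS/F1, macro-F1, accuracy, the
# generalized squared correlation (GC2), and the regression suite
# (PCC / MAE / MSE / R2).
#
# Naming follows the folding-rate prediction literature: "SPEC" here is
# TP/(TP+FP), mathematically precision, and "SENS" is recall; the report
# carries precision/recall aliases rather than silently renaming published
# quantities.

#' Confusion matrix from labels
#'
#' @param truth,pred factors (or vectors coercible) over the same classes.
#' @param levels class levels; default: levels of `truth`.
#' @return K x K integer matrix, rows = truth, cols = predicted.
#' @export
confusion_matrix <- function(truth, pred, levels = NULL) {
  levels <- levels %||% (if (is.factor(truth)) base::levels(truth)
                         else sort(unique(c(truth, pred))))
  table(factor(truth, levels), factor(pred, levels), dnn = c("truth", "pred"))
}

#' Per-class confusion summary
#'
#' Derives the per-class TP/TN/FP/FN counts and marginals from a full
#' confusion matrix.
#'
#' @param z K x K confusion matrix (rows = truth, cols = predicted).
#' @return object of class `confusion_summary` with z, N, K, per-class
#'   counts, x (actual marginals) and y (predicted marginals).
#' @export
confusion_summary <- function(z) {
  z <- as.matrix(unclass(z))
  K <- nrow(z)
  stopifnot(ncol(z) == K)
  N <- sum(z)
  if (N <= 0) stopf("empty confusion matrix")
  TP <- diag(z)
  x <- rowSums(z)   # actuals per class
  y <- colSums(z)   # predictions per class
  structure(list(z = z, N = N, K = K, TP = TP, FP = y - TP, FN = x - TP,
                 TN = N - x - y + TP, x = x, y = y,
                 classes = rownames(z) %||% paste0("class", seq_len(K))),
            class = "confusion_summary")
}

#' Reconstruct a partial confusion summary from per-class counts
#'
#' Published evaluations often print only TP/TN/FP/FN per class.  The
#' marginals x_i = TP_i + FN_i and y_i = TP_i + FP_i are recovered exactly;
#' for K > 2 the off-diagonal cells z_ij are under-determined and left NA,
#' so metrics needing the full table (GC2) are flagged undefined.
#'
#' @param TP,FP,FN named numeric vectors of per-class counts.
#' @param N total number of items.
#' @return a `confusion_summary` with possibly-NA off-diagonal z.
#' @export
confusion_from_perclass <- function(TP, FP, FN, N) {
  K <- length(TP)
  stopifnot(length(FP) == K, length(FN) == K)
  x <- TP + FN
  y <- TP + FP
  TN <- N - TP - FP - FN
  if (sum(x) != N)
    stopf("inconsistent counts: sum(TP + FN) = %d but N = %d", sum(x), N)
  if (sum(y) != N)
    stopf("inconsistent counts: sum(TP + FP) = %d but N = %d", sum(y), N)
  if (any(TN < 0)) stopf("inconsistent counts: negative TN")
  z <- matrix(NA_real_, K, K,
              dimnames = list(names(TP) %||% paste0("class", 1:K),
                              names(TP) %||% paste0("class", 1:K)))
  diag(z) <- TP
  if (K == 2) { z[1, 2] <- FN[1]; z[2, 1] <- FP[1] }
  structure(list(z = z, N = N, K = K, TP = TP, FP = FP, FN = FN, TN = TN,
                 x = x, y = y, classes = rownames(z)),
            class = "confusion_summary")
}

safe_ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)

#' Classification metric report
#'
#' Per-class SPEC = TP/(TP+FP) (precision), SENS = TP/(TP+FN) (recall) and
#' their harmonic-mean F1; plus macro-F1, multi-class accuracy
#' ACC = sum_i z_ii / N, and the generalized squared correlation
#' GC2 = sum_ij (z_ij - e_ij)^2 / e_ij / (N (K - 1)) with
#' e_ij = x_i y_j / N.  A metric with a zero denominator (or, for GC2, an
#' under-determined confusion table) is reported as NA and listed in the
#' report's `undefined` field rather than coerced to 0.
#'
#' @param x a `confusion_summary`, a confusion matrix, or a truth vector
#'   (with `pred` supplied).
#' @param pred predicted labels when `x` is a truth vector.
#' @param levels optional class levels.
#' @return object of class `metric_report`.
#' @export
classification_metrics <- function(x, pred = NULL, levels = NULL) {
  cs <- if (inherits(x, "confusion_summary")) x
        else if (is.matrix(x) || is.table(x)) confusion_summary(x)
        else confusion_summary(confusion_matrix(x, pred, levels))
  spec <- safe_ratio(cs$TP, cs$TP + cs$FP)
  sens <- safe_ratio(cs$TP, cs$TP + cs$FN)
  f1 <- ifelse(!is.na(spec) & !is.na(sens) & (spec + sens) > 0,
               2 * spec * sens / (spec + sens), NA_real_)
  acc <- sum(cs$TP) / cs$N
  macro_f1 <- mean(f1)
  gc2 <- if (anyNA(cs$z)) NA_real_ else {
    e <- outer(cs$x, cs$y) / cs$N
    ok <- e > 0
    sum((cs$z[ok] - e[ok])^2 / e[ok]) / (cs$N * (cs$K - 1))
  }
  per_class <- data.frame(class = cs$classes, TP = as.numeric(cs$TP),
                          TN = as.numeric(cs$TN), FP = as.numeric(cs$FP),
                          FN = as.numeric(cs$FN), SPEC = spec, SENS = sens,
                          F1 = f1, row.names = NULL)
  overall <- c(ACC = acc, macro_F1 = macro_f1, GC2 = gc2)
  undefined <- c(names(overall)[is.na(overall)],
                 if (anyNA(spec)) "SPEC", if (anyNA(sens)) "SENS",
                 if (anyNA(f1)) "F1")
  structure(list(task = "classification", per_class = per_class,
                 overall = overall, confusion = cs,
                 aliases = c(SPEC = "precision", SENS = "recall"),
                 undefined = undefined),
            class = "metric_report")
}

#' Regression metric report
#'
#' Pearson correlation, mean absolute error, mean squared error and
#' R2 = 1 - SS_res / SS_tot (which may be negative for a predictor worse
#' than the mean baseline).
#'
#' @param predictions,truths equal-length numeric vectors (n >= 2).
#' @return object of class `metric_report`.
#' @export
regression_metrics <- function(predictions, truths) {
  if (length(predictions) != length(truths))
    stopf("predictions (%d) and truths (%d) differ in length",
          length(predictions), length(truths))
  if (length(truths) < 2) stopf("need at least 2 observations")
  err <- predictions - truths
  sstot <- sum((truths - mean(truths))^2)
  zero_var <- sstot == 0 || sd(predictions) == 0
  overall <- c(PCC = if (zero_var) NA_real_ else cor(predictions, truths),
               MAE = mean(abs(err)), MSE = mean(err^2),
               R2 = if (sstot == 0) NA_real_ else 1 - sum(err^2) / sstot)
  structure(list(task = "regression", overall = overall,
                 n = length(truths),
                 undefined = names(overall)[is.na(overall)]),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 3, ...) {
  cat(sprintf("<metric_report: %s>\n", x$task))
  if (x$task == "classification") {
    pc <- x$per_class
    pc[, c("SPEC", "SENS", "F1")] <- round(pc[, c("SPEC", "SENS", "F1")],
                                           digits)
    print(pc, row.names = FALSE)
  }
  print(round(x$overall, digits))
  if (length(x$undefined))
    cat("undefined:", paste(unique(x$undefined), collapse = ", "), "\n")
  invisible(x)
}

#' Write a metric report to TSV or JSON
#'
#' @param report a `metric_report`.
#' @param path output file.
#' @param format `"tsv"` or `"json"`.
#' @export
write_metric_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  rows <- data.frame(metric = names(report$overall),
                     class = "all", value = as.numeric(report$overall),
                     undefined = names(report$overall) %in% report$undefined)
  if (report$task == "classification") {
    pc <- report$per_class
    long <- do.call(rbind, lapply(c("SPEC", "SENS", "F1"), function(m)
      data.frame(metric = m, class = pc$class, value = pc[[m]],
                 undefined = is.na(pc[[m]]))))
    rows <- rbind(long, rows)
  }
  if (format == "tsv") write_tsv(rows, path)
  else jsonlite::write_json(rows, path, dataframe = "rows", digits = NA)
  invisible(path)
}
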