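# Variant data model: folding-rate records, labels, datasets and grouped
# train/test partitioning.

variant_labels <- function() c("decrease", "no_effect", "increase")

#' Folding rate change of a variant
#'
#' The natural-log ratio of the variant to wild-type folding rate,
#' \eqn{\Delta \ln k_f = \ln k_f^{var} - \ln k_f^{wt}}.
#'
#' @param kf_var,kf_wt folding rates (s^-1), strictly positive; vectorised.
#' @return numeric vector of log rate changes.
#' @export
compute_delta_lnkf <- function(kf_var, kf_wt) {
  if (any(!is.finite(kf_var) | kf_var <= 0))
    stopf("kf_var must be finite and > 0")
  if (any(!is.finite(kf_wt) | kf_wt <= 0))
    stopf("kf_wt must be finite and > 0")
  log(kf_var) - log(kf_wt)
}

#' Three-class folding-rate-effect label
#'
#' Maps a log rate change to decrease / no_effect / increase using a
#' symmetric band of half-width `threshold` around zero.  The band is
#' closed: |delta| exactly equal to the threshold is `no_effect`.
#'
#' @param delta numeric vector of log rate changes.
#' @param threshold positive band half-width (default 0.15).
#' @return factor with levels decrease, no_effect, increase.
#' @export
classify_delta <- function(delta, threshold = 0.15) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0)
    stopf("threshold must be a single positive number")
  if (any(!is.finite(delta))) stopf("non-finite delta value")
  lab <- ifelse(delta < -threshold, "decrease",
         ifelse(delta > threshold, "increase", "no_effect"))
  factor(lab, levels = variant_labels())
}

#' Construct and validate a variant dataset
#'
#' Bundles variant records with their protein sequences and enforces the
#' dataset invariants: every record's protein has a sequence, positions are
#' inside the sequence, the recorded wild-type residue matches the sequence,
#' and labels are a pure function of the log rate change and the threshold.
#' Records carrying both a rate pair and an explicit delta that disagree by
#' more than 1e-6 are rejected.
#'
#' @param records data.frame with columns protein_id, wt_aa, position,
#'   var_aa and at least one of (kf_wt & kf_var) or delta_lnkf.
#' @param sequences named character vector of protein sequences.
#' @param threshold classification band half-width.
#' @return object of class `variant_dataset`.
#' @export
variant_dataset <- function(records, sequences, threshold = 0.15) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  req <- c("protein_id", "wt_aa", "position", "var_aa")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols))
    stopf("records lack column(s): %s", paste(missing_cols, collapse = ", "))
  records$position <- as.integer(records$position)
  for (col in c("kf_wt", "kf_var", "delta_lnkf"))
    if (is.null(records[[col]])) records[[col]] <- NA_real_

  check_standard_aa(records$wt_aa, "wild-type residue")
  check_standard_aa(records$var_aa, "variant residue")
  if (any(records$wt_aa == records$var_aa))
    stopf("wt and variant residue identical in record(s): %s",
          paste(which(records$wt_aa == records$var_aa), collapse = ", "))
  if (any(records$position < 1)) stopf("positions must be >= 1")

  has_rates <- !is.na(records$kf_wt) & !is.na(records$kf_var)
  has_delta <- !is.na(records$delta_lnkf)
  if (any(!has_rates & !has_delta))
    stopf("record(s) without rates or delta_lnkf: %s",
          paste(which(!has_rates & !has_delta), collapse = ", "))
  if (any(has_rates)) {
    bad <- has_rates & (records$kf_wt <= 0 | records$kf_var <= 0)
    if (any(bad)) stopf("non-positive folding rate in record(s): %s",
                        paste(which(bad), collapse = ", "))
    d <- compute_delta_lnkf(records$kf_var[has_rates], records$kf_wt[has_rates])
    both <- has_delta[has_rates]
    if (any(both)) {
      disagree <- abs(d[both] - records$delta_lnkf[has_rates][both]) > 1e-6
      if (any(disagree))
        stopf("delta_lnkf disagrees with rate pair in record(s): %s",
              paste(which(has_rates)[both][disagree], collapse = ", "))
    }
    records$delta_lnkf[has_rates] <- d
  }

  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stopf("sequences must be a named character vector")
  unknown <- setdiff(unique(records$protein_id), names(sequences))
  if (length(unknown))
    stopf("no sequence for protein id(s): %s", paste(unknown, collapse = ", "))
  seqs <- toupper(sequences[unique(records$protein_id)])
  lens <- nchar(seqs)
  too_far <- records$position > lens[records$protein_id]
  if (any(too_far))
    stopf("position beyond sequence length in record(s): %s",
          paste(which(too_far), collapse = ", "))
  seq_aa <- substr(seqs[records$protein_id], records$position, records$position)
  mism <- seq_aa != records$wt_aa
  if (any(mism))
    stopf("wild-type residue mismatch against sequence in record(s): %s",
          paste(sprintf("%d (%s%d is %s, record says %s)", which(mism),
                        records$protein_id[mism], records$position[mism],
                        seq_aa[mism], records$wt_aa[mism]), collapse = "; "))

  records$label <- classify_delta(records$delta_lnkf, threshold)
  structure(list(records = records, sequences = seqs, threshold = threshold),
            class = "variant_dataset")
}

#' Class counts of a variant dataset
#' @param dataset a `variant_dataset`.
#' @return named integer vector over the three labels.
#' @export
class_counts <- function(dataset) {
  stopifnot(inherits(dataset, "variant_dataset"))
  table(dataset$records$label)
}

#' @export
print.variant_dataset <- function(x, ...) {
  cc <- class_counts(x)
  cat(sprintf("<variant_dataset: %d variants in %d proteins>\n",
              nrow(x$records), length(x$sequences)))
  cat(sprintf("  decrease %d | no_effect %d | increase %d (|delta| band %.2f)\n",
              cc[["decrease"]], cc[["no_effect"]], cc[["increase"]],
              x$threshold))
  invisible(x)
}

# Compact substitution notation "A25F" -> (wt, pos, var).
parse_substitution <- function(s) {
  m <- regmatches(s, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", s))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stopf("malformed substitution string(s): %s",
          paste(s[bad], collapse = ", "))
  data.frame(wt_aa = toupper(vapply(m, `[`, "", 2L)),
             position = as.integer(vapply(m, `[`, "", 3L)),
             var_aa = toupper(vapply(m, `[`, "", 4L)),
             stringsAsFactors = FALSE)
}

#' Read protein sequences from a FASTA file
#' @param path FASTA file.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write protein sequences to a FASTA file
#' @param sequences named character vector.
#' @param path output file.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}

#' Load a variant dataset from TSV + FASTA
#'
#' The variant table is tab-separated with a header and '#' comment lines.
#' Substitutions are given either as wt_aa/position/var_aa columns or as a
#' compact `substitution` column ("A25F").  Rate information comes from
#' kf_wt/kf_var columns, a delta_lnkf column, or both (which must agree).
#'
#' @param variants_path variant TSV.
#' @param fasta_path protein FASTA; ids must match the table's protein_id.
#' @param threshold classification band half-width.
#' @return a `variant_dataset`.
#' @export
load_dataset <- function(variants_path, fasta_path, threshold = 0.15) {
  tab <- read_tsv_commented(variants_path)
  if (!"protein_id" %in% names(tab)) stopf("variant table lacks protein_id")
  if (!all(c("wt_aa", "position", "var_aa") %in% names(tab))) {
    if (!"substitution" %in% names(tab))
      stopf("variant table needs wt_aa/position/var_aa or substitution")
    tab <- cbind(tab, parse_substitution(tab$substitution))
  }
  variant_dataset(tab, read_fasta(fasta_path), threshold = threshold)
}

#' Write a variant dataset back to TSV (and optionally FASTA)
#'
#' The writer includes the derived delta_lnkf and label columns; reloading
#' the written files reproduces the dataset exactly.
#'
#' @param dataset a `variant_dataset`.
#' @param variants_path output TSV.
#' @param fasta_path optional output FASTA.
#' @export
write_dataset <- function(dataset, variants_path, fasta_path = NULL) {
  stopifnot(inherits(dataset, "variant_dataset"))
  rec <- dataset$records
  rec$label <- as.character(rec$label)
  write_tsv(rec, variants_path)
  if (!is.null(fasta_path)) write_fasta(dataset$sequences, fasta_path)
  invisible(variants_path)
}

group_keys <- function(dataset) {
  paste(dataset$records$protein_id, dataset$records$position, sep = ":")
}

#' Group-aware train/test split
#'
#' All variants sharing a (protein, position) group are kept on the same
#' side, mirroring leakage-safe benchmark construction.  Groups are shuffled
#' under the seed and assigned greedily to the test side until the target
#' fraction of records is reached.
#'
#' @param dataset a `variant_dataset`.
#' @param test_fraction target fraction of records in the test side.
#' @param seed integer seed; the split is deterministic given the seed.
#' @return list of class `split_spec` with train_indices, test_indices and
#'   grouping_key.
#' @export
grouped_split <- function(dataset, test_fraction, seed) {
  stopifnot(inherits(dataset, "variant_dataset"))
  if (!(test_fraction > 0 && test_fraction < 1))
    stopf("test_fraction must be in (0, 1)")
  keys <- group_keys(dataset)
  n <- length(keys)
  target <- test_fraction * n
  sizes <- table(keys)
  if (any(sizes > max(target, n - target)))
    warnf("group(s) larger than a split side; assigned whole: %s",
          paste(names(sizes)[sizes > max(target, n - target)], collapse = ", "))
  groups <- local_seed(seed, sample(names(sizes)))
  test_groups <- character(0)
  n_test <- 0
  for (g in groups) {
    if (n_test >= target) break
    test_groups <- c(test_groups, g)
    n_test <- n_test + sizes[[g]]
  }
  test_idx <- which(keys %in% test_groups)
  structure(list(train_indices = setdiff(seq_len(n), test_idx),
                 test_indices = test_idx,
                 grouping_key = "protein_id:position", seed = seed),
            class = "split_spec")
}

#' One-line dataset summary with per-class counts
#'
#' Prints the number of variants per effect class, the style used to
#' describe benchmark composition tables.
#'
#' @param dataset a `variant_dataset`.
#' @return invisibly, the class count vector.
#' @export
dataset_summary <- function(dataset) {
  cc <- class_counts(dataset)
  cat(sprintf("%-12s %10s %10s %10s %8s\n", "", "decrease", "no_effect",
              "increase", "total"))
  cat(sprintf("%-12s %10d %10d %10d %8d\n", "variants", cc[["decrease"]],
              cc[["no_effect"]], cc[["increase"]], sum(cc)))
  invisible(cc)
}
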