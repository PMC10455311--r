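# Variant feature extraction: six feature families totalling 1161 values.
#
# Layout (fixed order): amino_acid 688 | conservation 3 | variation_type 436
# | neighborhood 25 | protein_type 1 | structural 8.

#' Feature extraction configuration
#'
#' @param window_halfwidth residues on each side of the variant site in the
#'   neighborhood window (default 12, i.e. a 25-position window).
#' @param groups6 named residue -> group map for the 6x6 substitution
#'   features (default [aa_groups6()]).
#' @param class_sets residue class lists for the 5 window group features.
#' @return list of class `feature_config`.
#' @export
feature_config <- function(window_halfwidth = 12L, groups6 = aa_groups6(),
                           class_sets = aa_class_sets()) {
  stopifnot(window_halfwidth >= 1)
  missing <- setdiff(amino_acids(), names(groups6))
  if (length(missing))
    stopf("groups6 does not cover residues: %s", paste(missing, collapse = ", "))
  structure(list(window_halfwidth = as.integer(window_halfwidth),
                 groups6 = groups6, class_sets = class_sets),
            class = "feature_config")
}

variation_type_names <- function(groups6 = aa_groups6()) {
  aa <- amino_acids()
  cells <- as.vector(t(outer(aa, aa, paste, sep = "_"))) # wt-major order
  gids <- sort(unique(groups6))
  gcells <- as.vector(t(outer(gids, gids, paste, sep = "_")))
  c(cells, gcells)
}

#' Substitution-type one-hot features
#'
#' 400 indicators for the (wild-type, variant) cell of the 20x20 residue
#' substitution matrix plus 36 indicators for the corresponding cell of a
#' 6x6 physicochemical-group matrix; exactly two entries are 1.
#'
#' @param wt_aa,var_aa one-letter residue codes (vectorised).
#' @param groups6 residue -> group map.
#' @return named vector of length 436 (or matrix with one row per pair).
#' @export
variation_type_features <- function(wt_aa, var_aa, groups6 = aa_groups6()) {
  check_standard_aa(c(wt_aa, var_aa))
  n <- length(wt_aa)
  stopifnot(length(var_aa) == n)
  aa <- amino_acids()
  gids <- sort(unique(groups6))
  if (anyNA(groups6[wt_aa]) || anyNA(groups6[var_aa]))
    stopf("residue not covered by the 6-way group partition")
  out <- matrix(0, n, 436, dimnames = list(NULL, variation_type_names(groups6)))
  wt_i <- match(wt_aa, aa); var_i <- match(var_aa, aa)
  out[cbind(seq_len(n), (wt_i - 1L) * 20L + var_i)] <- 1
  gw <- match(groups6[wt_aa], gids); gv <- match(groups6[var_aa], gids)
  out[cbind(seq_len(n), 400L + (gw - 1L) * length(gids) + gv)] <- 1
  if (n == 1) out[1, ] else out
}

neighborhood_names <- function(class_sets = aa_class_sets()) {
  c(paste0("window_", amino_acids()), paste0("window_", names(class_sets)))
}

#' Sequence-neighborhood composition features
#'
#' Proportions of each residue type, and of five physicochemical classes,
#' in a window centred on the variant position (truncated at the sequence
#' ends; proportions are normalised by the number of residues actually in
#' the window).
#'
#' @param sequence protein sequence (single string).
#' @param position 1-based variant position.
#' @param window_halfwidth residues per side (default 12 => 25 positions).
#' @param class_sets residue class lists for the 5 group features.
#' @return named numeric vector of length 25.
#' @export
neighborhood_features <- function(sequence, position, window_halfwidth = 12L,
                                  class_sets = aa_class_sets()) {
  len <- nchar(sequence)
  if (position < 1 || position > len)
    stopf("position %d outside sequence of length %d", position, len)
  lo <- max(1L, position - window_halfwidth)
  hi <- min(len, position + window_halfwidth)
  win <- strsplit(substr(sequence, lo, hi), "")[[1]]
  w <- length(win)
  props <- vapply(amino_acids(), function(a) sum(win == a), 0) / w
  groups <- vapply(class_sets, function(s) sum(win %in% s), 0) / w
  setNames(c(props, groups), neighborhood_names(class_sets))
}

#' Relative sequence position of a variant
#'
#' @param position 1-based position.
#' @param sequence_length protein length.
#' @return position / length, in (0, 1].
#' @export
relative_position <- function(position, sequence_length) {
  if (any(position < 1 | position > sequence_length))
    stopf("position outside [1, %d]", sequence_length)
  position / sequence_length
}

structural_feature_names <- function() c(paste0("ss_", ss7_states()), "rsa")

#' Structural features at a variant position
#'
#' A 7-state secondary-structure one-hot vector plus the relative solvent
#' accessibility RSA = ASA / maxASA of the wild-type residue.  An
#' unannotated position is a hard error: no silent imputation.
#'
#' @param annotation data.frame with columns position, ss, asa.
#' @param position variant position.
#' @param wt_aa wild-type residue (for the maxASA normalisation).
#' @return named numeric vector of length 8.
#' @export
structural_features <- function(annotation, position, wt_aa) {
  row <- annotation[annotation$position == position, , drop = FALSE]
  if (nrow(row) != 1 || is.na(row$ss) || is.na(row$asa))
    stopf("no structural annotation for position %d", position)
  if (!row$ss %in% ss7_states())
    stopf("unknown secondary-structure state '%s'", row$ss)
  ma <- max_asa_table()
  if (!wt_aa %in% names(ma)) stopf("no maxASA value for residue %s", wt_aa)
  ss <- as.numeric(ss7_states() == row$ss)
  setNames(c(ss, row$asa / ma[[wt_aa]]), structural_feature_names())
}

conservation_feature_names <- function() c("C-score", "coev_max", "coev_np")

#' Conservation features at a variant position
#'
#' Three per-position values consumed from an annotation table: an
#' evolutionary conservation score and two coevolution summaries (maximum
#' coupling strength and number of strongly coupled partners).
#'
#' @param annotation data.frame with columns position, c_score, coev_max,
#'   coev_np.
#' @param position variant position.
#' @return named numeric vector of length 3.
#' @export
conservation_features <- function(annotation, position) {
  row <- annotation[annotation$position == position, , drop = FALSE]
  if (nrow(row) != 1)
    stopf("no conservation annotation for position %d", position)
  setNames(as.numeric(row[1, c("c_score", "coev_max", "coev_np")]),
           conservation_feature_names())
}

#' Conservation score from a multiple sequence alignment (fallback)
#'
#' When no external conservation annotation is available, a simple stand-in
#' score can be computed per column as 1 minus the normalised Shannon
#' entropy of residue frequencies (1 = fully conserved).
#'
#' @param alignment character vector of aligned sequences (equal lengths;
#'   '-' for gaps).
#' @return numeric vector, one score per alignment column.
#' @export
entropy_conservation <- function(alignment) {
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  apply(mat, 2, function(col) {
    col <- col[col %in% amino_acids()]
    if (!length(col)) return(NA_real_)
    p <- table(col) / length(col)
    1 - (-sum(p * log(p))) / log(20)
  })
}

#' Names and family layout of the full feature vector
#'
#' @param aaindex an `aaindex_table`.
#' @param config a [feature_config()].
#' @return named list of character vectors, one per family, in vector order.
#' @export
feature_families <- function(aaindex = default_aaindex(),
                             config = feature_config()) {
  list(amino_acid = aaindex_feature_names(aaindex),
       conservation = conservation_feature_names(),
       variation_type = variation_type_names(config$groups6),
       neighborhood = neighborhood_names(config$class_sets),
       protein_type = "rp",
       structural = structural_feature_names())
}

with_family <- function(family, expr) {
  tryCatch(expr, error = function(e)
    stopf("[%s features] %s", family, conditionMessage(e)))
}

#' Compute the full feature matrix for a variant dataset
#'
#' Emits one row of 1161 features per variant, in a stable family order.
#' The computation is a pure function of the dataset, annotations, index
#' table and configuration: repeated calls are bit-identical.
#'
#' @param dataset a `variant_dataset`.
#' @param annotations list with elements `structural` and `conservation`,
#'   each a named (by protein id) list of per-residue annotation
#'   data.frames (see [structural_features()], [conservation_features()]).
#' @param aaindex an `aaindex_table`.
#' @param config a [feature_config()].
#' @return numeric matrix, one named column per feature.
#' @export
featurize_dataset <- function(dataset, annotations,
                              aaindex = default_aaindex(),
                              config = feature_config()) {
  stopifnot(inherits(dataset, "variant_dataset"))
  rec <- dataset$records
  n <- nrow(rec)
  missing_prot <- setdiff(unique(rec$protein_id),
                          intersect(names(annotations$structural),
                                    names(annotations$conservation)))
  if (length(missing_prot))
    stopf("annotations missing for protein(s): %s",
          paste(missing_prot, collapse = ", "))

  A <- with_family("amino_acid",
                   aaindex_features(rec$wt_aa, rec$var_aa, aaindex))
  if (n == 1) A <- matrix(A, 1, dimnames = list(NULL, names(A)))

  C <- with_family("conservation", t(vapply(seq_len(n), function(i)
    conservation_features(annotations$conservation[[rec$protein_id[i]]],
                          rec$position[i]), numeric(3))))

  V <- with_family("variation_type",
                   variation_type_features(rec$wt_aa, rec$var_aa,
                                           config$groups6))
  if (n == 1) V <- matrix(V, 1, dimnames = list(NULL, names(V)))

  N <- with_family("neighborhood", t(vapply(seq_len(n), function(i)
    neighborhood_features(dataset$sequences[[rec$protein_id[i]]],
                          rec$position[i], config$window_halfwidth,
                          config$class_sets), numeric(25))))

  rp <- with_family("protein_type", matrix(
    relative_position(rec$position, nchar(dataset$sequences)[rec$protein_id]),
    ncol = 1, dimnames = list(NULL, "rp")))

  S <- with_family("structural", t(vapply(seq_len(n), function(i)
    structural_features(annotations$structural[[rec$protein_id[i]]],
                        rec$position[i], rec$wt_aa[i]), numeric(8))))

  out <- cbind(A, C, V, N, rp, S)
  fam <- feature_families(aaindex, config)
  stopifnot(identical(colnames(out), unlist(fam, use.names = FALSE)))
  out
}

#' Featurize a single variant
#'
#' Convenience wrapper around [featurize_dataset()] for one record.
#'
#' @param dataset a `variant_dataset`.
#' @param index row number of the record to featurize.
#' @param annotations,aaindex,config as in [featurize_dataset()].
#' @return named numeric vector of length 1161.
#' @export
featurize <- function(dataset, index, annotations,
                      aaindex = default_aaindex(),
                      config = feature_config()) {
  sub <- dataset
  sub$records <- dataset$records[index, , drop = FALSE]
  featurize_dataset(sub, annotations, aaindex, config)[1, ]
}

#' Project a feature vector or matrix onto a named subset
#'
#' @param x named numeric vector or matrix with named columns.
#' @param names feature identifiers to keep, in the requested order.
#' @return the reduced vector/matrix.
#' @export
select_named_subset <- function(x, names) {
  have <- if (is.matrix(x)) colnames(x) else base::names(x)
  unknown <- setdiff(names, have)
  if (length(unknown))
    stopf("unknown feature name(s): %s", paste(unknown, collapse = ", "))
  if (is.matrix(x)) x[, names, drop = FALSE] else x[names]
}

#' Published selected-feature subsets
#'
#' The bundled selected-feature lists: 31 names for the three-class
#' classifier, 21 for the regression predictor.
#'
#' @param task `"classification"` or `"regression"`.
#' @return character vector of feature names (rank order).
#' @export
selected_features <- function(task = c("classification", "regression")) {
  task <- match.arg(task)
  f <- if (task == "classification") "selected_features_classification.tsv"
       else "selected_features_regression.tsv"
  read_tsv_commented(extdata_path(f))$feature
}
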