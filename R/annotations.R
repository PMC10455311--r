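# Readers/writers for the per-residue annotation tables consumed by the
# feature extractor (produced externally by structure/conservation tools,
# or by the synthetic generator).

#' Read a per-residue structural annotation table
#'
#' TSV with columns protein_id, position, ss (7-state code) and asa
#' (Angstrom^2); '#' lines are comments.
#'
#' @param path annotation TSV.
#' @return named list (by protein id) of data.frames (position, ss, asa).
#' @export
read_structural_annotation <- function(path) {
  df <- read_tsv_commented(path)
  need <- c("protein_id", "position", "ss", "asa")
  if (!all(need %in% names(df)))
    stopf("structural annotation needs columns: %s", paste(need, collapse = ", "))
  split(df[, c("position", "ss", "asa")], df$protein_id)
}

#' Read a per-position conservation annotation table
#'
#' TSV with columns protein_id, position, c_score, coev_max, coev_np.
#'
#' @param path annotation TSV.
#' @return named list (by protein id) of data.frames.
#' @export
read_conservation_annotation <- function(path) {
  df <- read_tsv_commented(path)
  need <- c("protein_id", "position", "c_score", "coev_max", "coev_np")
  if (!all(need %in% names(df)))
    stopf("conservation annotation needs columns: %s",
          paste(need, collapse = ", "))
  split(df[, c("position", "c_score", "coev_max", "coev_np")], df$protein_id)
}

annotation_to_long <- function(ann) {
  do.call(rbind, lapply(names(ann), function(p)
    cbind(protein_id = p, ann[[p]], stringsAsFactors = FALSE)))
}

#' Write structural / conservation annotations to TSV
#' @param ann named list of per-protein annotation data.frames.
#' @param path output file.
#' @export
write_annotation <- function(ann, path) {
  write_tsv(annotation_to_long(ann), path)
}

#' Read both annotation tables into the list the featurizer expects
#' @param structural_path,conservation_path annotation TSVs.
#' @return list with elements `structural` and `conservation`.
#' @export
read_annotations <- function(structural_path, conservation_path) {
  list(structural = read_structural_annotation(structural_path),
       conservation = read_conservation_annotation(conservation_path))
}

#' Write the full feature matrix with a named header
#' @param x feature matrix.
#' @param path output TSV.
#' @export
write_feature_matrix <- function(x, path) {
  write_tsv(as.data.frame(x, check.names = FALSE), path)
}
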