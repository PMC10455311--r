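# Amino acid alphabets, physicochemical groupings and normalisation tables.

#' The 20 standard amino acids (one-letter codes, alphabetical)
#' @return character vector of length 20.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Seven-state secondary structure alphabet (alpha helix, 3-10 helix, pi
# helix, strand, bridge, turn, coil) as assigned by standard tools.
ss7_states <- function() c("H", "G", "I", "E", "B", "T", "C")

# Residue classes used for the five window-composition group features.
aa_class_sets <- function() {
  list(
    NonPolarAA = c("G", "A", "V", "L", "I", "P", "F", "M", "W"),
    PolarAA    = c("S", "T", "C", "Y", "N", "Q"),
    ChargedAA  = c("D", "E", "K", "R", "H"),
    PosAA      = c("K", "R", "H"),
    NegAA      = c("D", "E")
  )
}

pkg_cache <- new.env(parent = emptyenv())

#' Maximum accessible surface area per residue type
#'
#' Residue-specific normalisation maxima for computing relative solvent
#' accessibility, RSA = ASA / maxASA.
#'
#' @return named numeric vector (\eqn{\AA^2}) over the 20 standard residues.
#' @export
max_asa_table <- function() {
  if (is.null(pkg_cache$max_asa)) {
    df <- read_tsv_commented(extdata_path("max_asa.tsv"))
    pkg_cache$max_asa <- setNames(df$max_asa, df$aa)
  }
  pkg_cache$max_asa
}

#' Six-way physicochemical amino acid partition
#'
#' The grouping behind the 6x6 substitution-type matrix.  Loaded from a
#' configuration file rather than hard-coded; a custom partition may be
#' supplied anywhere a `groups6` argument is accepted.
#'
#' @param path optional path to a two-column TSV (aa, group) overriding the
#'   bundled partition.
#' @return named character vector mapping residue -> group id (g1..g6).
#' @export
aa_groups6 <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(pkg_cache$groups6)) {
      df <- read_tsv_commented(extdata_path("aa_groups6.tsv"))
      pkg_cache$groups6 <- setNames(df$group, df$aa)
    }
    return(pkg_cache$groups6)
  }
  df <- read_tsv_commented(path)
  g <- setNames(df$group, df$aa)
  missing <- setdiff(amino_acids(), names(g))
  if (length(missing))
    stopf("group partition does not cover residues: %s",
          paste(missing, collapse = ", "))
  g
}

check_standard_aa <- function(aa, what = "residue") {
  bad <- setdiff(unique(aa), amino_acids())
  if (length(bad))
    stopf("non-standard %s code(s): %s", what, paste(bad, collapse = ", "))
  invisible(aa)
}
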