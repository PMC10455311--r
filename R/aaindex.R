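# Physicochemical amino acid index tables: flat-file ingestion, a
# deterministic synthetic stand-in, and the 688 index-derived features.

# Row order of values in single-index flat files (two lines of ten).
AAINDEX_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Index identifiers named in the published selected-feature lists, split by
# whether they are per-residue scales or residue-pair potentials.
published_single_ids <- function() {
  c("AURR980118", "AURR980102", "QIAN880128", "NADH010101",
    "GARJ730101", "BULH740101", "SNEP660101", "LAWE840101")
}
published_pair_ids <- function() {
  c("TOBD000102", "SIMK990102", "SIMK990105", "THOP960101", "VENM980101",
    "BONM030101", "BONM030105", "BONM030106", "MOOG990101", "MIYS850103",
    "SKOJ970101", "BETM990101", "LIWA970101", "KESO980102", "BASU010101",
    "ZHAC000102", "ZHAC000105", "OVEJ920103")
}

new_aaindex_table <- function(single, pair, synthetic = FALSE) {
  structure(list(single = single, pair = pair, synthetic = synthetic),
            class = "aaindex_table")
}

#' @export
print.aaindex_table <- function(x, ...) {
  cat(sprintf("<aaindex_table: %d single indices, %d pair indices%s>\n",
              length(x$single), length(x$pair),
              if (isTRUE(x$synthetic)) ", synthetic" else ""))
  invisible(x)
}

parse_aaindex_numbers <- function(lines) {
  toks <- unlist(strsplit(paste(lines, collapse = " "), "[[:space:]]+"))
  toks <- toks[nzchar(toks)]
  suppressWarnings(ifelse(toks %in% c("NA", "-", "."), NA_real_,
                          as.numeric(toks)))
}

#' Read amino acid index flat files
#'
#' Parses the standard H/I/M block format: `H` introduces the accession,
#' `I` a 20-value per-residue scale (two lines of ten, A R N D C Q E G H I /
#' L K M F P S T W Y V), and `M` a residue-pair matrix (lower-triangular or
#' full 20x20 over the alphabet given in the `rows =` declaration).
#' Triangular matrices are symmetrised.  Indices containing missing values
#' are dropped (with a message), matching the convention of excluding
#' incomplete scales.
#'
#' @param path flat file containing one or more index entries.
#' @param drop_incomplete drop indices with any missing value (default TRUE).
#' @return an `aaindex_table` with `single` (named list of named numeric
#'   20-vectors) and `pair` (named list of 20x20 matrices over [amino_acids()]).
#' @export
read_aaindex <- function(path, drop_incomplete = TRUE) {
  lines <- readLines(path)
  rec_end <- grep("^//", lines)
  rec_start <- c(1L, head(rec_end, -1L) + 1L)
  single <- list()
  pair <- list()
  dropped <- 0L
  for (r in seq_along(rec_end)) {
    block <- lines[rec_start[r]:rec_end[r]]
    hline <- grep("^H ", block, value = TRUE)
    if (!length(hline)) next
    id <- trimws(sub("^H ", "", hline[1]))
    iline <- grep("^I ", block)
    mline <- grep("^M ", block)
    # data lines: the indented continuation lines after I/M
    if (length(iline)) {
      dat <- block[(iline[1] + 1):(length(block) - 1)]
      dat <- dat[grepl("^[[:space:]]", dat)]
      vals <- parse_aaindex_numbers(dat)
      if (length(vals) != 20)
        stopf("index %s: expected 20 values, got %d", id, length(vals))
      v <- setNames(vals, AAINDEX_ORDER)[amino_acids()]
      if (anyNA(v) && drop_incomplete) { dropped <- dropped + 1L; next }
      single[[id]] <- v
    } else if (length(mline)) {
      decl <- block[mline[1]]
      rows <- sub(".*rows *= *([A-Z]+).*", "\\1", decl)
      alphabet <- strsplit(rows, "")[[1]]
      if (length(alphabet) != 20)
        stopf("index %s: unsupported matrix alphabet '%s'", id, rows)
      dat <- block[(mline[1] + 1):(length(block) - 1)]
      dat <- dat[grepl("^[[:space:]]", dat)]
      vals <- parse_aaindex_numbers(dat)
      m <- matrix(NA_real_, 20, 20, dimnames = list(alphabet, alphabet))
      if (length(vals) == 210) {          # lower triangle incl. diagonal
        k <- 1L
        for (i in 1:20) for (j in 1:i) {
          m[i, j] <- vals[k]; m[j, i] <- vals[k]; k <- k + 1L
        }
      } else if (length(vals) == 400) {
        m[] <- matrix(vals, 20, 20, byrow = TRUE)
      } else {
        stopf("index %s: expected 210 or 400 values, got %d", id, length(vals))
      }
      m <- m[amino_acids(), amino_acids()]
      if (anyNA(m) && drop_incomplete) { dropped <- dropped + 1L; next }
      pair[[id]] <- m
    }
  }
  if (dropped) message(sprintf("dropped %d incomplete index(es)", dropped))
  new_aaindex_table(single, pair)
}

#' Deterministic synthetic amino acid index table
#'
#' A stand-in for the real index database, for offline use and testing: 553
#' per-residue scales and 135 symmetric residue-pair matrices drawn from a
#' seeded standard normal.  The identifiers include every index named in the
#' published selected-feature lists so those subsets resolve by name; the
#' values are synthetic, NOT the published scales, and the table is flagged
#' accordingly.
#'
#' @param n_single,n_pair numbers of single and pair indices.
#' @param seed RNG seed (fixed default so every session sees one table).
#' @return an `aaindex_table` with `synthetic = TRUE`.
#' @export
synthetic_aaindex <- function(n_single = 553L, n_pair = 135L, seed = 101L) {
  sids <- published_single_ids()
  pids <- published_pair_ids()
  stopifnot(n_single >= length(sids), n_pair >= length(pids))
  sids <- c(sids, sprintf("SYNA%04d", seq_len(n_single - length(sids))))
  pids <- c(pids, sprintf("SYNP%04d", seq_len(n_pair - length(pids))))
  local_seed(seed, {
    single <- lapply(sids, function(id)
      setNames(round(rnorm(20), 6), amino_acids()))
    pair <- lapply(pids, function(id) {
      m <- matrix(rnorm(400), 20, 20,
                  dimnames = list(amino_acids(), amino_acids()))
      round((m + t(m)) / 2, 6)
    })
  })
  new_aaindex_table(setNames(single, sids), setNames(pair, pids),
                    synthetic = TRUE)
}

default_aaindex <- function() {
  if (is.null(pkg_cache$aaindex)) pkg_cache$aaindex <- synthetic_aaindex()
  pkg_cache$aaindex
}

aaindex_feature_names <- function(table) c(names(table$single), names(table$pair))

#' Amino-acid index features of a substitution
#'
#' One value per index: for per-residue scales the difference
#' value(variant) - value(wild type); for pair matrices the (wt, var) entry.
#'
#' @param wt_aa,var_aa one-letter residue codes (vectorised, equal length).
#' @param table an `aaindex_table` (default: the bundled synthetic table).
#' @return if one substitution, a named numeric vector; otherwise a matrix
#'   with one row per substitution.
#' @export
aaindex_features <- function(wt_aa, var_aa, table = default_aaindex()) {
  check_standard_aa(c(wt_aa, var_aa))
  stopifnot(length(wt_aa) == length(var_aa))
  n <- length(wt_aa)
  S <- do.call(rbind, table$single)            # n_single x 20
  wt_i <- match(wt_aa, amino_acids())
  var_i <- match(var_aa, amino_acids())
  singles <- t(S[, var_i, drop = FALSE] - S[, wt_i, drop = FALSE])
  pairs <- vapply(table$pair,
                  function(m) m[cbind(wt_i, var_i)], numeric(n))
  if (n == 1) pairs <- matrix(pairs, nrow = 1)
  out <- cbind(singles, pairs)
  dimnames(out) <- list(NULL, aaindex_feature_names(table))
  if (n == 1) out[1, ] else out
}
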