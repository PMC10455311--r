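# Shared fixtures, built in code and cached per test run.

fixture_cache <- new.env(parent = emptyenv())

# A mid-sized synthetic benchmark reused across test files.
get_bench <- function(n = 400L, seed = 11L, noise_sd = 0.1) {
  key <- sprintf("bench_%d_%d_%s", n, seed, noise_sd)
  if (is.null(fixture_cache[[key]]))
    fixture_cache[[key]] <- generate_dataset(
      synthetic_spec(n_variants = n, n_proteins = 12L, seed = seed,
                     noise_sd = noise_sd))
  fixture_cache[[key]]
}

# A reduced feature matrix: planted-signal features plus noise columns, the
# standard shape for model and selection tests.
get_small_matrix <- function(n = 400L, n_noise = 46L, seed = 11L) {
  key <- sprintf("smallmat_%d_%d_%d", n, n_noise, seed)
  if (is.null(fixture_cache[[key]])) {
    b <- get_bench(n = n, seed = seed)
    informative <- names(b$weights)
    noise_cols <- setdiff(colnames(b$features), informative)
    noise_cols <- noise_cols[seq_len(n_noise)]
    fixture_cache[[key]] <- list(
      x = b$features[, c(informative, noise_cols)],
      y = b$dataset$records$delta_lnkf,
      labels = b$dataset$records$label,
      groups = paste(b$dataset$records$protein_id,
                     b$dataset$records$position, sep = ":"),
      informative = informative, bench = b)
  }
  fixture_cache[[key]]
}

# Per-item tally oracle for classification metrics, independent of the
# package's confusion-matrix path.
oracle_metrics <- function(truth, pred, classes) {
  per <- lapply(classes, function(k) {
    tp <- sum(truth == k & pred == k)
    fp <- sum(truth != k & pred == k)
    fn <- sum(truth == k & pred != k)
    spec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(spec) && !is.na(sens) && spec + sens > 0)
      2 * spec * sens / (spec + sens) else NA_real_
    c(spec, sens, f1)
  })
  m <- do.call(rbind, per)
  list(SPEC = m[, 1], SENS = m[, 2], F1 = m[, 3],
       ACC = mean(truth == pred), macro_F1 = mean(m[, 3]))
}

# Tiny hand-built dataset: 2 proteins, a handful of variants.
toy_records <- function() {
  data.frame(
    protein_id = c("P1", "P1", "P1", "P2", "P2"),
    wt_aa = c("M", "A", "A", "M", "K"),
    position = c(1L, 3L, 3L, 1L, 4L),
    var_aa = c("V", "G", "W", "L", "R"),
    kf_wt = c(10, 10, 10, 2, 2),
    kf_var = c(10 * exp(-0.5), 10 * exp(0.05), 10 * exp(0.3),
               2 * exp(-1), 2 * exp(0.151)),
    stringsAsFactors = FALSE)
}

toy_sequences <- function() {
  c(P1 = "MAAGWKLYDE", P2 = "MKCKTTVVSP")
}

toy_dataset <- function() variant_dataset(toy_records(), toy_sequences())

toy_annotations <- function() {
  seqs <- toy_sequences()
  structural <- lapply(seqs, function(s) {
    aa <- strsplit(s, "")[[1]]
    data.frame(position = seq_along(aa),
               ss = rep(c("H", "E", "C", "T", "G"), length.out = length(aa)),
               asa = seq(10, 100, length.out = length(aa)),
               stringsAsFactors = FALSE)
  })
  conservation <- lapply(seqs, function(s) {
    n <- nchar(s)
    data.frame(position = seq_len(n),
               c_score = seq(0, 1, length.out = n),
               coev_max = rep(0.5, n), coev_np = rep(2L, n))
  })
  list(structural = structural, conservation = conservation)
}
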