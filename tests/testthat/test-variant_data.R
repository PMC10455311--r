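test_that("compute_delta_lnkf follows the log-ratio definition", {
  expect_equal(compute_delta_lnkf(5, 5), 0)
  for (c0 in c(0.01, 1, 250))
    expect_equal(compute_delta_lnkf(exp(1) * c0, c0), 1)
  # antisymmetry over random positive pairs
  set.seed(1)
  a <- runif(50, 1e-3, 1e3); b <- runif(50, 1e-3, 1e3)
  expect_equal(compute_delta_lnkf(a, b), -compute_delta_lnkf(b, a))
  expect_error(compute_delta_lnkf(-1, 2), "kf_var")
  expect_error(compute_delta_lnkf(1, 0), "kf_wt")
})

test_that("classify_delta applies a closed +/-0.15 band", {
  expect_equal(as.character(classify_delta(c(-0.5, 0, 0.151))),
               c("decrease", "no_effect", "increase"))
  # boundary values fall inside the band
  expect_equal(as.character(classify_delta(c(-0.15, 0.15))),
               c("no_effect", "no_effect"))
  # monotone with exactly two change points
  d <- seq(-1, 1, by = 0.001)
  lab <- as.integer(classify_delta(d))
  expect_true(all(diff(lab) >= 0))
  expect_equal(sum(diff(lab) > 0), 2L)
  expect_error(classify_delta(NaN), "non-finite")
  expect_error(classify_delta(0, threshold = 0), "positive")
})

test_that("variant_dataset validates its invariants", {
  ds <- toy_dataset()
  expect_s3_class(ds, "variant_dataset")
  expect_equal(sum(class_counts(ds)), nrow(ds$records))
  expect_equal(as.character(ds$records$label),
               c("decrease", "no_effect", "increase", "decrease", "increase"))

  bad <- toy_records(); bad$wt_aa[2] <- "C"  # sequence holds A at P1:3
  expect_error(variant_dataset(bad, toy_sequences()), "mismatch")
  bad <- toy_records(); bad$protein_id[1] <- "P9"
  expect_error(variant_dataset(bad, toy_sequences()), "P9")
  bad <- toy_records(); bad$var_aa[1] <- "M"
  expect_error(variant_dataset(bad, toy_sequences()), "identical")
  bad <- toy_records(); bad$position[1] <- 99L
  expect_error(variant_dataset(bad, toy_sequences()), "beyond sequence length")
  bad <- toy_records(); bad$delta_lnkf <- bad$position * 0 + 1  # contradicts rates
  expect_error(variant_dataset(bad, toy_sequences()), "disagrees")
})

test_that("TSV/FASTA round trip reproduces records and labels exactly", {
  ds <- toy_dataset()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_dataset(ds, tsv, fa)
  ds2 <- load_dataset(tsv, fa)
  expect_equal(ds2$records$delta_lnkf, ds$records$delta_lnkf)
  expect_equal(ds2$records$label, ds$records$label)
  expect_equal(ds2$sequences, ds$sequences)
})

test_that("load_dataset accepts compact substitution notation", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("# toy file", "protein_id\tsubstitution\tdelta_lnkf",
               "P1\tM1V\t-0.4", "P1\tA3G\t0.0", "P2\tK4R\t0.2"), tsv)
  write_fasta(toy_sequences(), fa)
  ds <- load_dataset(tsv, fa)
  expect_equal(nrow(ds$records), 3L)
  expect_equal(sum(class_counts(ds)), 3L)
  expect_equal(ds$records$wt_aa, c("M", "A", "K"))
})

test_that("grouped_split keeps (protein, position) groups together", {
  ds <- get_bench(200L)$dataset
  sp <- grouped_split(ds, 0.25, seed = 5)
  keys <- paste(ds$records$protein_id, ds$records$position)
  expect_length(intersect(keys[sp$train_indices], keys[sp$test_indices]), 0)
  expect_setequal(c(sp$train_indices, sp$test_indices),
                  seq_len(nrow(ds$records)))
  # determinism
  sp2 <- grouped_split(ds, 0.25, seed = 5)
  expect_identical(sp$test_indices, sp2$test_indices)
  expect_false(identical(sp$test_indices,
                         grouped_split(ds, 0.25, seed = 6)$test_indices))
})

test_that("grouped_split hits the target fraction on singleton groups", {
  rec <- data.frame(protein_id = "P1", wt_aa = "A",
                    position = seq(2, 101), var_aa = "G",
                    delta_lnkf = 0)
  seqs <- c(P1 = paste(rep("A", 200), collapse = ""))
  ds <- variant_dataset(rec, seqs)
  sp <- grouped_split(ds, 0.2, seed = 1)
  expect_equal(length(sp$test_indices), 20L)  # granularity 1 => exact
})
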