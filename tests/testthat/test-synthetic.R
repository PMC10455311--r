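test_that("generated class counts track the stated proportions", {
  b <- get_bench(n = 952L, seed = 42L)
  cc <- class_counts(b$dataset)
  p <- b$spec$class_proportions
  n <- 952
  for (k in names(p)) {
    expected <- n * p[[k]]
    bound <- 3 * sqrt(n * p[[k]] * (1 - p[[k]]))
    expect_lt(abs(cc[[k]] - expected), bound)
  }
  # labels regenerate exactly from the stored deltas and from the rates
  rec <- b$dataset$records
  expect_identical(rec$label, classify_delta(rec$delta_lnkf))
  expect_identical(rec$label,
                   classify_delta(compute_delta_lnkf(rec$kf_var, rec$kf_wt)))
})

test_that("generation is deterministic per seed, down to written bytes", {
  b1 <- generate_dataset(synthetic_spec(n_variants = 120, n_proteins = 6,
                                        seed = 77))
  b2 <- generate_dataset(synthetic_spec(n_variants = 120, n_proteins = 6,
                                        seed = 77))
  expect_identical(b1$dataset$records, b2$dataset$records)
  expect_identical(b1$features, b2$features)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_fixture_files(b1, d1); p2 <- write_fixture_files(b2, d2)
  for (k in names(p1))
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  b3 <- generate_dataset(synthetic_spec(n_variants = 120, n_proteins = 6,
                                        seed = 78))
  expect_false(identical(b1$dataset$records, b3$dataset$records))
})

test_that("noiseless generation makes delta an exact function of the signal", {
  spec <- synthetic_spec(n_variants = 150, n_proteins = 6, noise_sd = 1e-9,
                         signal_weights = c(rsa = 1), seed = 9)
  b <- generate_dataset(spec)
  rsa <- b$features[, "rsa"]
  d <- b$dataset$records$delta_lnkf
  # delta is an affine function of rsa alone
  fit <- lm(d ~ rsa)
  expect_gt(summary(fit)$r.squared, 0.999999)
})

test_that("infeasible noise level is rejected with guidance", {
  expect_error(generate_dataset(synthetic_spec(n_variants = 60,
                                               noise_sd = 5, seed = 1)),
               "lower noise_sd")
})

test_that("fixture files reload into an equivalent pipeline input", {
  b <- get_bench(200L)
  dir <- withr::local_tempdir()
  paths <- write_fixture_files(b, dir)
  ds <- load_dataset(paths[["variants"]], paths[["fasta"]])
  expect_equal(nrow(ds$records), 200)
  ann <- read_annotations(paths[["structural"]], paths[["conservation"]])
  x <- featurize_dataset(ds, ann)
  expect_equal(dim(x), dim(b$features))
  expect_equal(x[, "rsa"], b$features[, "rsa"], tolerance = 1e-4)
})

test_that("toy helix structures parse back with expected geometry", {
  lines <- generate_toy_structure(20)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, pdb)
  atoms <- read_pdb(pdb)
  expect_equal(length(unique(atoms$resnum)), 20)
  expect_true(all(c("N", "CA", "C", "O", "CB") %in% atoms$atom))
  # glycine gets no CB pseudo-atom
  gly <- generate_toy_structure(sequence = "AGA")
  expect_equal(sum(grepl(" CB ", gly)), 2)
  expect_error(generate_toy_structure(2), "at least 3")
})
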