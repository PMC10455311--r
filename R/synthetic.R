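# Synthetic benchmark generator: self-contained proteins, structures,
# annotations and variant sets with a known planted feature -> delta signal,
# so every pipeline stage is testable offline.

#' Specification for a synthetic variant benchmark
#'
#' The defaults state the emulated world: 952 variants in 25 proteins with
#' class proportions 653:175:124 (decrease : no effect : increase), the
#' +/-0.15 classification band, and a linear signal on a small set of named
#' features plus Gaussian noise.  The overall mean and spread of the log
#' rate change are derived from the class proportions and the band, so the
#' planted labels reproduce the stated imbalance.
#'
#' @param n_proteins number of synthetic proteins.
#' @param length_range min/max sequence length.
#' @param n_variants number of variants.
#' @param class_proportions named proportions for decrease/no_effect/increase.
#' @param signal_weights named weights over feature names; the linear
#'   combination (standardised over the generated variants) is the signal.
#' @param noise_sd Gaussian noise on the log rate change (default 0.1).
#' @param threshold classification band half-width.
#' @param alanine_bias if TRUE, about half of variant residues are alanine,
#'   mimicking the alanine-scanning bias of real folding datasets.
#' @param seed master seed; generation is fully deterministic.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_proteins = 25L, length_range = c(60L, 120L),
                           n_variants = 952L,
                           class_proportions = c(decrease = 653, no_effect = 175,
                                                 increase = 124) / 952,
                           signal_weights = c(rsa = -1, `C-score` = 1,
                                              rp = 0.6,
                                              window_NonPolarAA = 0.5),
                           noise_sd = 0.1, threshold = 0.15,
                           alanine_bias = FALSE, seed = 42L) {
  p <- class_proportions / sum(class_proportions)
  if (any(p <= 0) || length(p) != 3)
    stopf("class_proportions must be three positive values")
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 n_variants = as.integer(n_variants),
                 class_proportions = p, signal_weights = signal_weights,
                 noise_sd = noise_sd, threshold = threshold,
                 alanine_bias = alanine_bias, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Mean and total sd of a normal delta distribution that hits the target
# class proportions at the given band half-width.
delta_distribution_params <- function(p, threshold) {
  a <- qnorm(p[["decrease"]])        # (-thr - mu) / s
  b <- qnorm(1 - p[["increase"]])    # ( thr - mu) / s
  if (b <= a) stopf("infeasible class proportions")
  s <- 2 * threshold / (b - a)
  c(mu = -threshold - s * a, s = s)
}

random_ss <- function(len) {
  states <- character(0)
  while (length(states) < len) {
    s <- sample(ss7_states(), 1,
                prob = c(0.32, 0.05, 0.02, 0.25, 0.03, 0.12, 0.21))
    states <- c(states, rep(s, sample(3:8, 1)))
  }
  states[seq_len(len)]
}

#' Generate a synthetic variant benchmark
#'
#' Draws sequences from a residue frequency model, per-residue structural
#' and conservation annotations, and variants whose log folding-rate change
#' is a standardised linear function of the planted signal features plus
#' Gaussian noise, rescaled so the label proportions match the spec.
#' Wild-type and variant rates consistent with the deltas are included, so
#' labels regenerate exactly from the stored values.
#'
#' @param spec a [synthetic_spec()].
#' @param aaindex index table used for featurization (default: the bundled
#'   synthetic table).
#' @param config a [feature_config()].
#' @return list of class `synthetic_benchmark`: dataset, annotations,
#'   features (n x 1161 matrix), weights, spec.
#' @export
generate_dataset <- function(spec = synthetic_spec(),
                             aaindex = default_aaindex(),
                             config = feature_config()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dp <- delta_distribution_params(spec$class_proportions, spec$threshold)
  if (spec$noise_sd >= dp[["s"]])
    stopf(paste("noise_sd %.3f is not below the total delta spread %.3f",
                "implied by the class proportions; lower noise_sd or widen",
                "the proportions"), spec$noise_sd, dp[["s"]])

  local_seed(spec$seed, {
    ids <- sprintf("SYNP%02d", seq_len(spec$n_proteins))
    lens <- sample(spec$length_range[1]:spec$length_range[2],
                   spec$n_proteins, replace = TRUE)
    freqs <- if (spec$alanine_bias)
      setNames(ifelse(amino_acids() == "A", 3, 1), amino_acids())
    else setNames(rep(1, 20), amino_acids())
    seqs <- setNames(vapply(lens, function(l)
      paste(sample(amino_acids(), l, replace = TRUE, prob = freqs),
            collapse = ""), ""), ids)
    kf_wt <- setNames(10 ^ runif(spec$n_proteins, -3, 5), ids)

    structural <- lapply(seqs, function(s) {
      aa <- strsplit(s, "")[[1]]
      data.frame(position = seq_along(aa), ss = random_ss(length(aa)),
                 asa = round(runif(length(aa)) * max_asa_table()[aa], 3),
                 stringsAsFactors = FALSE)
    })
    conservation <- lapply(lens, function(l)
      data.frame(position = seq_len(l), c_score = round(runif(l), 4),
                 coev_max = round(runif(l), 4),
                 coev_np = rpois(l, 2)))
    names(conservation) <- ids

    # sample distinct (protein, position, variant residue) triples
    pool_n <- spec$n_variants * 3L
    pid <- sample(ids, pool_n, replace = TRUE)
    pos <- vapply(pid, function(p) sample.int(lens[match(p, ids)], 1), 1L)
    wt <- substr(seqs[pid], pos, pos)
    var <- vapply(seq_len(pool_n), function(i) {
      others <- setdiff(amino_acids(), wt[i])
      if (spec$alanine_bias && wt[i] != "A" && runif(1) < 0.5) "A"
      else sample(others, 1)
    }, "")
    keep <- !duplicated(paste(pid, pos, var))
    if (sum(keep) < spec$n_variants)
      stopf("could not draw %d distinct variants", spec$n_variants)
    sel <- which(keep)[seq_len(spec$n_variants)]
    rec <- data.frame(protein_id = pid[sel], wt_aa = wt[sel],
                      position = as.integer(pos[sel]), var_aa = var[sel],
                      stringsAsFactors = FALSE)

    # featurize, then plant the signal
    proto <- rec
    proto$delta_lnkf <- 0
    proto_ds <- variant_dataset(proto, seqs, threshold = spec$threshold)
    annotations <- list(structural = structural, conservation = conservation)
    feats <- featurize_dataset(proto_ds, annotations, aaindex, config)

    w <- spec$signal_weights
    raw <- as.numeric(feats[, names(w), drop = FALSE] %*% w)
    if (sd(raw) == 0) stopf("planted signal has zero variance")
    signal <- (raw - mean(raw)) / sd(raw)
    s_sig <- sqrt(dp[["s"]]^2 - spec$noise_sd^2)
    v <- s_sig * signal + rnorm(spec$n_variants, 0, spec$noise_sd)
    # affine calibration: place the empirical p_dec and 1 - p_inc quantiles
    # of the signal + noise sum exactly on the +/- threshold band edges, so
    # realised class proportions match the spec up to order-statistic ties
    q <- stats::quantile(v, c(spec$class_proportions[["decrease"]],
                              1 - spec$class_proportions[["increase"]]),
                         names = FALSE)
    if (q[2] <= q[1]) stopf("infeasible class proportions")
    b <- 2 * spec$threshold / (q[2] - q[1])
    delta <- -spec$threshold + b * (v - q[1])
    rec$kf_wt <- unname(kf_wt[rec$protein_id])
    rec$kf_var <- rec$kf_wt * exp(delta)
    rec$delta_lnkf <- delta
  })

  dataset <- variant_dataset(rec, seqs, threshold = spec$threshold)
  structure(list(dataset = dataset, annotations = annotations,
                 features = feats, weights = spec$signal_weights,
                 signal_sd = unname(sqrt(dp[["s"]]^2 - spec$noise_sd^2)),
                 spec = spec, aaindex = aaindex),
            class = "synthetic_benchmark")
}

#' @export
print.synthetic_benchmark <- function(x, ...) {
  cat(sprintf("<synthetic_benchmark: %d variants, %d proteins, noise sd %.2f>\n",
              nrow(x$dataset$records), length(x$dataset$sequences),
              x$spec$noise_sd))
  invisible(x)
}

#' Generate an idealised helical toy structure
#'
#' A poly-alanine (or given sequence) alpha-helical backbone with CB
#' pseudo side-chain atoms, written as valid PDB ATOM records.  The
#' geometry is deterministic: no randomness.
#'
#' @param length number of residues (>= 3); ignored if `sequence` given.
#' @param sequence optional one-letter sequence.
#' @param path optional output file; when NULL the PDB text is returned.
#' @return the path (invisibly) or a character vector of PDB lines.
#' @export
generate_toy_structure <- function(length = 20L, sequence = NULL,
                                   path = NULL) {
  if (!is.null(sequence)) {
    aa <- strsplit(toupper(sequence), "")[[1]]
    check_standard_aa(aa)
  } else aa <- rep("A", length)
  if (base::length(aa) < 3) stopf("need at least 3 residues")
  three <- setNames(names(THREE_TO_ONE), THREE_TO_ONE)

  lines <- character(0)
  serial <- 0L
  emit <- function(name, resname, resnum, xyz, element) {
    serial <<- serial + 1L
    lines <<- c(lines, sprintf(
      "ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      serial, name, resname, resnum, xyz[1], xyz[2], xyz[3], element))
  }
  helix_point <- function(i, radius, phase_deg, dz) {
    t <- (i - 1) * 100 * pi / 180 + phase_deg * pi / 180
    c(radius * cos(t), radius * sin(t), (i - 1) * 1.5 + dz)
  }
  for (i in seq_along(aa)) {
    rn <- three[[aa[i]]]
    emit("N", rn, i, helix_point(i, 1.6, -28, -0.9), "N")
    emit("CA", rn, i, helix_point(i, 2.3, 0, 0), "C")
    emit("C", rn, i, helix_point(i, 1.8, 26, 0.7), "C")
    emit("O", rn, i, helix_point(i, 2.1, 31, 1.6), "O")
    if (aa[i] != "G") emit("CB", rn, i, helix_point(i, 3.4, 4, -0.2), "C")
  }
  lines <- c(lines, "END")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(path)
}

#' Write a synthetic benchmark as the pipeline's input files
#'
#' Emits variants.tsv, proteins.fasta, structural.tsv and conservation.tsv
#' (the exact formats the loaders consume) into a directory.
#'
#' @param bench a `synthetic_benchmark`.
#' @param dir output directory.
#' @return named character vector of the written paths.
#' @export
write_fixture_files <- function(bench, dir) {
  stopifnot(inherits(bench, "synthetic_benchmark"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(variants = file.path(dir, "variants.tsv"),
             fasta = file.path(dir, "proteins.fasta"),
             structural = file.path(dir, "structural.tsv"),
             conservation = file.path(dir, "conservation.tsv"))
  write_dataset(bench$dataset, paths[["variants"]], paths[["fasta"]])
  write_annotation(bench$annotations$structural, paths[["structural"]])
  write_annotation(bench$annotations$conservation, paths[["conservation"]])
  paths
}
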