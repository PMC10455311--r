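# PDB coordinate ingestion and a reference Shrake-Rupley accessible surface
# area computation.
#
# Coordinates are canonicalised (centroid + principal-axes frame with
# deterministic sign fixing) before the sphere points are laid out, so the
# computed areas are exactly invariant to rigid-body rotation and
# translation of the input structure.

THREE_TO_ONE <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
                  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
                  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
                  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

vdw_radius <- function(element) {
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
  out <- r[element]
  out[is.na(out)] <- 1.70
  unname(out)
}

#' Read ATOM records from a PDB file
#'
#' Fixed-width parsing of the first model; alternate locations other than
#' ' ' or 'A' are dropped.
#'
#' @param path PDB file.
#' @return data.frame: atom, altloc, resname, chain, resnum, x, y, z, element.
#' @export
read_pdb <- function(path) {
  lines <- readLines(path)
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1L)]
  lines <- lines[startsWith(lines, "ATOM")]
  if (!length(lines)) stopf("no ATOM records in %s", path)
  fw <- function(from, to) trimws(substr(lines, from, to))
  df <- data.frame(atom = fw(13, 16), altloc = substr(lines, 17, 17),
                   resname = fw(18, 20), chain = substr(lines, 22, 22),
                   resnum = as.integer(fw(23, 26)),
                   x = as.numeric(fw(31, 38)), y = as.numeric(fw(39, 46)),
                   z = as.numeric(fw(47, 54)), element = fw(77, 78),
                   stringsAsFactors = FALSE)
  df <- df[df$altloc %in% c(" ", "A"), , drop = FALSE]
  blank <- !nzchar(df$element)
  df$element[blank] <- substr(gsub("[0-9]", "", df$atom[blank]), 1, 1)
  rownames(df) <- NULL
  df
}

# Deterministic canonical frame: centre at the centroid, rotate onto the
# principal axes of the coordinate covariance, fix each axis sign so the
# third moment along it is positive (falling back to the largest-magnitude
# coordinate when the moment is degenerate).
canonicalize_coords <- function(xyz) {
  xyz <- sweep(xyz, 2, colMeans(xyz))
  if (nrow(xyz) < 3) return(xyz)
  ev <- eigen(crossprod(xyz), symmetric = TRUE)$vectors
  proj <- xyz %*% ev
  for (k in 1:3) {
    m3 <- sum(proj[, k]^3)
    s <- if (abs(m3) > 1e-8) sign(m3)
         else sign(proj[which.max(abs(proj[, k])), k])
    if (s < 0) proj[, k] <- -proj[, k]
  }
  proj
}

# Deterministic near-uniform unit sphere points (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley accessible surface area per atom
#'
#' Rolls a probe of radius `probe` over each atom's expanded sphere,
#' sampled at `n_points` deterministic points, and counts the fraction not
#' occluded by any neighbouring atom.
#'
#' @param xyz n x 3 coordinate matrix.
#' @param radii per-atom van der Waals radii.
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param n_points sphere sample points per atom (default 240).
#' @return numeric vector of per-atom areas (A^2).
#' @export
shrake_rupley <- function(xyz, radii, probe = 1.4, n_points = 240L) {
  xyz <- canonicalize_coords(as.matrix(xyz))
  n <- nrow(xyz)
  stopifnot(length(radii) == n)
  pts <- sphere_points(n_points)
  R <- radii + probe
  area <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (R[i] + R)^2 & seq_len(n) != i)
    if (!length(nb)) { area[i] <- 4 * pi * R[i]^2; next }
    sp <- sweep(pts * R[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj <- (sp[acc, 1] - xyz[j, 1])^2 + (sp[acc, 2] - xyz[j, 2])^2 +
            (sp[acc, 3] - xyz[j, 3])^2
      acc[acc] <- dj > R[j]^2
    }
    area[i] <- 4 * pi * R[i]^2 * sum(acc) / n_points
  }
  area
}

#' Per-residue accessible surface area of a structure
#'
#' Reference reimplementation of a solvent-accessibility assignment:
#' Shrake-Rupley areas summed over each residue's atoms.  Residues missing
#' a CA atom are flagged as unannotated (`asa = NA`) rather than silently
#' imputed.
#'
#' @param pdb a PDB path or a data.frame from [read_pdb()].
#' @param probe probe radius (default 1.4 A).
#' @param n_points sphere samples per atom (default 240; fixed count makes
#'   the computation deterministic).
#' @return data.frame: chain, resnum, resname, aa (one-letter or NA), asa.
#' @export
compute_asa <- function(pdb, probe = 1.4, n_points = 240L) {
  atoms <- if (is.character(pdb)) read_pdb(pdb) else pdb
  area <- shrake_rupley(as.matrix(atoms[, c("x", "y", "z")]),
                        vdw_radius(atoms$element), probe, n_points)
  key <- paste(atoms$chain, atoms$resnum)
  res <- !duplicated(key)
  out <- data.frame(chain = atoms$chain[res], resnum = atoms$resnum[res],
                    resname = atoms$resname[res],
                    aa = unname(THREE_TO_ONE[atoms$resname[res]]),
                    asa = as.numeric(tapply(area, key, sum)[unique(key)]),
                    stringsAsFactors = FALSE)
  has_ca <- tapply(atoms$atom == "CA", key, any)[unique(key)]
  out$asa[!has_ca] <- NA_real_
  rownames(out) <- NULL
  out
}

#' Build a structural annotation table from a PDB file
#'
#' Combines the internal ASA computation with a user-supplied (or uniform
#' coil) secondary-structure assignment, producing the per-residue table the
#' feature extractor consumes.
#'
#' @param pdb_path PDB file.
#' @param ss optional per-residue secondary structure states (7-state
#'   alphabet); default all coil ("C").
#' @param ... passed to [compute_asa()].
#' @return data.frame with columns position, ss, asa.
#' @export
structural_annotation_from_pdb <- function(pdb_path, ss = NULL, ...) {
  asa <- compute_asa(pdb_path, ...)
  ss <- ss %||% rep("C", nrow(asa))
  stopifnot(length(ss) == nrow(asa))
  data.frame(position = seq_len(nrow(asa)), ss = ss, asa = asa$asa,
             stringsAsFactors = FALSE)
}
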