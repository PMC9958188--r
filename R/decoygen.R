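## Synthetic fixtures: toy RNA-protein complexes and rigid-body decoy sets
## with controlled ligand RMSD.  This replaces an external FFT-docking decoy
## pipeline: the scoring method only needs pose diversity with known RMSD
## labels, which rigid-body perturbation of the RNA provides exactly.

rot_axis_angle <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) * ct + st * K + (1 - ct) * tcrossprod(u)
}

# template heavy-atom geometries (Angstrom, approximate but non-degenerate)
nt_template <- function(res) {
  bb <- rbind(
    P = c(-4.0, 1.0, 0.0), OP1 = c(-4.8, 1.9, 0.8), OP2 = c(-4.5, 0.9, -1.4),
    "O5'" = c(-2.6, 1.6, 0.2), "C5'" = c(-1.6, 0.7, 0.7),
    "C4'" = c(-0.3, 1.4, 0.9), "O4'" = c(0.5, 1.4, -0.3),
    "C3'" = c(0.6, 0.7, 2.0), "O3'" = c(0.4, 1.5, 3.2),
    "C2'" = c(1.9, 0.7, 1.4), "O2'" = c(2.9, 1.5, 2.0),
    "C1'" = c(1.8, 0.9, -0.1))
  pur <- rbind(
    N9 = c(2.5, -0.2, -0.8), C8 = c(2.3, -1.5, -0.7), N7 = c(3.1, -2.2, -1.4),
    C5 = c(3.9, -1.3, -2.0), C6 = c(4.9, -1.5, -2.9), N1 = c(5.5, -0.4, -3.3),
    C2 = c(5.1, 0.8, -2.9), N3 = c(4.2, 1.1, -2.1), C4 = c(3.6, 0.0, -1.7))
  pyr <- rbind(
    N1 = c(2.5, -0.2, -0.8), C2 = c(3.3, 0.5, -1.6), N3 = c(4.0, -0.2, -2.4),
    C4 = c(3.9, -1.5, -2.5), C5 = c(3.1, -2.3, -1.7),
    C6 = c(2.4, -1.6, -0.9))
  base <- switch(res,
    A = rbind(pur, N6 = c(5.4, -2.7, -3.3)),
    G = rbind(pur, O6 = c(5.3, -2.6, -3.2), N2 = c(5.8, 1.8, -3.4)),
    C = rbind(pyr, O2 = c(3.4, 1.7, -1.6), N4 = c(4.6, -2.1, -3.4)),
    U = rbind(pyr, O2 = c(3.4, 1.7, -1.6), O4 = c(4.6, -2.2, -3.3)))
  rbind(bb, base)
}

aa_template <- function(res) {
  bb <- rbind(N = c(-0.5, 1.4, 0.0), CA = c(0.0, 0.0, 0.0),
              C = c(1.5, 0.0, 0.2), O = c(2.2, 1.0, 0.3))
  side <- switch(res,
    GLY = NULL,
    ALA = rbind(CB = c(-0.6, -0.8, -1.1)),
    SER = rbind(CB = c(-0.6, -0.8, -1.1), OG = c(-0.1, -2.1, -1.3)),
    VAL = rbind(CB = c(-0.6, -0.8, -1.1), CG1 = c(-0.2, -2.2, -1.2),
                CG2 = c(-2.1, -0.7, -1.3)),
    stop("no template for residue ", res))
  rbind(bb, side)
}

place_unit <- function(template, rotation, translation) {
  sweep(template %*% t(rotation), 2, translation, "+")
}

#' Generate a deterministic toy RNA-protein complex
#'
#' Builds an idealized A-form-like RNA strand (bases cycling A, G, C, U with
#' full phosphate backbones) and an extended peptide (residues cycling ALA,
#' GLY, SER, VAL), positions the peptide against the RNA so that the minimum
#' intermolecular heavy-atom distance falls between 3 and 5 Angstrom, and
#' adds a small seeded coordinate jitter (+-0.05 Angstrom) so no two
#' complexes are exactly alike.  Every unit carries all frame-anchor atoms
#' and only table-covered atom names, so the complex types and featurizes
#' fully.
#'
#' @param seed Integer seed (all randomness is the jitter).
#' @param n_nt Number of nucleotides (>= 2).
#' @param n_aa Number of residues (>= 2).
#' @return A `complex_structure` (RNA chain "R", protein chain "P").
#' @export
generate_toy_complex <- function(seed = 1L, n_nt = 6L, n_aa = 8L) {
  stopifnot(n_nt >= 2, n_aa >= 2)
  set.seed(seed)
  bases <- rep(c("A", "G", "C", "U"), length.out = n_nt)
  resn <- rep(c("ALA", "GLY", "SER", "VAL"), length.out = n_aa)

  rows <- list()
  add_unit <- function(xyz, res, kind, chain, idx) {
    xyz <- xyz + matrix(stats::runif(length(xyz), -0.05, 0.05),
                        nrow(xyz), 3)
    rows[[length(rows) + 1L]] <<- data.frame(
      chain_id = chain, seq_index = idx, res_code = res, kind = kind,
      atom_name = rownames(xyz), element = element_from_name(rownames(xyz)),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], is_hydrogen = FALSE,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_nt)) {
    R <- rot_axis_angle(c(0, 0, 1), 32.7 * (i - 1))
    tr <- as.vector(R %*% c(9, 0, 0)) + c(0, 0, 2.81 * (i - 1))
    add_unit(place_unit(nt_template(bases[i]), R, tr),
             bases[i], "nucleotide", "R", i)
  }
  for (i in seq_len(n_aa)) {
    R <- rot_axis_angle(c(1, 0, 0), 25 * (i - 1))
    tr <- c(3.2 * (i - 1), 0, 0)
    add_unit(place_unit(aa_template(resn[i]), R, tr),
             resn[i], "amino_acid", "P", i)
  }
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL

  # slide the peptide along +x toward the RNA until the minimum
  # intermolecular heavy-atom distance is 4.0 Angstrom
  is_prot <- atoms$kind == "amino_acid"
  rna_xyz <- as.matrix(atoms[!is_prot, c("x", "y", "z")])
  prot_xyz <- as.matrix(atoms[is_prot, c("x", "y", "z")])
  ctr_r <- colMeans(rna_xyz)
  prot_xyz <- sweep(prot_xyz, 2, colMeans(prot_xyz) - ctr_r - c(40, 0, 0))
  u <- c(-1, 0, 0)
  for (k in 1:40) {
    m <- sqrt(min(cross_dist2(prot_xyz, rna_xyz)))
    if (abs(m - 4.0) < 0.02) break
    prot_xyz <- sweep(prot_xyz, 2, (m - 4.0) * u, "+")
  }
  atoms[is_prot, c("x", "y", "z")] <- prot_xyz
  atoms <- atoms[order(atoms$kind, atoms$chain_id, atoms$seq_index), ,
                 drop = FALSE]
  rownames(atoms) <- NULL
  new_complex_structure(atoms, sprintf("toy_seed%d_%dnt_%daa",
                                       seed, n_nt, n_aa))
}

#' Rigid-body perturbation of the RNA partner
#'
#' Rotates the RNA about its heavy-atom centroid by the given axis-angle and
#' then translates it; the protein is untouched, mimicking rigid-body
#' re-docking of the ligand.
#'
#' @param complex A `complex_structure`.
#' @param axis Rotation axis (3-vector, any nonzero length).
#' @param angle_deg Rotation angle in degrees.
#' @param translation Translation 3-vector, Angstrom.
#' @return The perturbed `complex_structure`.
#' @export
perturb_rigid <- function(complex, axis = c(0, 0, 1), angle_deg = 0,
                          translation = c(0, 0, 0)) {
  a <- complex$atoms
  is_rna <- a$kind == "nucleotide"
  xyz <- as.matrix(a[is_rna, c("x", "y", "z")])
  if (angle_deg != 0) {
    ctr <- colMeans(xyz[!a$is_hydrogen[is_rna], , drop = FALSE])
    R <- rot_axis_angle(axis, angle_deg)
    xyz <- sweep(sweep(xyz, 2, ctr) %*% t(R), 2, ctr, "+")
  }
  xyz <- sweep(xyz, 2, translation, "+")  # exact for pure translations
  a[is_rna, c("x", "y", "z")] <- xyz
  out <- complex
  out$atoms <- a
  out$source_id <- paste0(complex$source_id, "_perturbed")
  out
}

#' Ligand (RNA) RMSD to a reference pose, without superposition
#' @param native,decoy `complex_structure` poses of the same complex.
#' @return RMSD over RNA heavy atoms, Angstrom.
#' @export
ligand_rmsd <- function(native, decoy) {
  m <- match_heavy_atoms(native, decoy, kind = "nucleotide")
  rmsd(coords_matrix(m$native), coords_matrix(m$decoy))
}

#' Decoy set specification
#'
#' @param n_decoys Total decoys.
#' @param max_translation Translation sampling radius, Angstrom (default 12).
#' @param max_rotation Maximum rotation angle, degrees (default 60).
#' @param rmsd_bins Named-free list of `c(lo, hi)` ligand-RMSD bins
#'   (Angstrom, half-open `(lo, hi]` except the first which includes `lo`).
#' @param quotas Integer decoys per bin; must sum to `n_decoys`.
#' @param seed Integer seed.
#' @return A `decoy_spec` list.
#' @export
decoy_spec <- function(n_decoys = 20L, max_translation = 12,
                       max_rotation = 60,
                       rmsd_bins = list(c(0, 4), c(4, 12)),
                       quotas = NULL, seed = 1L) {
  if (is.null(quotas)) {
    quotas <- rep(n_decoys %/% length(rmsd_bins), length(rmsd_bins))
    quotas[1] <- quotas[1] + n_decoys - sum(quotas)
  }
  if (sum(quotas) != n_decoys)
    stop("bin quotas must sum to n_decoys", call. = FALSE)
  lo <- vapply(rmsd_bins, `[`, 0, 1); hi <- vapply(rmsd_bins, `[`, 0, 2)
  if (any(hi <= lo) || any(utils::head(hi, -1) > utils::tail(lo, -1)))
    stop("rmsd_bins must be increasing and non-overlapping", call. = FALSE)
  structure(list(n_decoys = as.integer(n_decoys),
                 max_translation = max_translation,
                 max_rotation = max_rotation, rmsd_bins = rmsd_bins,
                 quotas = as.integer(quotas), seed = as.integer(seed)),
            class = "decoy_spec")
}

#' Generate a rigid-body decoy set with controlled RMSD
#'
#' Rejection-samples rigid transforms (axis uniform on the sphere, angle
#' uniform on `(0, max_rotation]`, translation uniform in the ball of radius
#' `max_translation`) until every RMSD bin quota is met.  Fully determined by
#' `spec$seed`.
#'
#' @param native A `complex_structure`.
#' @param spec A [decoy_spec()].
#' @param max_attempts Attempt budget before an unmet bin raises an error.
#' @return A `decoy_set`: list with `native`, `decoys` (each: `structure`,
#'   `transform`, `ligand_rmsd`, `decoy_id`) and `spec`.
#' @export
generate_decoy_set <- function(native, spec = decoy_spec(),
                               max_attempts = 5000L * max(spec$n_decoys, 1L)) {
  set.seed(spec$seed)
  remaining <- spec$quotas
  decoys <- list()
  attempts <- 0L
  while (sum(remaining) > 0L) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      open <- which(remaining > 0L)[1]
      stop(sprintf("cannot fill RMSD bin (%g, %g] under max_translation %g / max_rotation %g",
                   spec$rmsd_bins[[open]][1], spec$rmsd_bins[[open]][2],
                   spec$max_translation, spec$max_rotation), call. = FALSE)
    }
    axis <- stats::rnorm(3)
    angle <- stats::runif(1, 0, spec$max_rotation)
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    tr <- dir * spec$max_translation * stats::runif(1)^(1 / 3)
    dec <- perturb_rigid(native, axis, angle, tr)
    r <- ligand_rmsd(native, dec)
    bin <- which(vapply(seq_along(spec$rmsd_bins), function(i) {
      b <- spec$rmsd_bins[[i]]
      remaining[i] > 0L && r <= b[2] && (r > b[1] || (i == 1L && r >= b[1]))
    }, TRUE))
    if (length(bin) == 0L) next
    bin <- bin[1]
    remaining[bin] <- remaining[bin] - 1L
    id <- sprintf("decoy_%03d", length(decoys) + 1L)
    dec$source_id <- paste0(native$source_id, "_", id)
    decoys[[id]] <- list(structure = dec,
                         transform = list(axis = axis, angle_deg = angle,
                                          translation = tr),
                         ligand_rmsd = r, decoy_id = id)
  }
  structure(list(native = native, decoys = decoys, spec = spec),
            class = "decoy_set")
}

#' Write a decoy set as PDB files plus a manifest CSV
#'
#' @param set A `decoy_set`.
#' @param dir Output directory (created if needed).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_decoy_set <- function(set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_pdb(set$native, file.path(dir, "native.pdb"))
  rows <- lapply(set$decoys, function(d) {
    write_pdb(d$structure, file.path(dir, paste0(d$decoy_id, ".pdb")))
    ax <- d$transform$axis / sqrt(sum(d$transform$axis^2))
    data.frame(decoy_id = d$decoy_id, rx = ax[1], ry = ax[2], rz = ax[3],
               angle = d$transform$angle_deg, tx = d$transform$translation[1],
               ty = d$transform$translation[2],
               tz = d$transform$translation[3], ligand_rmsd = d$ligand_rmsd)
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}
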