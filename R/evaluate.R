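## Assessment: RMSD, protein superposition, interface RMSD, success rates,
## and a simplified intermolecular hydrogen-bond detector.

#' Root-mean-square deviation between paired coordinate sets
#'
#' `sqrt(mean(|a_i - b_i|^2))` over the given pairing; no superposition is
#' performed.
#'
#' @param coords_a,coords_b Numeric n x 3 matrices, row i of `coords_a`
#'   paired with row i of `coords_b`.
#' @return RMSD in the units of the input (Angstrom).
#' @export
rmsd <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (!identical(dim(coords_a), dim(coords_b)) || ncol(coords_a) != 3L ||
      nrow(coords_a) < 1L)
    stop("coordinate sets must be equal-sized n x 3 matrices (n >= 1)",
         call. = FALSE)
  sqrt(mean(rowSums((coords_a - coords_b)^2)))
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of
#' `rotation %*% mobile_i + translation` onto the reference.  Reflections are
#' forbidden (determinant forced to +1), so a mirror-image pair keeps a
#' positive fit RMSD.
#'
#' @param mobile,reference Paired n x 3 coordinate matrices, n >= 3 and not
#'   collinear.
#' @return A `superposition_result`: `rotation` (3 x 3, det +1),
#'   `translation` (3-vector), `fit_rmsd`.
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference)) || ncol(mobile) != 3L)
    stop("paired n x 3 matrices required", call. = FALSE)
  n <- nrow(mobile)
  if (n < 3L)
    stop("at least 3 atom pairs required for superposition", call. = FALSE)
  mbar <- colMeans(mobile); rbar <- colMeans(reference)
  P <- sweep(mobile, 2, mbar); Q <- sweep(reference, 2, rbar)
  sv_ref <- svd(Q)$d
  if (sv_ref[2] < 1e-8 * max(sv_ref[1], 1))
    stop("degenerate (collinear or coincident) coordinates", call. = FALSE)
  H <- crossprod(P, Q)                      # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tvec <- rbar - as.vector(R %*% mbar)
  fitted <- tcrossprod(P, R) + matrix(rbar, n, 3, byrow = TRUE)
  structure(list(rotation = R, translation = tvec,
                 fit_rmsd = rmsd(fitted, reference)),
            class = "superposition_result")
}

apply_transform <- function(coords, rotation, translation) {
  tcrossprod(coords, rotation) + matrix(translation, nrow(coords), 3,
                                        byrow = TRUE)
}

# pair heavy atoms of two poses of the same complex by identity
match_heavy_atoms <- function(native, decoy, kind = NULL) {
  a <- heavy_atoms(native); b <- heavy_atoms(decoy)
  if (!is.null(kind)) {
    a <- a[a$kind == kind, , drop = FALSE]
    b <- b[b$kind == kind, , drop = FALSE]
  }
  akey <- paste(a$kind, a$chain_id, a$seq_index, a$atom_name, sep = "\r")
  bkey <- paste(b$kind, b$chain_id, b$seq_index, b$atom_name, sep = "\r")
  idx <- match(akey, bkey)
  if (anyNA(idx)) {
    missing <- a[is.na(idx), c("res_code", "chain_id", "seq_index",
                               "atom_name")]
    stop("atom correspondence failure; decoy lacks: ",
         paste(utils::head(apply(missing, 1, paste, collapse = " "), 5),
               collapse = "; "),
         if (nrow(missing) > 5) " ...", call. = FALSE)
  }
  list(native = a, decoy = b[idx, , drop = FALSE])
}

#' Interface RMSD between a native complex and a decoy pose
#'
#' CAPRI-style I_rmsd: (1) interface units are defined on the native at
#' `cutoff`; (2) the decoy's protein heavy atoms (or backbone, see
#' `superpose_atoms`) are superposed onto the native protein; (3) the
#' transform is applied to the whole decoy; (4) the RMSD is taken over all
#' heavy atoms of the native interface units on both sides.
#'
#' @param native,decoy `complex_structure` poses of the same complex.
#' @param cutoff Interface cutoff on the native, 6.0 Angstrom.
#' @param superpose_atoms `"heavy"` (all protein heavy atoms, default) or
#'   `"backbone"` (N, CA, C, O).
#' @return Interface RMSD in Angstrom.
#' @export
interface_rmsd <- function(native, decoy, cutoff = 6.0,
                           superpose_atoms = c("heavy", "backbone")) {
  superpose_atoms <- match.arg(superpose_atoms)
  sel <- suppressWarnings(extract_interface(native, cutoff = cutoff))
  if (nrow(sel) == 0L)
    stop("native interface is empty at ", cutoff,
         " Angstrom: I_rmsd undefined", call. = FALSE)

  prot <- match_heavy_atoms(native, decoy, kind = "amino_acid")
  if (superpose_atoms == "backbone") {
    bb <- prot$native$atom_name %in% c("N", "CA", "C", "O")
    prot <- list(native = prot$native[bb, , drop = FALSE],
                 decoy = prot$decoy[bb, , drop = FALSE])
  }
  sp <- superpose(coords_matrix(prot$decoy), coords_matrix(prot$native))

  all_atoms <- match_heavy_atoms(native, decoy)
  ukey <- paste(all_atoms$native$kind, all_atoms$native$chain_id,
                all_atoms$native$seq_index, sep = "\r")
  skey <- paste(sel$kind, sel$chain_id, sel$seq_index, sep = "\r")
  in_iface <- ukey %in% skey
  nat_xyz <- coords_matrix(all_atoms$native[in_iface, , drop = FALSE])
  dec_xyz <- apply_transform(
    coords_matrix(all_atoms$decoy[in_iface, , drop = FALSE]),
    sp$rotation, sp$translation)
  rmsd(nat_xyz, dec_xyz)
}

#' Top-N success rate over a set of complexes
#'
#' A complex counts as a success when at least one of its `N` best-scored
#' decoys has interface RMSD at or below `threshold` (closed interval, so a
#' decoy at exactly 4.0 Angstrom is native-like).
#'
#' @param reports List with one element per complex: a data frame ranked
#'   best-first with at least an `irmsd` column.
#' @param N Number of top-ranked decoys considered.
#' @param threshold Native-likeness threshold, 4.0 Angstrom.
#' @return Fraction of complexes predicted successfully.
#' @export
success_rate <- function(reports, N, threshold = 4.0) {
  if (length(reports) == 0L) stop("no ranked reports given", call. = FALSE)
  hits <- vapply(reports, function(r) {
    top <- utils::head(r$irmsd, N)
    any(top <= threshold)
  }, TRUE)
  mean(hits)
}

#' Per-complex evaluation report
#'
#' Combines rankings and interface RMSDs into a success table over a list of
#' top-N cutoffs.
#'
#' @param reports As in [success_rate()].
#' @param top_n Integer vector of N values (default 1, 5, 10, 20, 30, 40, 50).
#' @param threshold Native-likeness threshold.
#' @return An `evaluation_report`: list with `success` (data frame `N`,
#'   `rate`), `best_irmsd_top_n`, `threshold`, `per_complex`.
#' @export
evaluation_report <- function(reports, top_n = c(1, 5, 10, 20, 30, 40, 50),
                              threshold = 4.0) {
  success <- data.frame(
    N = top_n,
    rate = vapply(top_n, function(n) success_rate(reports, n, threshold), 0))
  best <- vapply(top_n, function(n)
    mean(vapply(reports, function(r) min(utils::head(r$irmsd, n)), 0)), 0)
  structure(list(success = success,
                 best_irmsd_top_n = data.frame(N = top_n, mean_best = best),
                 threshold = threshold, per_complex = reports),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report: %d complexes, threshold %.1f Angstrom>\n",
              length(x$per_complex), x$threshold))
  print(x$success, row.names = FALSE)
  invisible(x)
}

## ---- hydrogen bonds --------------------------------------------------------

# simplified donor/acceptor classification per (residue, atom)
hbond_class <- local({
  rna_donor <- list(common = "O2'", A = "N6", G = c("N1", "N2"), C = "N4",
                    U = "N3")
  rna_acceptor <- list(
    common = c("OP1", "OP2", "O5'", "O3'", "O4'", "O2'"),
    A = c("N1", "N3", "N7"), G = c("O6", "N3", "N7"), C = c("O2", "N3"),
    U = c("O2", "O4"))
  prot_donor <- list(
    common = "N",  # backbone amide; proline excluded in code
    ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
    HIS = c("ND1", "NE2"), LYS = "NZ", SER = "OG", THR = "OG1",
    TRP = "NE1", TYR = "OH")
  prot_acceptor <- list(
    common = "O",
    ASN = "OD1", ASP = c("OD1", "OD2"), GLN = "OE1", GLU = c("OE1", "OE2"),
    HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH")
  list(rna_donor = rna_donor, rna_acceptor = rna_acceptor,
       prot_donor = prot_donor, prot_acceptor = prot_acceptor)
})

flag_atoms <- function(atoms, spec) {
  out <- atoms$atom_name %in% spec$common
  for (res in setdiff(names(spec), "common"))
    out <- out | (atoms$res_code == res & atoms$atom_name %in% spec[[res]])
  out
}

#' Detect intermolecular hydrogen bonds
#'
#' A simplified geometric detector for RNA-protein hydrogen bonds: a
#' donor-acceptor pair across the interface is reported when the
#' donor-acceptor distance is at most `da_max` (3.35 Angstrom) and, if the
#' structure contains hydrogens bonded to the donor (within 1.2 Angstrom),
#' the shortest hydrogen-acceptor distance is at most `ha_max`
#' (2.7 Angstrom).  Structures without hydrogens (typical X-ray models) are
#' judged by the heavy-atom criterion alone and flagged `h_checked = FALSE`.
#' No angular criteria are applied.
#'
#' @param complex A `complex_structure`.
#' @param da_max Maximum donor-acceptor distance, Angstrom.
#' @param ha_max Maximum hydrogen-acceptor distance, Angstrom.
#' @return Data frame, one row per bond: donor/acceptor residue and atom
#'   labels, `da_dist`, `ha_dist` (NA without hydrogens), `h_checked`.
#' @export
find_hbonds <- function(complex, da_max = 3.35, ha_max = 2.7) {
  a <- complex$atoms
  hyd <- a[a$is_hydrogen, , drop = FALSE]
  heavy <- a[!a$is_hydrogen, , drop = FALSE]
  rna <- heavy[heavy$kind == "nucleotide", , drop = FALSE]
  prot <- heavy[heavy$kind == "amino_acid", , drop = FALSE]
  pro_bb_n <- prot$atom_name == "N" & prot$res_code == "PRO"

  pairs <- list(
    list(don = rna[flag_atoms(rna, hbond_class$rna_donor), , drop = FALSE],
         acc = prot[flag_atoms(prot, hbond_class$prot_acceptor), ,
                    drop = FALSE]),
    list(don = prot[flag_atoms(prot, hbond_class$prot_donor) & !pro_bb_n, ,
                    drop = FALSE],
         acc = rna[flag_atoms(rna, hbond_class$rna_acceptor), , drop = FALSE]))

  rows <- list()
  for (p in pairs) {
    if (nrow(p$don) == 0L || nrow(p$acc) == 0L) next
    d2 <- cross_dist2(coords_matrix(p$don), coords_matrix(p$acc))
    hit <- which(d2 <= da_max^2, arr.ind = TRUE)
    for (k in seq_len(nrow(hit))) {
      don <- p$don[hit[k, 1], ]; acc <- p$acc[hit[k, 2], ]
      ha <- NA_real_; h_checked <- FALSE
      if (nrow(hyd) > 0L) {
        same_unit <- hyd$kind == don$kind & hyd$chain_id == don$chain_id &
          hyd$seq_index == don$seq_index
        hu <- hyd[same_unit, , drop = FALSE]
        if (nrow(hu) > 0L) {
          dh <- sqrt(rowSums(sweep(coords_matrix(hu), 2,
                                   unlist(don[c("x", "y", "z")]))^2))
          hu <- hu[dh <= 1.2, , drop = FALSE]
          if (nrow(hu) > 0L) {
            h_checked <- TRUE
            ha <- min(sqrt(rowSums(sweep(coords_matrix(hu), 2,
                                         unlist(acc[c("x", "y", "z")]))^2)))
            if (ha > ha_max) next
          }
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        donor_res = don$res_code, donor_chain = don$chain_id,
        donor_seq = don$seq_index, donor_atom = don$atom_name,
        acceptor_res = acc$res_code, acceptor_chain = acc$chain_id,
        acceptor_seq = acc$seq_index, acceptor_atom = acc$atom_name,
        da_dist = sqrt(d2[hit[k, 1], hit[k, 2]]), ha_dist = ha,
        h_checked = h_checked, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(donor_res = character(), donor_chain = character(),
                      donor_seq = integer(), donor_atom = character(),
                      acceptor_res = character(),
                      acceptor_chain = character(), acceptor_seq = integer(),
                      acceptor_atom = character(), da_dist = numeric(),
                      ha_dist = numeric(), h_checked = logical(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$da_dist), , drop = FALSE]
}
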