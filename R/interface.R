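## Atom typing and interface extraction.

#' Annotate a complex with atom types, masses and charges
#'
#' Looks every heavy atom up in the RNA or protein atom type table (by
#' residue code and atom name) and attaches `type_id`, `mass` and `charge`
#' columns.  Hydrogens are never typed.  Heavy atoms missing from the tables
#' are either skipped with a warning (default) or cause an error.
#'
#' @param complex A `complex_structure` from [parse_pdb()].
#' @param rna_table,protein_table [atom_type_table()] objects.
#' @param unknown_policy `"skip"` (drop untyped atoms from featurization,
#'   warn) or `"fail"` (error naming the offending pair).
#' @return The complex with annotated atoms; untyped heavy atoms carry `NA`
#'   type columns and are excluded by [n_typed_atoms()] and featurization.
#' @export
assign_types <- function(complex, rna_table = atom_type_table("rna"),
                         protein_table = atom_type_table("protein"),
                         unknown_policy = c("skip", "fail")) {
  unknown_policy <- match.arg(unknown_policy)
  a <- complex$atoms
  tab <- rbind(as.data.frame(rna_table), as.data.frame(protein_table))
  # protein/rna alphabets are disjoint so one combined key is unambiguous
  key <- paste(a$res_code, a$atom_name, sep = "\r")
  tkey <- paste(tab$res_code, tab$atom_name, sep = "\r")
  idx <- match(key, tkey)
  idx[a$is_hydrogen] <- NA_integer_

  a$type_id <- tab$type_id[idx]
  a$mass <- tab$mass[idx]
  a$charge <- tab$charge[idx]

  unknown <- is.na(idx) & !a$is_hydrogen
  if (any(unknown)) {
    pairs <- unique(paste0("(", a$res_code[unknown], ", ",
                           a$atom_name[unknown], ")"))
    if (unknown_policy == "fail")
      stop("atoms not in type tables: ", paste(pairs, collapse = ", "),
           call. = FALSE)
    warning(sum(unknown), " heavy atom(s) not in type tables, skipped: ",
            paste(pairs, collapse = ", "), call. = FALSE)
  }
  complex$atoms <- a
  complex$typed <- TRUE
  complex
}

#' @rdname assign_types
#' @return For `n_typed_atoms()`: number of heavy atoms carrying a type.
#' @export
n_typed_atoms <- function(complex) {
  sum(!is.na(complex$atoms$type_id))
}

typed_atoms <- function(complex) {
  complex$atoms[!is.na(complex$atoms$type_id), , drop = FALSE]
}

# per-unit minimum heavy-atom distance to the partner molecule
min_partner_distances <- function(complex) {
  h <- heavy_atoms(complex)
  rna <- h[h$kind == "nucleotide", , drop = FALSE]
  prot <- h[h$kind == "amino_acid", , drop = FALSE]
  d2 <- cross_dist2(coords_matrix(rna), coords_matrix(prot))
  rna_min <- sqrt(apply(d2, 1, min))
  prot_min <- sqrt(apply(d2, 2, min))
  mins <- function(a, dmin, units) {
    v <- tapply(dmin, paste(a$chain_id, a$seq_index, sep = "\r"), min)
    as.numeric(v[paste(units$chain_id, units$seq_index, sep = "\r")])
  }
  ru <- unit_table(complex, "nucleotide")
  pu <- unit_table(complex, "amino_acid")
  u <- rbind(cbind(ru, min_partner_distance = mins(rna, rna_min, ru)),
             cbind(pu, min_partner_distance = mins(prot, prot_min, pu)))
  rownames(u) <- NULL
  u
}

# squared distances, n x m
cross_dist2 <- function(A, B) {
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

#' Extract the RNA-protein interaction interface
#'
#' A unit (nucleotide or residue) belongs to the interface when the minimum
#' distance from any of its heavy atoms to any heavy atom of the partner
#' molecule is at most `cutoff` (closed interval).  Selection is ordered RNA
#' units first, then protein units, each by (chain, sequence number).
#'
#' @param complex A `complex_structure`.
#' @param cutoff Interface distance cutoff in Angstrom (default 6.0).
#' @return An `interface_selection`: data frame of selected units with their
#'   `min_partner_distance`, plus a `cutoff` attribute.  An empty selection
#'   is returned (with a warning) when the molecules do not approach within
#'   `cutoff`.
#' @export
extract_interface <- function(complex, cutoff = 6.0) {
  stopifnot(cutoff > 0)
  u <- min_partner_distances(complex)
  sel <- u[u$min_partner_distance <= cutoff, , drop = FALSE]
  sel <- sel[order(sel$kind != "nucleotide", sel$chain_id, sel$seq_index), ,
             drop = FALSE]
  rownames(sel) <- NULL
  if (nrow(sel) == 0L)
    warning("empty interface at cutoff ", cutoff, " Angstrom", call. = FALSE)
  structure(sel, cutoff = cutoff,
            class = c("interface_selection", "data.frame"))
}

#' @export
print.interface_selection <- function(x, ...) {
  cat(sprintf("<interface_selection: %d units (%d rna, %d protein) at %.1f Angstrom>\n",
              nrow(x), sum(x$kind == "nucleotide"),
              sum(x$kind == "amino_acid"), attr(x, "cutoff")))
  invisible(x)
}
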