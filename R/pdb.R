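## PDB ingestion and the complex_structure container.
##
## A complex_structure holds the heavy-atom model of one RNA-protein complex
## as a single atom table plus a source label.  Units (nucleotides /
## amino-acid residues) are identified by (kind, chain_id, seq_index).

RNA_CODES <- c("A", "G", "C", "U")
AA_CODES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
              "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
              "TYR", "VAL")

# map PDB residue names to canonical codes; NA = not a standard unit
canonical_res_code <- function(res_name) {
  res_name <- toupper(trimws(res_name))
  out <- rep(NA_character_, length(res_name))
  out[res_name %in% AA_CODES] <- res_name[res_name %in% AA_CODES]
  out[res_name %in% RNA_CODES] <- res_name[res_name %in% RNA_CODES]
  pref <- res_name %in% paste0("R", RNA_CODES)  # RA/RG/RC/RU variants
  out[pref] <- substr(res_name[pref], 2, 2)
  out
}

element_from_name <- function(name) {
  # heavy biopolymer atoms start with their element letter; names such as
  # "1H5'" indicate hydrogens
  first <- sub("^[0-9']*", "", name)
  el <- toupper(substr(first, 1, 1))
  el[el == ""] <- "X"
  el
}

#' Parse a PDB file into a complex structure
#'
#' Reads ATOM records of standard residues (20 amino acids) and
#' ribonucleotides (A, G, C, U, optionally written RA/RG/RC/RU), resolves
#' alternate locations to the highest-occupancy conformer, drops waters,
#' ions and other heteroatoms, and groups atoms into protein and RNA units.
#' Hydrogens are retained but flagged (`is_hydrogen`); all downstream
#' distance and featurization logic uses heavy atoms only.
#'
#' @param path Path to a PDB-format text file.
#' @param source_id Label for the structure; defaults to the file name.
#' @return A `complex_structure`: list with `atoms` (data frame: `chain_id`,
#'   `seq_index`, `res_code`, `kind`, `atom_name`, `element`, `x`, `y`, `z`,
#'   `is_hydrogen`) and `source_id`.
#' @seealso [write_pdb()], [assign_types()], [extract_interface()]
#' @export
parse_pdb <- function(path, source_id = basename(path)) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  lines <- lines[rec %in% c("ATOM  ", "HETATM")]
  if (length(lines) == 0L)
    stop("no ATOM records in ", path, call. = FALSE)

  df <- data.frame(
    atom_name = trimws(substr(lines, 13, 16)),
    altloc    = substr(lines, 17, 17),
    res_name  = trimws(substr(lines, 18, 20)),
    chain_id  = trimws(substr(lines, 22, 22)),
    seq_index = as.integer(substr(lines, 23, 26)),
    x = as.numeric(substr(lines, 31, 38)),
    y = as.numeric(substr(lines, 39, 46)),
    z = as.numeric(substr(lines, 47, 54)),
    occupancy = suppressWarnings(as.numeric(substr(lines, 55, 60))),
    element   = trimws(substr(lines, 77, 78)),
    stringsAsFactors = FALSE)
  df$occupancy[is.na(df$occupancy)] <- 1.0
  df$res_code <- canonical_res_code(df$res_name)
  df <- df[!is.na(df$res_code), , drop = FALSE]  # waters/ions/hetero dropped
  if (nrow(df) == 0L)
    stop("no standard protein or RNA residues in ", path, call. = FALSE)
  if (any(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z)))
    stop("non-finite coordinates in ", path, call. = FALSE)

  no_el <- df$element == ""
  df$element[no_el] <- element_from_name(df$atom_name[no_el])
  df$is_hydrogen <- df$element %in% c("H", "D")
  df$kind <- ifelse(df$res_code %in% RNA_CODES, "nucleotide", "amino_acid")

  # altloc resolution: keep the highest-occupancy copy of each atom,
  # preserving file order otherwise
  df$.row <- seq_len(nrow(df))
  key <- paste(df$kind, df$chain_id, df$seq_index, df$res_code, df$atom_name,
               sep = "\r")
  ord <- order(key, -df$occupancy)
  df <- df[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
  df <- df[order(df$kind, df$chain_id, df$seq_index, df$.row), , drop = FALSE]
  atoms <- df[, c("chain_id", "seq_index", "res_code", "kind", "atom_name",
                  "element", "x", "y", "z", "is_hydrogen")]
  rownames(atoms) <- NULL
  new_complex_structure(atoms, source_id)
}

new_complex_structure <- function(atoms, source_id) {
  if (!any(atoms$kind == "amino_acid") || !any(atoms$kind == "nucleotide"))
    stop("complex must contain at least one protein and one RNA unit",
         call. = FALSE)
  structure(list(atoms = atoms, source_id = source_id),
            class = "complex_structure")
}

unit_table <- function(x, kind = NULL) {
  a <- x$atoms
  if (!is.null(kind)) a <- a[a$kind == kind, , drop = FALSE]
  u <- unique(a[, c("kind", "chain_id", "seq_index", "res_code")])
  u <- u[order(u$kind, u$chain_id, u$seq_index), , drop = FALSE]
  rownames(u) <- NULL
  u
}

#' @rdname parse_pdb
#' @param x A `complex_structure`.
#' @return For `rna_units()`/`protein_units()`: a data frame with one row per
#'   unit (`kind`, `chain_id`, `seq_index`, `res_code`), ordered by chain and
#'   author sequence number.
#' @export
rna_units <- function(x) unit_table(x, "nucleotide")

#' @rdname parse_pdb
#' @export
protein_units <- function(x) unit_table(x, "amino_acid")

# atoms of one unit
unit_atoms <- function(x, kind, chain_id, seq_index) {
  a <- x$atoms
  a[a$kind == kind & a$chain_id == chain_id & a$seq_index == seq_index, ,
    drop = FALSE]
}

heavy_atoms <- function(x) x$atoms[!x$atoms$is_hydrogen, , drop = FALSE]

coords_matrix <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z")])
}

#' @export
print.complex_structure <- function(x, ...) {
  cat(sprintf("<complex_structure '%s': %d rna units, %d protein units, %d atoms>\n",
              x$source_id, nrow(rna_units(x)), nrow(protein_units(x)),
              nrow(x$atoms)))
  invisible(x)
}

#' Write a complex structure to a PDB file
#'
#' Emits fixed-column ATOM records (one chain block per chain, RNA chains
#' first) with coordinates at PDB precision (0.001 Angstrom).
#'
#' @param complex A `complex_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(complex, path) {
  a <- complex$atoms
  a <- a[order(a$kind == "amino_acid", a$chain_id, a$seq_index), , drop = FALSE]
  name_fmt <- ifelse(nchar(a$atom_name) < 4, sprintf(" %-3s", a$atom_name),
                     a$atom_name)
  res_out <- ifelse(a$kind == "nucleotide", sprintf("%3s", a$res_code),
                    a$res_code)
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), name_fmt, res_out, a$chain_id, a$seq_index,
    a$x, a$y, a$z, 1.0, 0.0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
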