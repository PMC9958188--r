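#' Atom type tables
#'
#' An atom type table maps a (residue code, atom name) pair to an integer
#' type id, an atomic mass (Da) and a partial charge (elementary charge
#' units).  The tables drive featurization: only atoms present in a table
#' contribute to the voxel channels.  Two tables ship with the package under
#' \code{inst/extdata}: a canonical RNA heavy-atom table (85 entries: the
#' four ribonucleotides with a full 5'-phosphate backbone) and a canonical
#' protein heavy-atom table (167 entries: backbone N, CA, C, O plus side
#' chains of the 20 standard amino acids).  Masses are IUPAC standard atomic
#' weights; charges are AMBER-style approximations (the files are labelled
#' \code{_synthetic} because no reference charge set is bundled) and the
#' table file is the single source of truth - point \code{path} at your own
#' file to replace them.
#'
#' @param molecule `"rna"` or `"protein"`.
#' @param path Optional path to a tab-separated table with columns
#'   `res_code`, `atom_name`, `type_id`, `mass`, `charge`.  Defaults to the
#'   bundled table for `molecule`.
#' @return An object of class `atom_type_table`: a data frame with the five
#'   columns above and a `molecule` attribute.
#' @examples
#' tab <- atom_type_table("rna")
#' count_types(tab)  # 85
#' @export
atom_type_table <- function(molecule = c("rna", "protein"), path = NULL) {
  molecule <- match.arg(molecule)
  if (is.null(path)) {
    fname <- sprintf("atom_types_%s_synthetic.tsv", molecule)
    path <- system.file("extdata", fname, package = "rpscore", mustWork = TRUE)
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           quote = "", comment.char = "",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "character",
                                          "integer", "numeric", "numeric"))
  required <- c("res_code", "atom_name", "type_id", "mass", "charge")
  if (!all(required %in% names(tab)))
    stop("atom type table must have columns: ",
         paste(required, collapse = ", "), call. = FALSE)
  validate_atom_type_table(tab)
  structure(tab[, required], molecule = molecule,
            class = c("atom_type_table", "data.frame"))
}

validate_atom_type_table <- function(tab) {
  if (nrow(tab) == 0L) return(invisible(tab))
  ids <- sort(tab$type_id)
  if (anyDuplicated(ids) || !identical(ids, seq_len(nrow(tab)) - 1L))
    stop("type_ids must be unique and contiguous from 0", call. = FALSE)
  if (any(tab$mass <= 0))
    stop("masses must be strictly positive", call. = FALSE)
  if (anyDuplicated(tab[, c("res_code", "atom_name")]))
    stop("duplicate (res_code, atom_name) entries", call. = FALSE)
  invisible(tab)
}

#' Number of entries in an atom type table
#'
#' @param table An [atom_type_table()].
#' @return Integer count of (residue code, atom name) entries.
#' @export
count_types <- function(table) {
  stopifnot(inherits(table, "atom_type_table") || is.data.frame(table))
  nrow(table)
}

#' @export
print.atom_type_table <- function(x, ...) {
  cat(sprintf("<atom_type_table: %s, %d entries>\n",
              attr(x, "molecule"), nrow(x)))
  invisible(x)
}
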