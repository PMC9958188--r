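## Local coordinate frames.
##
## Each interface unit gets a right-handed orthonormal frame built from four
## anchor atoms, making the voxel features invariant to global rigid motion
## of the complex:
##   x = r_anchor - r_origin            (glycosidic N for nucleotides, CB for
##                                       residues; origin C1' / CA)
##   y = (r_a3 + r_a4) / 2 - r_origin   (O5' and C5' / O and C)
##   z = x cross y;  X = x/|x|;  Z = z/|z|;  Y = Z cross X

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# ideal-tetrahedral virtual CB from backbone N, CA, C (used for glycine)
virtual_cb <- function(n, ca, c) {
  b <- ca - n
  cc <- c - ca
  a <- cross3(b, cc)
  -0.58273431 * a + 0.56802827 * b - 0.54067466 * cc + ca
}

glycosidic_n <- function(res_code) {
  if (res_code %in% c("A", "G")) "N9" else "N1"
}

#' Build the local coordinate frame of one unit
#'
#' @param atoms Data frame with the atoms of a single nucleotide or residue
#'   (one row per atom, columns as in `complex_structure$atoms`).
#' @return A `local_frame`: list with `origin` (3-vector, the C1'/CA
#'   position) and `axes` (3x3 matrix with rows X, Y, Z).  Local coordinates
#'   of a point r are `axes %*% (r - origin)`.
#' @details For glycine, which has no CB, a virtual CB is placed from N, CA
#'   and C by the standard ideal-tetrahedral construction.  Errors of class
#'   `rpscore_frame_error` signal a missing anchor atom; collinear anchors
#'   (vanishing x or x-cross-y) raise `rpscore_degenerate_frame`.
#' @export
build_frame <- function(atoms) {
  kind <- atoms$kind[1]
  res <- atoms$res_code[1]
  get <- function(name) {
    i <- which(atoms$atom_name == name)
    if (length(i) == 0L) return(NULL)
    c(atoms$x[i[1]], atoms$y[i[1]], atoms$z[i[1]])
  }
  if (kind == "nucleotide") {
    origin <- get("C1'"); a1 <- get(glycosidic_n(res))
    a3 <- get("O5'"); a4 <- get("C5'")
    needed <- c("C1'", glycosidic_n(res), "O5'", "C5'")
  } else {
    origin <- get("CA"); a1 <- get("CB")
    a3 <- get("O"); a4 <- get("C")
    needed <- c("CA", if (res != "GLY") "CB", "O", "C")
    if (is.null(a1) && res == "GLY") {
      n <- get("N")
      if (!is.null(n) && !is.null(origin) && !is.null(a4))
        a1 <- virtual_cb(n, origin, a4)
      needed <- c(needed, "N")
    }
  }
  if (is.null(origin) || is.null(a1) || is.null(a3) || is.null(a4)) {
    miss <- setdiff(needed, atoms$atom_name)
    stop(structure(class = c("rpscore_frame_error", "error", "condition"),
                   list(message = paste0("missing frame anchor atom(s) ",
                                         paste(miss, collapse = ", "), " in ",
                                         res, " ", atoms$chain_id[1],
                                         atoms$seq_index[1]),
                        call = NULL)))
  }
  x <- a1 - origin
  y <- (a3 + a4) / 2 - origin
  z <- cross3(x, y)
  nx <- sqrt(sum(x^2)); nz <- sqrt(sum(z^2))
  if (nx < 1e-10 || nz < 1e-10)
    stop(structure(class = c("rpscore_degenerate_frame", "error", "condition"),
                   list(message = paste0("degenerate (collinear) frame anchors in ",
                                         res, " ", atoms$chain_id[1],
                                         atoms$seq_index[1]),
                        call = NULL)))
  X <- x / nx
  Z <- z / nz
  Y <- cross3(Z, X)
  structure(list(origin = origin, axes = rbind(X = X, Y = Y, Z = Z)),
            class = "local_frame")
}

#' @export
print.local_frame <- function(x, ...) {
  cat("<local_frame>\norigin:", format(x$origin, digits = 4), "\n")
  print(x$axes, digits = 4)
  invisible(x)
}
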