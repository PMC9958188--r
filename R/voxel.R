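## Voxelization: per-unit grids and the stacked complex tensor.

#' Voxelize typed atoms into a unit's local grid
#'
#' Bins every typed heavy atom of the complex (both molecules - this is what
#' lets a grid encode intermolecular contacts) into a cube of
#' `grid_dim` x `grid_dim` x `grid_dim` voxels of 1 Angstrom edge, centered
#' on the frame origin and aligned with the frame axes.  An atom at local
#' coordinates c falls into voxel `floor(c + grid_dim/2)` per axis (half-open
#' bins; atoms on the +half-extent boundary are excluded).  Three channels
#' accumulate occupancy count, summed mass (Da) and summed charge (e).
#'
#' @param frame A [build_frame()] result.
#' @param atoms Data frame of typed atoms (rows with non-`NA` `mass`,
#'   `charge`), e.g. the typed atoms of a whole complex.
#' @param grid_dim Number of 1-Angstrom bins per axis (default 32).
#' @return A numeric array of dim `c(3, grid_dim, grid_dim, grid_dim)`
#'   (channels: occupancy, mass, charge), class `voxel_grid`.
#' @export
voxelize <- function(frame, atoms, grid_dim = 32L) {
  g <- as.integer(grid_dim)
  half <- g / 2
  out <- array(0, dim = c(3L, g, g, g))
  if (nrow(atoms) > 0L) {
    local <- (coords_matrix(atoms) -
                matrix(frame$origin, nrow(atoms), 3, byrow = TRUE)) %*%
      t(frame$axes)
    idx <- floor(local + half)
    keep <- rowSums(idx >= 0 & idx <= g - 1) == 3L
    if (any(keep)) {
      idx <- idx[keep, , drop = FALSE]
      lin <- 1L + idx[, 1] + g * idx[, 2] + g * g * idx[, 3]
      occ <- rowsum(rep(1, length(lin)), lin)
      ms <- rowsum(atoms$mass[keep], lin)
      ch <- rowsum(atoms$charge[keep], lin)
      at <- as.integer(rownames(occ))
      # channel-first layout: channel varies fastest
      out[1L + 3L * (at - 1L)] <- occ
      out[2L + 3L * (at - 1L)] <- ms
      out[3L + 3L * (at - 1L)] <- ch
    }
  }
  class(out) <- c("voxel_grid", class(out))
  out
}

#' Assemble the network input tensor for one complex
#'
#' Builds a local frame and voxel grid for every interface unit and stacks
#' the grids along the sequence dimension: RNA units first (by chain,
#' sequence number), then protein units, zero-padded to length `L`.  Units
#' whose frame cannot be built are dropped with a warning.  If more than `L`
#' units are featurizable, the `L` units closest to the partner molecule
#' (smallest `min_partner_distance`, ties by selection order) are kept and a
#' warning reports the truncation.
#'
#' @param selection An [extract_interface()] result.
#' @param complex The typed `complex_structure` the selection came from.
#' @param L Maximum number of units (sequence length), default 128.
#' @param grid_dim Voxel grid edge, default 32.
#' @return A `complex_tensor`: list with `data` (array
#'   `c(3, L, grid_dim, grid_dim, grid_dim)`), `mask` (length-`L` 0/1
#'   vector) and `unit_order` (data frame mapping slice index to unit).
#' @export
assemble_tensor <- function(selection, complex, L = 128L, grid_dim = 32L) {
  if (nrow(selection) == 0L)
    stop("empty interface selection: nothing to featurize", call. = FALSE)
  atoms <- typed_atoms(complex)

  frames <- vector("list", nrow(selection))
  ok <- logical(nrow(selection))
  for (i in seq_len(nrow(selection))) {
    ua <- unit_atoms(complex, selection$kind[i], selection$chain_id[i],
                     selection$seq_index[i])
    frames[[i]] <- tryCatch(build_frame(ua), error = function(e) e)
    ok[i] <- inherits(frames[[i]], "local_frame")
  }
  if (any(!ok))
    warning(sum(!ok), " unit(s) dropped (no valid frame)", call. = FALSE)
  if (!any(ok))
    stop("no featurizable interface units", call. = FALSE)

  sel <- selection[ok, , drop = FALSE]
  frames <- frames[ok]
  if (nrow(sel) > L) {
    keep <- order(sel$min_partner_distance)[seq_len(L)]
    keep <- sort(keep)  # preserve RNA-then-protein unit order
    warning("interface has ", nrow(sel), " units; keeping the ", L,
            " closest to the partner molecule", call. = FALSE)
    sel <- sel[keep, , drop = FALSE]
    frames <- frames[keep]
  }

  g <- as.integer(grid_dim)
  data <- array(0, dim = c(3L, as.integer(L), g, g, g))
  for (i in seq_along(frames))
    data[, i, , , ] <- voxelize(frames[[i]], atoms, g)
  mask <- c(rep(1L, nrow(sel)), rep(0L, L - nrow(sel)))
  sel$slice <- seq_len(nrow(sel))
  structure(list(data = data, mask = mask, unit_order = sel),
            class = "complex_tensor")
}

#' Featurize a typed complex end-to-end
#'
#' Convenience wrapper: interface selection at `cutoff` followed by
#' [assemble_tensor()].  A pose whose partners share no contact within
#' `cutoff` (possible for strongly perturbed rigid-body decoys, unlike real
#' docked poses) is featurized from its nearest-contact units instead: the
#' cutoff is widened to the minimum intermolecular distance plus 1 Angstrom,
#' with a warning, so that every pose remains scoreable.
#'
#' @param complex A typed `complex_structure` (see [assign_types()]).
#' @param cutoff Interface cutoff, Angstrom.
#' @param L,grid_dim Tensor dimensions, see [assemble_tensor()].
#' @return A `complex_tensor`.
#' @export
featurize_structure <- function(complex, cutoff = 6.0, L = 128L,
                                grid_dim = 32L) {
  sel <- suppressWarnings(extract_interface(complex, cutoff = cutoff))
  if (nrow(sel) == 0L) {
    u <- min_partner_distances(complex)
    c2 <- min(u$min_partner_distance) + 1
    warning(sprintf("no contacts within %.1f Angstrom; using nearest-contact units at %.1f Angstrom",
                    cutoff, c2), call. = FALSE)
    sel <- extract_interface(complex, cutoff = c2)
  }
  assemble_tensor(sel, complex, L = L, grid_dim = grid_dim)
}

#' @export
print.complex_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<complex_tensor: %d x %d x %d^3, %d real units>\n",
              d[1], d[2], d[3], sum(x$mask)))
  invisible(x)
}
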