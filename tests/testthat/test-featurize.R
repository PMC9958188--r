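# Local frames and voxelization.

fake_unit <- function(names, coords, res = "A", kind = "nucleotide") {
  data.frame(chain_id = "R", seq_index = 1L, res_code = res, kind = kind,
             atom_name = names, element = substr(names, 1, 1),
             x = coords[, 1], y = coords[, 2], z = coords[, 3],
             is_hydrogen = FALSE, stringsAsFactors = FALSE)
}

test_that("build_frame reproduces the axis-aligned case", {
  u <- fake_unit(c("C1'", "N9", "O5'", "C5'"),
                 rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 1, 0)))
  fr <- build_frame(u)
  expect_equal(fr$origin, c(0, 0, 0))
  expect_equal(unname(fr$axes["X", ]), c(1, 0, 0))
  expect_equal(unname(fr$axes["Y", ]), c(0, 1, 0))
  expect_equal(unname(fr$axes["Z", ]), c(0, 0, 1))
})

test_that("build_frame signals missing anchors and degeneracy", {
  u <- fake_unit(c("C1'", "O5'", "C5'"),
                 rbind(c(0, 0, 0), c(0, 1, 0), c(0, 1, 0)))
  expect_error(build_frame(u), class = "rpscore_frame_error")
  # y parallel to x
  u2 <- fake_unit(c("C1'", "N9", "O5'", "C5'"),
                  rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(2, 0, 0)))
  expect_error(build_frame(u2), class = "rpscore_degenerate_frame")
})

test_that("frames are orthonormal and right-handed on 100 random units", {
  nt <- toy_complex$atoms[toy_complex$atoms$kind == "nucleotide" &
                            toy_complex$atoms$seq_index == 1, ]
  set.seed(99)
  for (i in 1:100) {
    R <- random_rotation(i)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    u <- nt
    xyz <- as.matrix(u[, c("x", "y", "z")]) %*% t(R) +
      matrix(stats::rnorm(3, sd = 10), nrow(u), 3, byrow = TRUE)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = 0.05), nrow(u), 3)
    u[, c("x", "y", "z")] <- xyz
    fr <- build_frame(u)
    A <- fr$axes
    expect_equal(unname(A %*% t(A)), diag(3), tolerance = 1e-9)
    expect_equal(det(A), 1, tolerance = 1e-9)
  }
})

test_that("glycine units get a virtual CB frame", {
  gly <- toy_complex$atoms[toy_complex$atoms$res_code == "GLY" &
                             toy_complex$atoms$seq_index == 2, ]
  expect_false("CB" %in% gly$atom_name)
  fr <- build_frame(gly)
  expect_equal(det(fr$axes), 1, tolerance = 1e-9)
})

test_that("voxelize follows the floor(c + half) indexing rule", {
  fr <- structure(list(origin = c(0, 0, 0), axes = diag(3)),
                  class = "local_frame")
  atom <- data.frame(x = 0, y = 0, z = 0, mass = 12.011, charge = -0.1)
  g <- voxelize(fr, atom, grid_dim = 32)
  expect_equal(g[1, 17, 17, 17], 1)       # local 0 -> bin 16 (0-based)
  expect_equal(g[2, 17, 17, 17], 12.011)
  expect_equal(g[3, 17, 17, 17], -0.1)
  expect_equal(sum(g != 0), 3)

  # out of extent: unchanged grid
  far <- data.frame(x = 20, y = 0, z = 0, mass = 1, charge = 0)
  expect_equal(sum(voxelize(fr, far, grid_dim = 32)), 0)
  # +16 boundary excluded, -16 included
  edge <- data.frame(x = c(16, -16), y = 0, z = 0, mass = 1, charge = 0)
  ge <- voxelize(fr, edge, grid_dim = 32)
  expect_equal(sum(ge[1, , , ]), 1)
  expect_equal(ge[1, 1, 17, 17], 1)

  # additivity in a shared voxel
  two <- data.frame(x = c(0.2, 0.7), y = 0.1, z = 0.1,
                    mass = c(12, 14), charge = c(-0.3, 0.1))
  g2 <- voxelize(fr, two, grid_dim = 32)
  expect_equal(g2[1, 17, 17, 17], 2)
  expect_equal(g2[2, 17, 17, 17], 26)
  expect_equal(g2[3, 17, 17, 17], -0.2, tolerance = 1e-12)
})

test_that("channel totals conserve in-box counts, mass and charge", {
  atoms <- rpscore:::typed_atoms(toy_complex)
  sel <- extract_interface(toy_complex)
  for (i in seq_len(nrow(sel))) {
    u <- rpscore:::unit_atoms(toy_complex, sel$kind[i], sel$chain_id[i],
                              sel$seq_index[i])
    fr <- build_frame(u)
    g <- voxelize(fr, atoms, grid_dim = 32)
    # brute-force containment: local coordinates per atom
    local <- (as.matrix(atoms[, c("x", "y", "z")]) -
                matrix(fr$origin, nrow(atoms), 3, byrow = TRUE)) %*%
      t(fr$axes)
    inside <- rowSums(floor(local + 16) >= 0 & floor(local + 16) <= 31) == 3
    expect_equal(sum(g[1, , , ]), sum(inside))
    expect_equal(sum(g[2, , , ]), sum(atoms$mass[inside]))
    expect_equal(sum(g[3, , , ]), sum(atoms$charge[inside]), tolerance = 1e-9)
    expect_true(all(g[1, , , ] == round(g[1, , , ])) && all(g[1, , , ] >= 0))
  }
})

test_that("voxel grids are invariant under global rigid motion", {
  t1 <- assemble_tensor(extract_interface(toy_complex), toy_complex,
                        L = 16, grid_dim = 16)
  moved <- apply_rigid(toy_complex, random_rotation(5), c(13.2, -7.5, 40))
  t2 <- assemble_tensor(extract_interface(moved), moved,
                        L = 16, grid_dim = 16)
  expect_identical(t1$data, t2$data)
  expect_identical(t1$mask, t2$mask)
})

test_that("assemble_tensor pads, masks and truncates as specified", {
  sel <- extract_interface(toy_complex)
  tt <- assemble_tensor(sel, toy_complex, L = 8, grid_dim = 8)
  n <- nrow(tt$unit_order)
  expect_equal(sum(tt$mask), n)
  for (i in seq(n + 1, 8)) expect_true(all(tt$data[, i, , , ] == 0))
  # determinism
  tt2 <- assemble_tensor(sel, toy_complex, L = 8, grid_dim = 8)
  expect_identical(tt$data, tt2$data)

  # truncation keeps the units closest to the partner
  wide <- suppressWarnings(extract_interface(toy_complex, cutoff = 30))
  expect_gt(nrow(wide), 3)
  expect_warning(tr <- assemble_tensor(wide, toy_complex, L = 3,
                                       grid_dim = 8),
                 "keeping")
  kept <- sort(tr$unit_order$min_partner_distance)
  all_d <- sort(wide$min_partner_distance)
  expect_equal(kept, all_d[1:3])

  # total mass equals the per-unit brute-force totals
  atoms <- rpscore:::typed_atoms(toy_complex)
  want_mass <- 0
  for (i in seq_len(nrow(tr$unit_order))) {
    u <- rpscore:::unit_atoms(toy_complex, tr$unit_order$kind[i],
                              tr$unit_order$chain_id[i],
                              tr$unit_order$seq_index[i])
    fr <- build_frame(u)
    local <- (as.matrix(atoms[, c("x", "y", "z")]) -
                matrix(fr$origin, nrow(atoms), 3, byrow = TRUE)) %*%
      t(fr$axes)
    inside <- rowSums(floor(local + 4) >= 0 & floor(local + 4) <= 7) == 3
    want_mass <- want_mass + sum(atoms$mass[inside])
  }
  expect_equal(sum(tr$data[2, , , , ]), want_mass)
})
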