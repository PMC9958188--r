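# RMSD, superposition, interface RMSD, success bookkeeping, hydrogen bonds.

test_that("rmsd obeys closed forms and an independent summation oracle", {
  A <- matrix(stats::rnorm(30, sd = 5), 10)
  expect_equal(rmsd(A, A), 0)
  B <- sweep(A, 2, c(3, 4, 0), "+")
  expect_equal(rmsd(A, B), 5.0, tolerance = 1e-12)

  set.seed(50)
  P <- matrix(stats::rnorm(150), 50)
  Q <- matrix(stats::rnorm(150), 50)
  acc <- 0
  for (i in 1:50) acc <- acc + sum((P[i, ] - Q[i, ])^2)
  expect_equal(rmsd(P, Q), sqrt(acc / 50), tolerance = 1e-12)
  expect_equal(rmsd(P, Q), rmsd(Q, P))
  # triangle-like bound
  R <- matrix(stats::rnorm(150), 50)
  expect_lte(rmsd(P, R), rmsd(P, Q) + rmsd(Q, R) + 1e-12)
  expect_error(rmsd(P, Q[1:10, ]), "equal-sized")
})

test_that("superpose recovers rigid motions and forbids reflections", {
  set.seed(51)
  ref <- matrix(stats::rnorm(60, sd = 4), 20)
  R <- random_rotation(51); if (det(R) < 0) R[, 1] <- -R[, 1]
  mob <- ref %*% R + matrix(c(5, -3, 2), 20, 3, byrow = TRUE)
  sp <- superpose(mob, ref)
  expect_lt(sp$fit_rmsd, 1e-9)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  expect_equal(unname(t(sp$rotation) %*% sp$rotation), diag(3),
               tolerance = 1e-9)

  # mirror image cannot be superposed with a proper rotation
  mirror <- ref; mirror[, 1] <- -mirror[, 1]
  spm <- superpose(mirror, ref)
  expect_equal(det(spm$rotation), 1, tolerance = 1e-9)
  expect_gt(spm$fit_rmsd, 0.1)

  # optimality: no random rigid placement beats the least-squares fit
  noisy <- ref + matrix(stats::rnorm(60, sd = 0.3), 20)
  spn <- superpose(noisy, ref)
  set.seed(52)
  for (i in 1:1000) {
    Rr <- random_rotation(1000 + i); if (det(Rr) < 0) Rr[, 1] <- -Rr[, 1]
    tr <- stats::rnorm(3, sd = 2)
    placed <- noisy %*% t(Rr) + matrix(tr, 20, 3, byrow = TRUE)
    expect_gte(rmsd(placed, ref) + 1e-12, spn$fit_rmsd)
  }
  # degenerate input
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(superpose(line, line), "degenerate")
})

test_that("interface RMSD matches its closed form and invariances", {
  native <- toy_complex
  expect_equal(interface_rmsd(native, native), 0)

  # RNA translated by (0,0,2): protein superposition is the identity, so
  # interface RNA atoms contribute 4 each and protein atoms 0
  dec <- perturb_rigid(native, translation = c(0, 0, 2))
  sel <- extract_interface(native)
  h <- native$atoms[!native$atoms$is_hydrogen, ]
  key <- paste(h$kind, h$chain_id, h$seq_index)
  skey <- paste(sel$kind, sel$chain_id, sel$seq_index)
  n_rna <- sum(key %in% skey & h$kind == "nucleotide")
  n_prot <- sum(key %in% skey & h$kind == "amino_acid")
  expect_gt(n_rna, 0); expect_gt(n_prot, 0)
  expect_equal(interface_rmsd(native, dec),
               sqrt(n_rna * 4 / (n_rna + n_prot)), tolerance = 1e-9)

  # global rigid motion of the decoy is removed by superposition
  moved <- apply_rigid(dec, random_rotation(53), c(20, -10, 5))
  expect_equal(interface_rmsd(native, moved), interface_rmsd(native, dec),
               tolerance = 1e-6)
  whole <- apply_rigid(native, random_rotation(54), c(-7, 3, 11))
  expect_lt(interface_rmsd(native, whole), 1e-6)

  # empty native interface is an error
  apart <- perturb_rigid(native, translation = c(500, 0, 0))
  expect_error(interface_rmsd(apart, apart), "empty|undefined")
})

test_that("success rates follow the closed-interval top-N rules", {
  mk <- function(irmsds) data.frame(decoy_id = seq_along(irmsds),
                                    irmsd = irmsds)
  # native at rank 1 everywhere: 100% at N = 1
  expect_equal(success_rate(list(mk(c(0, 9, 9)), mk(c(0.5, 8, 8))), N = 1),
               1.0)
  # exactly 4.0 at rank 3 counts (closed interval) at N = 5
  expect_equal(success_rate(list(mk(c(9, 9, 4.0, 9, 9))), N = 5), 1.0)
  expect_equal(success_rate(list(mk(c(9, 9, 4.01, 9, 9))), N = 5), 0.0)
  # only sub-4 decoy at rank 6: failure at 5, success at 10
  r <- mk(c(9, 9, 9, 9, 9, 3.2, 9, 9, 9, 9))
  expect_equal(success_rate(list(r), N = 5), 0.0)
  expect_equal(success_rate(list(r), N = 10), 1.0)
  # monotone in N and threshold
  rates_n <- vapply(c(1, 5, 10), function(n) success_rate(list(r), n), 0)
  expect_identical(rates_n, sort(rates_n))
  rates_t <- vapply(c(2, 4, 10), function(th)
    success_rate(list(r), N = 10, threshold = th), 0)
  expect_identical(rates_t, sort(rates_t))
  # mixed set: one success of two complexes
  expect_equal(success_rate(list(mk(c(1, 9)), mk(c(9, 9))), N = 2), 0.5)
  expect_error(success_rate(list(), N = 1), "no ranked")

  rep <- evaluation_report(list(r), top_n = c(1, 5, 10))
  expect_equal(rep$success$rate, c(0, 0, 1))
})

test_that("hydrogen bonds honour both distance cutoffs", {
  mk_cx <- function(da, ha = NULL) {
    atoms <- data.frame(
      chain_id = c("R", "P"), seq_index = 1L,
      res_code = c("A", "SER"), kind = c("nucleotide", "amino_acid"),
      atom_name = c("N6", "OE1"), element = c("N", "O"),
      x = c(0, da), y = 0, z = 0, is_hydrogen = FALSE,
      stringsAsFactors = FALSE)
    atoms$atom_name[2] <- "OG"  # SER acceptor
    if (!is.null(ha)) {
      atoms <- rbind(atoms, data.frame(
        chain_id = "R", seq_index = 1L, res_code = "A", kind = "nucleotide",
        atom_name = "H61", element = "H", x = da - ha, y = 0, z = 0,
        is_hydrogen = TRUE, stringsAsFactors = FALSE))
    }
    rpscore:::new_complex_structure(atoms, "hb")
  }
  hb <- find_hbonds(mk_cx(3.30, ha = 2.5))
  expect_equal(nrow(hb), 1)
  expect_equal(hb$da_dist, 3.30, tolerance = 1e-9)
  expect_true(hb$h_checked)
  expect_equal(nrow(find_hbonds(mk_cx(3.40))), 0)
  expect_equal(nrow(find_hbonds(mk_cx(3.30, ha = 2.9))), 0)
  # without hydrogens the heavy-atom criterion decides, flagged unchecked
  hb2 <- find_hbonds(mk_cx(3.30))
  expect_equal(nrow(hb2), 1)
  expect_false(hb2$h_checked)
})

test_that("hydrogen bond detection matches a brute-force scan", {
  cx <- toy_complex
  hb <- find_hbonds(cx)
  # independent double loop with the same classification tables
  cls <- rpscore:::hbond_class
  h <- cx$atoms[!cx$atoms$is_hydrogen, ]
  rna <- h[h$kind == "nucleotide", ]; prot <- h[h$kind == "amino_acid", ]
  count <- 0
  flag <- rpscore:::flag_atoms
  pairs <- list(list(d = rna[flag(rna, cls$rna_donor), ],
                     a = prot[flag(prot, cls$prot_acceptor), ]),
                list(d = prot[flag(prot, cls$prot_donor) &
                                !(prot$atom_name == "N" &
                                    prot$res_code == "PRO"), ],
                     a = rna[flag(rna, cls$rna_acceptor), ]))
  for (p in pairs)
    for (i in seq_len(nrow(p$d))) for (j in seq_len(nrow(p$a))) {
      d <- sqrt(sum((unlist(p$d[i, c("x", "y", "z")]) -
                       unlist(p$a[j, c("x", "y", "z")]))^2))
      if (d <= 3.35) count <- count + 1
    }
  expect_equal(nrow(hb), count)
})
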