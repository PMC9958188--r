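# PDB parsing, atom typing, interface extraction.

pdb_line <- function(serial, name, alt, res, chain, seq, x, y, z,
                     occ = 1, el = substr(name, 1, 1)) {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, alt, res, chain, seq, x, y, z, occ, 0, el)
}

test_that("parse_pdb round-trips a generated complex", {
  cx <- generate_toy_complex(seed = 3, n_nt = 4, n_aa = 5)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(cx, path)
  back <- parse_pdb(path)
  expect_equal(nrow(rna_units(back)), 4)
  expect_equal(nrow(protein_units(back)), 5)
  # coordinates preserved to PDB precision
  expect_equal(back$atoms$x, cx$atoms$x, tolerance = 1e-3)
  expect_equal(back$atoms$atom_name, cx$atoms$atom_name)
})

test_that("parse_pdb rejects single-molecule and unreadable inputs", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_line(1, "N", " ", "ALA", "A", 1, 0, 0, 0),
               pdb_line(2, "CA", " ", "ALA", "A", 1, 1.5, 0, 0), "END"),
             path)
  expect_error(parse_pdb(path), "protein and.*RNA|RNA")
  expect_error(parse_pdb(file.path(tempdir(), "no_such.pdb")),
               "cannot read")
})

test_that("alternate locations resolve to the highest occupancy", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "C1'", "A", "  A", "R", 1, 1, 0, 0, occ = 0.6),
    pdb_line(2, "C1'", "B", "  A", "R", 1, 9, 9, 9, occ = 0.4),
    pdb_line(3, "N9", " ", "  A", "R", 1, 2, 0, 0),
    pdb_line(4, "CA", " ", "ALA", "P", 1, 5, 0, 0), "END"), path)
  cx <- parse_pdb(path)
  a <- cx$atoms[cx$atoms$atom_name == "C1'", ]
  expect_equal(nrow(a), 1)
  expect_equal(unname(unlist(a[, c("x", "y", "z")])), c(1, 0, 0))
})

test_that("hetero records and waters are dropped, hydrogens flagged", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "C1'", " ", "  A", "R", 1, 0, 0, 0),
    pdb_line(2, "H1'", " ", "  A", "R", 1, 0.5, 0, 0, el = "H"),
    pdb_line(3, "O", " ", "HOH", "W", 1, 8, 8, 8),
    sub("^ATOM  ", "HETATM", pdb_line(4, "MG", " ", " MG", "M", 1, 9, 9, 9)),
    pdb_line(5, "CA", " ", "GLY", "P", 1, 4, 0, 0), "END"), path)
  cx <- parse_pdb(path)
  expect_equal(nrow(cx$atoms), 3)
  expect_true(cx$atoms$is_hydrogen[cx$atoms$atom_name == "H1'"])
  expect_false(any(cx$atoms$res_code %in% c("HOH", "MG")))
})

test_that("atom type tables have the canonical entry counts", {
  expect_equal(count_types(rna_tab), 85)
  expect_equal(count_types(prot_tab), 167)
  expect_true(all(rna_tab$mass > 0) && all(prot_tab$mass > 0))
  # contiguous unique ids from 0
  expect_equal(sort(rna_tab$type_id), 0:84)
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("res_code\tatom_name\ttype_id\tmass\tcharge", empty)
  expect_equal(count_types(atom_type_table("rna", path = empty)), 0)
})

test_that("assign_types attaches table values and honours unknown_policy", {
  cx <- assign_types(generate_toy_complex(2, 4, 4))
  a_c1 <- cx$atoms[cx$atoms$res_code == "A" & cx$atoms$atom_name == "C1'", ][1, ]
  entry <- rna_tab[rna_tab$res_code == "A" & rna_tab$atom_name == "C1'", ]
  expect_equal(a_c1$mass, entry$mass)
  expect_equal(a_c1$charge, entry$charge)

  # inject a nonstandard atom name
  bad <- generate_toy_complex(2, 4, 4)
  bad$atoms$atom_name[1] <- "XX1"
  n_before <- n_typed_atoms(assign_types(generate_toy_complex(2, 4, 4)))
  expect_warning(typed <- assign_types(bad), "XX1")
  expect_equal(n_typed_atoms(typed), n_before - 1)
  expect_error(assign_types(bad, unknown_policy = "fail"), "XX1")

  # brute-force set-membership oracle over the whole complex
  keys <- paste(cx$atoms$res_code, cx$atoms$atom_name)
  tab_keys <- c(paste(rna_tab$res_code, rna_tab$atom_name),
                paste(prot_tab$res_code, prot_tab$atom_name))
  expect_equal(n_typed_atoms(cx),
               sum(!cx$atoms$is_hydrogen & keys %in% tab_keys))
})

test_that("interface membership uses a closed <= cutoff interval", {
  sel <- extract_interface(two_atom_complex(5.9), cutoff = 6)
  expect_equal(nrow(sel), 2)
  sel <- extract_interface(two_atom_complex(6.0), cutoff = 6)
  expect_equal(nrow(sel), 2)
  expect_warning(sel <- extract_interface(two_atom_complex(100), cutoff = 6),
                 "empty interface")
  expect_equal(nrow(sel), 0)
})

test_that("extract_interface agrees with a brute-force double loop", {
  cx <- toy_complex
  h <- cx$atoms[!cx$atoms$is_hydrogen, ]
  rna <- h[h$kind == "nucleotide", ]
  prot <- h[h$kind == "amino_acid", ]
  for (cutoff in c(4, 6, 10)) {
    want <- character()
    for (i in seq_len(nrow(rna))) for (j in seq_len(nrow(prot))) {
      d <- sqrt(sum((unlist(rna[i, c("x", "y", "z")]) -
                     unlist(prot[j, c("x", "y", "z")]))^2))
      if (d <= cutoff)
        want <- c(want,
                  paste("nucleotide", rna$chain_id[i], rna$seq_index[i]),
                  paste("amino_acid", prot$chain_id[j], prot$seq_index[j]))
    }
    sel <- suppressWarnings(extract_interface(cx, cutoff = cutoff))
    got <- paste(sel$kind, sel$chain_id, sel$seq_index)
    expect_setequal(got, unique(want))
    expect_true(all(sel$min_partner_distance <= cutoff))
  }
})

test_that("interface selection is monotone in the cutoff and two-sided", {
  cuts <- c(3, 4, 5, 6, 8)
  sels <- lapply(cuts, function(co)
    suppressWarnings(extract_interface(toy_complex, cutoff = co)))
  keys <- lapply(sels, function(s) paste(s$kind, s$chain_id, s$seq_index))
  for (i in seq_along(cuts)[-1])
    expect_true(all(keys[[i - 1]] %in% keys[[i]]))
  # both molecules present whenever nonempty; closest approach is shared
  big <- sels[[length(sels)]]
  expect_true(all(c("nucleotide", "amino_acid") %in% big$kind))
  expect_equal(min(big$min_partner_distance[big$kind == "nucleotide"]),
               min(big$min_partner_distance[big$kind == "amino_acid"]))
})
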