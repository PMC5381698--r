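test_that("a written synthetic assembly parses back identically", {
  asm <- toy_c4()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(asm, f)
  n_atom_records <- sum(grepl("^ATOM", readLines(f)))
  back <- read_structure(f)
  expect_equal(nrow(back), n_atom_records)
  expect_equal(chain_ids(back), chain_ids(asm))
  expect_equal(back$resno, asm$resno)
  expect_lte(max(abs(atom_coords(back) - atom_coords(asm))), 0.001)
  # idempotence of parse -> write -> parse on retained fields
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(back, f2)
  back2 <- read_structure(f2)
  expect_equal(as.data.frame(back2[, c("chain", "resno", "resid", "elety")]),
               as.data.frame(back[, c("chain", "resno", "resid", "elety")]),
               ignore_attr = TRUE)
  expect_equal(atom_coords(back2), atom_coords(back))
})

test_that("altloc policy keeps one highest-occupancy conformer", {
  lines <- c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA AALA A   1      11.639   6.071  -5.147  0.40  0.00           C",
    "ATOM      3  CA BALA A   1      12.639   7.071  -4.147  0.60  0.00           C",
    "ATOM      4  C   ALA A   1      10.673   6.661  -4.120  1.00  0.00           C",
    "ATOM      5  O   ALA A   1       9.580   6.138  -3.895  1.00  0.00           O",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  asm <- read_structure(f)
  ca <- asm[asm$elety == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$altloc, "B")   # higher occupancy wins
  expect_equal(ca$o, 0.6)

  # tie on occupancy: altloc letter order breaks it
  lines[2] <- sub("0.40", "0.50", lines[2])
  lines[3] <- sub("0.60", "0.50", lines[3])
  writeLines(lines, f)
  asm <- read_structure(f)
  expect_equal(asm[asm$elety == "CA", ]$altloc, "A")
})

test_that("mmCIF input is accepted", {
  asm <- toy_c4(n_res = 12)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(asm, f)
  # build a minimal mmCIF from the same atoms
  cif <- withr::local_tempfile(fileext = ".cif")
  at <- as.data.frame(asm)
  writeLines(c(
    "data_toy",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    sprintf("ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s %s %s 1",
            at$serial, at$element, at$elety, at$resid, at$chain, at$resno,
            at$x, at$y, at$z, at$resno, at$resid, at$chain, at$elety)
  ), cif)
  back <- read_structure(cif, format = "mmcif")
  expect_equal(nrow(back), nrow(asm))
  expect_equal(sort(unique(back$chain)), c("A", "B", "C", "D"))
})

test_that("unparsable and empty inputs raise errors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), f)
  expect_error(read_structure(f))
  expect_error(read_structure("no/such/file.pdb"), "not found")
  asm <- toy_c4()
  expect_error(write_structure(asm[0, ]), "empty")
  big <- asm
  big$x[1] <- 123456.0
  expect_error(write_structure(big, withr::local_tempfile()), "field")
})

test_that("region resolution counts, offsets and missing residues", {
  # chain with residues 280..300
  sub <- make_subunit(1, 21)
  sub$resno <- sub$resno + 279L
  asm <- new_assembly(sub)
  reg <- region_definition("SB_loop", c(286, 293), "hUGP1")
  sel <- resolve_region(asm, reg, "A")
  expect_equal(dplyr::n_distinct(sel$resno), 8)

  # isoform-2 style numbering: same chain renumbered 11 lower, offset -11
  iso2 <- asm
  iso2$resno <- iso2$resno - 11L
  sel2 <- resolve_region(iso2, reg, "A", offset = -11)
  expect_equal(sort(unique(sel2$resno)), 275:282)

  # disordered stretch is reported missing, not dropped silently
  gap <- asm[!(asm$resno %in% 290:291), ]
  sel3 <- resolve_region(gap, reg, "A")
  expect_equal(attr(sel3, "missing_resno"), c(290, 291))

  # empty selection warns but does not throw
  expect_warning(out <- resolve_region(asm, region_definition("far", c(900, 910)), "A"),
                 "no residues")
  expect_equal(nrow(out), 0)
  expect_error(resolve_region(asm, reg, "Z"), "not present")
})

test_that("region resolution is offset-linear", {
  asm <- new_assembly(make_subunit(1, 30))
  reg <- region_definition("r", c(5, 12))
  for (a in c(-7L, 3L, 25L)) {
    ren <- asm
    ren$resno <- ren$resno + a
    shifted <- resolve_region(ren, reg, "A", offset = a)
    base <- resolve_region(asm, reg, "A", offset = 0)
    expect_equal(shifted$resno - a, base$resno)
    expect_equal(atom_coords(shifted), atom_coords(base))
  }
})

test_that("region definitions validate and load from YAML", {
  expect_error(region_definition("bad", c(10, 5)), "start <= end")
  expect_error(region_definition("bad", list(c(1, 5), c(4, 8))), "overlap")
  path <- system.file("extdata", "hugp_regions.yaml", package = "quatstruct")
  regs <- read_regions(path)
  expect_true(all(c("SB_loop", "SB_region", "beta23") %in% names(regs)))
  expect_equal(regs$SB_loop$ranges[[1]], c(286L, 293L))
  expect_equal(regs$SB_region$numbering_scheme, "hUGP1")
})

test_that("heteroatoms survive parsing but stay out of protein selections", {
  asm <- toy_c4(n_res = 12)
  lig <- atom_row(9999L, "A", 500L, "UDP", "C1", c(3, 3, 3))
  lig$het <- TRUE
  withlig <- new_assembly(dplyr::bind_rows(tibble::as_tibble(asm), lig))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(withlig, f)
  back <- read_structure(f)
  expect_equal(sum(back$het), 1)
  expect_equal(sum(protein_atoms(back)$het), 0)
})
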