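plant_two_atoms <- function(d) {
  # an Arg guanidinium N and an Asp carboxylate O at distance d, plus
  # backbone scaffolding far from everything else
  at <- dplyr::bind_rows(
    atom_row(1, "A", 10, "ARG", "CA", c(0, 0, 0)),
    atom_row(2, "A", 10, "ARG", "NH1", c(0, 0, 5)),
    atom_row(3, "B", 40, "ASP", "CA", c(20, 0, 0)),
    atom_row(4, "B", 40, "ASP", "OD1", c(0, 0, 5 + d))
  )
  new_assembly(at, id = "pair")
}

test_that("typed criteria fire at and not beyond their cutoffs", {
  ct <- detect_contacts(plant_two_atoms(2.9))
  expect_setequal(ct$contact_type, c("hbond", "salt_bridge"))
  expect_equal(unique(ct$distance), 2.9, tolerance = 1e-9)
  expect_equal(unique(ct$scope), "inter_chain")

  ct2 <- detect_contacts(plant_two_atoms(4.2))
  expect_false(any(ct2$contact_type %in% c("hbond", "salt_bridge")))
})

test_that("grid contact detection equals the all-pairs oracle", {
  for (seed in c(42, 7, 99)) {
    asm <- random_toy_assembly(n_atoms = 50, seed = seed)
    got <- detect_contacts(asm)
    want <- oracle_contacts(asm)
    expect_setequal(contact_key(got), contact_key(want))
  }
})

test_that("contacts are invariant under global rigid motion", {
  asm <- random_toy_assembly(n_atoms = 50, seed = 3)
  a <- detect_contacts(asm)
  b <- detect_contacts(shift_rotate(asm))
  expect_equal(contact_key(a), contact_key(b))
  expect_equal(sort(a$distance), sort(b$distance), tolerance = 1e-9)
})

test_that("raising any cutoff only adds records", {
  asm <- random_toy_assembly(n_atoms = 60, seed = 12)
  base <- contact_key(detect_contacts(asm))
  wider <- contact_key(detect_contacts(
    asm, contact_criteria(hbond = 4.2, salt_bridge = 4.8,
                          hydrophobic = 5.5)))
  expect_true(all(base %in% wider))
})

test_that("planted oligomer contacts classify as interlock", {
  asm <- plant_contact(toy_c4(), 15, 25, 2.9)
  reg <- region_definition("binding", c(15, 15))
  rep <- detect_interlock(asm, reg)
  expect_equal(rep$classification, "interlock")
  # the same partner pair recurs in all four chains
  inter <- dplyr::filter(rep$partner_pairs, scope == "inter_chain",
                         partner_resno == 25)
  expect_equal(sort(unique(inter$region_chain)), c("A", "B", "C", "D"))
  expect_gte(length(rep$recurring_pairs), 1)
  expect_equal(length(rep$deviating_chains), 0)
})

test_that("long-range intramolecular stabilization classifies as lock", {
  # monomer: region residue 2.9 A from a residue far away in sequence
  at <- dplyr::bind_rows(
    atom_row(1, "A", 10, "ARG", "CA", c(0, 0, 0)),
    atom_row(2, "A", 10, "ARG", "NH1", c(0, 0, 5)),
    atom_row(3, "A", 160, "ASP", "CA", c(20, 0, 0)),
    atom_row(4, "A", 160, "ASP", "OD1", c(0, 0, 7.9))
  )
  mono <- new_assembly(at)
  reg <- region_definition("binding", c(10, 10))
  expect_equal(detect_interlock(mono, reg)$classification, "lock")
  # below the sequence-separation threshold it is not a lock
  at2 <- at
  at2$resno[3:4] <- 14L
  expect_equal(detect_interlock(new_assembly(at2), reg)$classification,
               "none")
  expect_error(detect_interlock(mono, region_definition("x", c(900, 901))),
               "resolves in no chain")
})

test_that("interlock reports are invariant to chain relabeling", {
  asm <- plant_contact(toy_c4(), 15, 25, 2.9)
  reg <- region_definition("binding", c(15, 15))
  a <- detect_interlock(asm, reg)
  rel <- asm
  map <- setNames(c("D", "C", "B", "A"), c("A", "B", "C", "D"))
  rel$chain <- unname(map[rel$chain])
  b <- detect_interlock(rel, reg)
  expect_equal(a$classification, b$classification)
  expect_equal(nrow(a$partner_pairs), nrow(b$partner_pairs))
  expect_equal(sort(a$recurring_pairs), sort(b$recurring_pairs))
})

test_that("in-silico truncation abolishes the planted salt bridge", {
  asm <- plant_contact(toy_c4(), 15, 25, 2.9)
  delta <- mutate_in_silico_contact_check(
    asm, data.frame(chain = "A", resno = 15, new_resid = "LEU"))
  expect_true("salt_bridge" %in% delta$contact_type)
  expect_true(all(delta$sub_resno == 15))
  # Leu keeps CB/CG, so only guanidinium-side contacts disappear
  involved <- ifelse(delta$chain_a == "A" & delta$resno_a == 15,
                     delta$atom_a, delta$atom_b)
  expect_true(all(involved %in% c("CD", "NE", "CZ", "NH1", "NH2")))

  # contact-free residue: empty delta
  none <- mutate_in_silico_contact_check(
    asm, data.frame(chain = "A", resno = 5, new_resid = "GLY"))
  expect_equal(nrow(none), 0)

  # double mutant is the union of the singles
  d1 <- mutate_in_silico_contact_check(
    asm, data.frame(chain = "A", resno = 15, new_resid = "LEU"))
  d2 <- mutate_in_silico_contact_check(
    asm, data.frame(chain = "B", resno = 25, new_resid = "LYS"))
  dd <- mutate_in_silico_contact_check(
    asm, data.frame(chain = c("A", "B"), resno = c(15, 25),
                    new_resid = c("LEU", "LYS")))
  key <- function(d) {
    sort(paste(d$chain_a, d$resno_a, d$atom_a, d$chain_b, d$resno_b,
               d$atom_b, d$contact_type, d$sub_chain, d$sub_resno))
  }
  expect_setequal(key(dd), c(key(d1), key(d2)))

  expect_error(mutate_in_silico_contact_check(
    asm, data.frame(chain = "A", resno = 15, new_resid = "XXX")),
    "unknown residue")
  expect_error(mutate_in_silico_contact_check(
    asm, data.frame(chain = "A", resno = 999, new_resid = "LEU")),
    "no residue")
})
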