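test_that("superposition recovers identity and exact rigid constructions", {
  set.seed(11)
  ref <- matrix(rnorm(30), ncol = 3)
  fit <- kabsch_fit(ref, ref)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$transform$rotation, diag(3), tolerance = 1e-9)
  expect_equal(fit$n_atoms_fit, 10)

  rot90 <- rotation_about(c(0, 0, 1), 90)
  mov <- sweep(ref %*% t(rot90), 2, c(1, 2, 3), "+")
  fit <- kabsch_fit(ref, mov)
  expect_lt(fit$rmsd, 1e-9)
  # recovered transform inverts the construction: rotation is the inverse
  expect_equal(fit$transform$rotation, t(rot90), tolerance = 1e-9)
  moved_back <- sweep(mov %*% t(fit$transform$rotation), 2,
                      fit$transform$translation, "+")
  expect_equal(moved_back, ref, tolerance = 1e-9)
})

test_that("kabsch matches the rotation-grid oracle on small point sets", {
  for (seed in 1:4) {
    set.seed(seed)
    ref <- matrix(rnorm(18), ncol = 3)
    mov <- matrix(rnorm(18), ncol = 3)
    expect_equal(kabsch_fit(ref, mov)$rmsd, oracle_min_rmsd(ref, mov),
                 tolerance = 1e-6)
  }
})

test_that("kabsch agrees with an established superposition routine", {
  set.seed(5)
  ref <- matrix(rnorm(24), ncol = 3)
  mov <- matrix(rnorm(24), ncol = 3)
  fit <- kabsch_fit(ref, mov)
  b3d <- suppressWarnings(bio3d::fit.xyz(as.vector(t(ref)),
                                         as.vector(t(mov))))
  rms_b3d <- sqrt(mean((b3d - as.vector(t(ref)))^2) * 3)
  expect_equal(fit$rmsd, rms_b3d, tolerance = 1e-6)
})

test_that("rmsd is invariant to pre-transforms and symmetric in arguments", {
  set.seed(21)
  ref <- matrix(rnorm(30), ncol = 3)
  mov <- matrix(rnorm(30), ncol = 3)
  base <- kabsch_fit(ref, mov)$rmsd
  for (k in 1:5) {
    ang <- runif(1, 0, 180); ax <- rnorm(3); sh <- rnorm(3, sd = 10)
    pre <- sweep(mov %*% t(rotation_about(ax / sqrt(sum(ax^2)), ang)),
                 2, sh, "+")
    expect_equal(kabsch_fit(ref, pre)$rmsd, base, tolerance = 1e-9)
  }
  expect_equal(kabsch_fit(mov, ref)$rmsd, base, tolerance = 1e-9)
})

test_that("degenerate and undersized inputs are handled", {
  expect_error(kabsch_fit(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
  line <- cbind(1:5, 0, 0)
  fit <- kabsch_fit(line, line * 1)
  expect_true(fit$degenerate)
  expect_lt(fit$rmsd, 1e-9)
})

test_that("displacement profile is zero for identical states", {
  asm <- toy_c4()
  chain <- chain_atoms(protein_atoms(asm), "A")
  prof <- displacement_profile(chain, chain,
                               region_definition("fit", c(1, 19)),
                               region_definition("rep", c(20, 30)))
  expect_true(all(prof$ca_disp < 1e-12))
  expect_true(all(prof$sc_disp < 1e-12))
})

test_that("hinge-rotated region displacements equal the chord formula", {
  asm <- toy_c4()
  reg <- region_definition("tip", c(20, 30))
  fitreg <- region_definition("core", c(1, 19))
  pair <- make_apo_holo_pair(asm, reg, angle = 10)
  prof <- displacement_profile(chain_atoms(protein_atoms(pair$apo), "A"),
                               chain_atoms(protein_atoms(pair$holo), "A"),
                               fitreg, reg)
  merged <- dplyr::inner_join(tidy(prof), pair$expected, by = "seq_num",
                              suffix = c("", "_exp"))
  expect_equal(merged$ca_disp, merged$ca_disp_exp, tolerance = 1e-6)
  expect_equal(merged$sc_disp, merged$sc_disp_exp, tolerance = 1e-6)
  got <- max_displacement(prof, "ca")
  expect_equal(got$max_disp, max(pair$expected$ca_disp), tolerance = 1e-6)
})

test_that("max displacement grows strictly with the hinge angle", {
  asm <- toy_c4()
  reg <- region_definition("tip", c(20, 30))
  fitreg <- region_definition("core", c(1, 19))
  maxima <- vapply(c(2, 5, 10, 20), function(a) {
    pair <- make_apo_holo_pair(asm, reg, angle = a)
    prof <- displacement_profile(chain_atoms(protein_atoms(pair$apo), "A"),
                                 chain_atoms(protein_atoms(pair$holo), "A"),
                                 fitreg, reg)
    max_displacement(prof, "ca")$max_disp
  }, 0)
  expect_true(all(diff(maxima) > 0))
})

test_that("profiles handle missing residues and empty overlap", {
  asm <- toy_c4()
  a <- chain_atoms(protein_atoms(asm), "A")
  b <- a[a$resno <= 25, ]   # truncated state
  prof <- displacement_profile(a, b, region_definition("fit", c(1, 19)),
                               region_definition("rep", c(20, 30)))
  expect_equal(attr(prof, "missing_resno"), 26:30)
  expect_warning(
    empty <- displacement_profile(a, b, region_definition("fit", c(1, 19)),
                                  region_definition("rep", c(27, 30))),
    "no residues|shares no")
  expect_equal(nrow(empty), 0)
  expect_error(max_displacement(empty, "ca"), "empty")
})

test_that("max_displacement reports value and attaining residue", {
  prof <- tibble::tibble(seq_num = 1:3, res_name = "ALA",
                         ca_disp = c(1.0, 2.5, 0.3),
                         sc_disp = c(NA, 1.1, 4.0))
  class(prof) <- c("displacement_profile", class(prof))
  m <- max_displacement(prof, "ca")
  expect_equal(m$max_disp, 2.5)
  expect_equal(m$seq_num, 2)
  expect_equal(max_displacement(prof, "sidechain")$max_disp, 4.0)
  zero <- prof
  zero$ca_disp <- 0
  expect_equal(max_displacement(zero, "ca")$max_disp, 0)
})
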