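test_that("cell volumes match closed forms", {
  expect_equal(cell_volume(unit_cell(100, 100, 100)), 1e6)
  expect_equal(cell_volume(unit_cell(50, 60, 70)), 50 * 60 * 70)
  # trigonal cell against the specialised a^2 c sin(gamma) formula
  trig <- unit_cell(138.97, 138.97, 311.62, 90, 90, 120)
  expect_equal(cell_volume(trig),
               138.97^2 * 311.62 * sin(120 * pi / 180), tolerance = 1e-12)
  expect_error(cell_volume(unit_cell(10, 10, 10, 179, 179, 179)),
               "invalid angle")
  expect_error(unit_cell(-1, 10, 10), "positive")
  expect_error(unit_cell(10, 10, 10, gamma = 181), "angles")
})

test_that("Matthews coefficient and solvent content follow the formulas", {
  m <- matthews(unit_cell(100, 100, 100), 4, 50000)
  expect_equal(m$matthews_vm, 5.0)
  m2 <- matthews(unit_cell(100, 100, 100), 4, 1e6 / (4 * 2.46))
  expect_equal(m2$matthews_vm, 2.46, tolerance = 1e-9)
  expect_equal(m2$solvent_fraction, 50.0, tolerance = 1e-9)
  # homogeneity: doubling cell volume and Z leaves V_M unchanged
  a2 <- 100 * 2^(1 / 3)
  m3 <- matthews(unit_cell(a2, a2, a2), 8, 50000)
  expect_equal(m3$matthews_vm, m$matthews_vm, tolerance = 1e-9)
  # V_M below the protein-only limit: solvent undefined
  expect_warning(m4 <- matthews(unit_cell(100, 100, 100), 4, 3e5),
                 "undefined")
  expect_true(is.na(m4$solvent_fraction))
})

test_that("sequence masses match independent references", {
  expect_equal(molar_mass_from_sequence("G"), 75.07, tolerance = 0.01)
  expect_equal(molar_mass_from_sequence("GG"), 132.12, tolerance = 0.01)
  # 50-mer frozen against an independent average-mass computation
  seq50 <- "MFPCDVENWCTHCDQQDIDVQCWEIWCWWPCICVFLQFVEWLVGEWWHNE"
  expect_equal(molar_mass_from_sequence(seq50), 6337.16, tolerance = 0.05)
  expect_error(molar_mass_from_sequence("GXZ"), "unknown")
  expect_error(molar_mass_from_sequence(""), "empty")
})

test_that("noise-free kinetics parameters are recovered exactly", {
  d <- simulate_kinetics("Hill", v_max = 10, k = 2, h = 2, noise_sd = 0)
  fit <- fit_kinetics(d, "Hill")
  est <- setNames(fit$parameters$estimate, fit$parameters$term)
  expect_equal(unname(est["v_max"]), 10, tolerance = 1e-6)
  expect_equal(unname(est["k_half"]), 2, tolerance = 1e-6)
  expect_equal(unname(est["hill_h"]), 2, tolerance = 1e-6)
  # at x = K the fitted curve sits at half of V_max, for any H
  g <- glance(fit)
  expect_equal(g$v_max * g$k^g$hill_h / (g$k^g$hill_h + g$k^g$hill_h),
               g$v_max / 2, tolerance = 1e-12)

  dm <- simulate_kinetics("MM", v_max = 7, k = 1.3, noise_sd = 0)
  fm <- fit_kinetics(dm, "MM")
  em <- setNames(fm$parameters$estimate, fm$parameters$term)
  expect_equal(unname(em["v_max"]), 7, tolerance = 1e-6)
  expect_equal(unname(em["k_m"]), 1.3, tolerance = 1e-6)
})

test_that("Hill at H = 1 reproduces the Michaelis-Menten fit", {
  d <- simulate_kinetics("MM", v_max = 9, k = 3,
                         conc = c(0.2, 0.5, 1, 2, 4, 8, 16, 32),
                         noise_sd = 0.15, seed = 4)
  mm <- fit_kinetics(d, "MM")
  hill <- fit_kinetics(d, "Hill")
  expect_lte(hill$rss, mm$rss + 1e-9)
  h <- hill$parameters$estimate[hill$parameters$term == "hill_h"]
  expect_equal(h, 1, tolerance = 0.15)
})

test_that("fits are scale covariant in velocity", {
  d <- simulate_kinetics("Hill", v_max = 10, k = 2, h = 1.7,
                         noise_sd = 0.2, seed = 9)
  f1 <- glance(fit_kinetics(d, "Hill"))
  d2 <- dplyr::mutate(d, velocity = velocity * 3.5)
  f2 <- glance(fit_kinetics(d2, "Hill"))
  expect_equal(f2$v_max, f1$v_max * 3.5, tolerance = 1e-4)
  expect_equal(f2$k, f1$k, tolerance = 1e-4)
  expect_equal(f2$hill_h, f1$hill_h, tolerance = 1e-4)
})

test_that("kinetics fitting enforces its preconditions", {
  expect_error(fit_kinetics(tibble::tibble(conc = 1:4, velocity = 1:4)),
               "at least 5")
  expect_error(fit_kinetics(tibble::tibble(conc = rep(1, 6),
                                           velocity = 1:6)), "distinct")
  expect_error(fit_kinetics(tibble::tibble(conc = c(-1, 1:5),
                                           velocity = 1:6)),
               "non-negative")
})

test_that("model comparison prefers the generating model", {
  # under the null (H = 1), MM is retained in at least 90% of replicates
  prefs <- vapply(1:200, function(s) {
    d <- simulate_kinetics("MM", v_max = 10, k = 2,
                           conc = c(0.25, 0.5, 1, 2, 4, 8, 16),
                           noise_sd = 0.3, seed = s)
    compare_kinetic_models(d)$preferred
  }, "")
  expect_gte(mean(prefs == "MM"), 0.9)

  # strongly cooperative, low-noise data select Hill
  d <- simulate_kinetics("Hill", v_max = 10, k = 2, h = 2.5,
                         noise_sd = 0.05, seed = 2)
  expect_equal(compare_kinetic_models(d)$preferred, "Hill")

  # noise-free MM data: F vanishes
  d0 <- simulate_kinetics("MM", v_max = 10, k = 2, noise_sd = 0)
  expect_lt(compare_kinetic_models(d0)$f_statistic, 1e-3)
})

test_that("noise-free Boltzmann curves return the exact melting point", {
  d <- simulate_melt(t_m = 50, slope = 2,
                     temperature = seq(20, 90, by = 1), noise_sd = 0)
  fit <- fit_melt(d)
  expect_equal(fit$t_m, 50, tolerance = 1e-5)
  expect_equal(fit$slope, 2, tolerance = 1e-4)
  expect_gt(fit$slope, 0)
  expect_true(fit$t_m >= 20 && fit$t_m <= 90)
})

test_that("melting point is invariant to additive fluorescence offsets", {
  d <- simulate_melt(t_m = 55.65, slope = 1.5, noise_sd = 0.01, seed = 6)
  t1 <- fit_melt(d)$t_m
  d2 <- dplyr::mutate(d, fluorescence = fluorescence + 100)
  expect_equal(fit_melt(d2)$t_m, t1, tolerance = 1e-9)
})

test_that("melt fitting rejects degenerate inputs", {
  flat <- tibble::tibble(temperature = seq(20, 40, by = 1),
                         fluorescence = 1)
  expect_error(fit_melt(flat), "not sigmoidal")
  d <- simulate_melt()
  expect_error(fit_melt(d[c(1:5, 5, 6:10), ]), "strictly increasing")
  expect_error(fit_melt(d[1:8, ]), "at least 10")
})

test_that("plateau normalisation resists a fluorescence spike", {
  d <- simulate_melt(t_m = 52, slope = 2, noise_sd = 0, seed = 1)
  d$fluorescence[35] <- d$fluorescence[35] * 3   # mid-curve spike
  t_plateau <- fit_melt(d, normalize = "plateau")$t_m
  expect_equal(t_plateau, 52, tolerance = 0.35)
})
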