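pair_system <- function(kind_a = "ASP", kind_b = "LYS", sep = 4) {
  s <- parse_structure(make_pair(kind_a, kind_b, sep))
  sites <- extract_ionisable_sites(s)
  list(sites = sites, W = build_interaction_matrix(sites))
}

test_that("microstate energies follow the proton-binding + interaction form", {
  rt <- 8.314462618e-3 * 298.15
  # two deprotonated acids 4 A apart: charge product (+1), energy +W(4)
  sys <- pair_system("ASP", "GLU", 4)
  expect_equal(microstate_energy(c(0, 0), 7, sys$sites, sys$W),
               pair_factor(4), tolerance = 1e-9)
  # protonated acid is neutral: Asp(1)-Lys(1) has no interaction term
  sys2 <- pair_system("ASP", "LYS", 4)
  e <- microstate_energy(c(1, 1), 5, sys2$sites, sys2$W)
  expect_equal(e, log(10) * rt * ((5 - 4.0) + (5 - 10.4)),
               tolerance = 1e-9)
  # single site, no interactions: ln10 RT (pH - pKa), zero at the pKa
  one <- extract_ionisable_sites(
    parse_structure(phstab:::make_single_residue("HIS")))
  expect_equal(microstate_energy(1, 6.3, one, NULL), 0, tolerance = 1e-12)
  expect_equal(microstate_energy(1, 8.3, one, NULL), log(10) * rt * 2,
               tolerance = 1e-9)
})

test_that("enumeration reproduces Henderson-Hasselbalch when W = 0", {
  one <- extract_ionisable_sites(
    parse_structure(phstab:::make_single_residue("ASP")))
  tr <- enumerate_titration(one, NULL, ph_grid_default())
  expect_equal(unname(tr$mean_protonation[1, tr$ph_grid == 4.0]), 0.5,
               tolerance = 1e-12)
  expect_equal(tr$mean_protonation[1, ],
               hh_protonation(4.0, tr$ph_grid), tolerance = 1e-9,
               ignore_attr = TRUE)

  # multi-site, W = 0: the partition function factorises into HH curves
  toy <- parse_structure(make_toy_domain(toy_spec(30, 3, 0)))
  sites <- extract_ionisable_sites(toy)
  tr0 <- enumerate_titration(sites, NULL, ph_grid_default())
  hh <- sapply(tr0$ph_grid, function(p) hh_protonation(sites$model_pka, p))
  expect_lt(max(abs(tr0$mean_protonation - hh)), 1e-9)
})

test_that("a favourable acid-base pair shifts both apparent pKas outward", {
  sys <- pair_system("ASP", "LYS", 4)
  tr <- enumerate_titration(sys$sites, sys$W)
  pka_asp <- apparent_pka(tr, "ASP_A1")
  pka_lys <- apparent_pka(tr, "LYS_B1")
  expect_lt(pka_asp, 4.0)
  expect_gt(pka_lys, 10.4)
})

test_that("titration results satisfy charge bookkeeping and monotonicity", {
  toy <- parse_structure(make_toy_domain(toy_spec(30, 3, 0)))
  sites <- extract_ionisable_sites(toy)
  W <- build_interaction_matrix(sites)
  tr <- enumerate_titration(sites, W, seq(0, 18, 0.5))
  # <Q> = sum(q_deprot + <x>)
  expect_lt(max(abs(tr$mean_charge -
                      colSums(sites$q_deprotonated + tr$mean_protonation))),
            1e-9)
  # thermodynamic monotonicity of the charge curve
  expect_true(all(diff(tr$mean_charge) <= 1e-9))
  # saturation plateaus 4 units beyond the model pKa range
  lo <- tr$ph_grid <= min(sites$model_pka) - 4
  hi <- tr$ph_grid >= max(sites$model_pka) + 4
  expect_true(all(tr$mean_protonation[, lo] > 0.98))
  expect_true(all(tr$mean_protonation[, hi] < 0.02))
  # enumeration refuses oversized systems
  big <- do.call(rbind, rep(list(sites), 4))
  big$site_id <- paste0("s", seq_len(nrow(big)))
  expect_error(enumerate_titration(big, NULL), "mc_titration")
})

test_that("Monte Carlo titration is seeded-deterministic and matches enumeration", {
  toy <- parse_structure(make_toy_domain(toy_spec(40, 4, 1)))
  sites <- extract_ionisable_sites(toy)   # 10 sites
  W <- build_interaction_matrix(sites)
  grid <- ph_grid_default()
  mc1 <- mc_titration(sites, W, grid, sweeps = 1e5, burn_in = 1e4,
                      seed = 99)
  mc2 <- mc_titration(sites, W, grid, sweeps = 1e5, burn_in = 1e4,
                      seed = 99)
  expect_identical(mc1$mean_protonation, mc2$mean_protonation)
  expect_identical(mc1$mean_charge, mc2$mean_charge)

  ex <- enumerate_titration(sites, W, grid)
  expect_lt(max(abs(mc1$mean_protonation - ex$mean_protonation)), 0.02)

  # W = 0 sampling agrees with the closed form
  mc0 <- mc_titration(sites, NULL, grid, sweeps = 2e4, burn_in = 2e3,
                      seed = 5)
  hh <- sapply(grid, function(p) hh_protonation(sites$model_pka, p))
  expect_lt(max(abs(mc0$mean_protonation - hh)), 0.02)
})

test_that("strongly coupled pairs sample correctly through paired flips", {
  # unscreened contact pair: W(3) ~ 5.9 kJ/mol > 2RT, activating the
  # pair-flip move set alongside single-site flips
  s <- parse_structure(make_pair("ASP", "LYS", 3))
  sites <- extract_ionisable_sites(s)
  W <- build_interaction_matrix(sites, electro_params(ionic_strength = 0))
  rt <- 8.314462618e-3 * 298.15
  expect_gt(max(W$W), 2 * rt)
  grid <- ph_grid_default()
  ex <- enumerate_titration(sites, W, grid)
  mc <- mc_titration(sites, W, grid, sweeps = 1e5, burn_in = 1e4,
                     seed = 3)
  expect_lt(max(abs(mc$mean_protonation - ex$mean_protonation)), 0.02)
  expect_lt(max(abs(mc$mean_interaction_energy -
                      ex$mean_interaction_energy)), 0.1)
  # alkaline limit: both acids deprotonated in an Asp-Glu pair leaves
  # exactly the repulsive pair energy
  s2 <- parse_structure(make_pair("ASP", "GLU", 4))
  sites2 <- extract_ionisable_sites(s2)
  W2 <- build_interaction_matrix(sites2)
  ex2 <- enumerate_titration(sites2, W2, seq(10, 14, 1))
  expect_equal(ex2$mean_interaction_energy[5], pair_factor(4),
               tolerance = 1e-6)
})

test_that("apparent pKa interpolation flags missing and multiple crossings", {
  one <- extract_ionisable_sites(
    parse_structure(phstab:::make_single_residue("HIS")))
  tr <- enumerate_titration(one, NULL)
  expect_equal(apparent_pka(tr, 1), 6.3, tolerance = 0.01)

  short <- enumerate_titration(one, NULL, seq(10, 14, 0.5))
  expect_warning(v <- apparent_pka(short, 1), "never crosses")
  expect_true(is.na(v))

  # synthetic non-monotone curve: first crossing used, warning raised
  fake <- tr
  fake$mean_protonation[1, ] <- 0.5 +
    0.4 * cos(seq_along(tr$ph_grid) / 3)
  expect_warning(v2 <- apparent_pka(fake, 1), "first used")
  first <- which(diff(sign(fake$mean_protonation[1, ] - 0.5)) != 0)[1]
  expect_true(v2 >= tr$ph_grid[first] && v2 <= tr$ph_grid[first + 1])
})
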