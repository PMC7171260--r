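test_that("no interactions means no pH-dependent stability contribution", {
  toy <- parse_structure(make_toy_domain(toy_spec(30, 3, 0)))
  sites <- extract_ionisable_sites(toy)
  dg <- folded_state_energy(sites, NULL)
  expect_lt(max(abs(dg$dG_kJ)), 1e-9)
})

test_that("a salt bridge stabilises at neutral pH and is lost in acid", {
  s <- parse_structure(make_pair("ASP", "LYS", 4))
  sites <- extract_ionisable_sites(s)
  W <- build_interaction_matrix(sites)
  dg <- folded_state_energy(sites, W)
  g <- function(ph) dg$dG_kJ[dg$pH == ph]
  expect_lt(g(7), 0)
  expect_lt(g(7), g(2))
  expect_lt(abs(g(2)), 0.1)   # acid neutralised: pair term gone
})

test_that("a like-charge acid pair destabilises until acid relieves it", {
  s <- parse_structure(make_pair("ASP", "GLU", 4))
  sites <- extract_ionisable_sites(s)
  W <- build_interaction_matrix(sites)
  dg <- folded_state_energy(sites, W)
  g <- function(ph) dg$dG_kJ[dg$pH == ph]
  expect_gt(g(7), 0)
  expect_lt(g(2), g(7))
  expect_lt(abs(g(2)), 0.1)
})

test_that("the pH-derivative of dG equals the proton-binding difference", {
  # Wyman linkage on a fine grid, exact method
  toy <- parse_structure(make_toy_domain(toy_spec(30, 3, 0)))
  sites <- extract_ionisable_sites(toy)
  W <- build_interaction_matrix(sites)
  grid <- seq(1, 14, 0.05)
  dg <- folded_state_energy(sites, W, grid)$dG_kJ
  tr <- exact_core <- enumerate_titration(sites, W, grid)
  x_fold <- colSums(tr$mean_protonation)
  x_unf <- sapply(grid, function(p) sum(hh_protonation(sites$model_pka, p)))
  rt <- 8.314462618e-3 * 298.15
  pred <- log(10) * rt * (x_fold - x_unf)
  num <- (dg[-(1:2)] - dg[1:(length(dg) - 2)]) / (2 * 0.05)
  keep <- abs(pred[-c(1, length(pred))]) > 0.05  # avoid 0/0 at plateaus
  rel <- abs(num[keep] - pred[-c(1, length(pred))][keep]) /
    abs(pred[-c(1, length(pred))][keep])
  expect_lt(max(rel), 0.02)
})

test_that("the anchored Monte Carlo free-energy path matches enumeration", {
  toy <- parse_structure(make_toy_domain(toy_spec(60, 6, 0)))   # 12 sites
  sites <- extract_ionisable_sites(toy)
  W <- build_interaction_matrix(sites)
  grid <- ph_grid_default()
  ex <- folded_state_energy(sites, W, grid, method = "exact")
  mc <- folded_state_energy(sites, W, grid, method = "mc",
                            sweeps = 1e5, burn_in = 1e4, seed = 17)
  n_aa <- n_residues(toy)
  expect_lt(max(abs(ex$dG_kJ - mc$dG_kJ)) / n_aa, 0.05)
  expect_error(folded_state_energy(sites, W, grid, method = "mc"),
               "seed")
})

test_that("a neutral-pH-optimised surface shows the expected stability window", {
  toy <- parse_structure(make_toy_domain(toy_spec(60, 6, 0)))
  sp <- stability_profile(toy)
  p <- sp$profile
  ph_min <- p$pH[which.min(p$dG_per_aa)]
  expect_gte(ph_min, 5); expect_lte(ph_min, 9)
  # acids neutralised: like-charge repulsion leaves net destabilisation
  expect_true(all(p$dG_per_aa[p$pH <= 2.5] > 0))
  expect_gt(dg_at(p, 2), 0)

  # swapping basic partners for polar stubs flattens the pH-dependence
  swap <- parse_structure(make_toy_domain(toy_spec(60, 0, 6)))
  sp2 <- stability_profile(swap)
  spread1 <- abs(dg_at(p, 2) - dg_at(p, 7))
  spread2 <- abs(dg_at(sp2$profile, 2) - dg_at(sp2$profile, 7))
  expect_lt(spread2, spread1)
})

test_that("profiles handle edge structures and scale with system size", {
  # no ionisable residues: all-zero profile with a warning
  gly <- parse_structure(polygly_pdb_text(5))
  expect_warning(sp <- stability_profile(gly), "no ionisable")
  expect_true(all(sp$profile$dG_per_aa == 0))
  expect_true(all(sp$profile$charge_per_aa == 0))

  # a far-translated duplicate leaves the per-residue profile unchanged
  toy <- parse_structure(make_toy_domain(toy_spec(30, 3, 0)))
  sp1 <- stability_profile(toy)
  sp2 <- stability_profile(duplicate_far(toy, 1000))
  expect_equal(sp2$n_residues, 2 * sp1$n_residues)
  expect_equal(sp2$profile$dG_per_aa, sp1$profile$dG_per_aa,
               tolerance = 1e-4)
})

test_that("ensemble summaries compute pointwise means and spreads", {
  toy <- parse_structure(make_toy_domain(toy_spec(30, 3, 0)))
  sp <- stability_profile(toy)
  ens <- ensemble_profile(list(sp, sp, sp))
  expect_equal(ens$dG_mean, sp$profile$dG_per_aa)
  expect_true(all(ens$dG_sd == 0))

  # hand-computed mean/SD on three small synthetic profiles
  mk <- function(v) phstab:::new_stability_profile(
    tibble::tibble(pH = 1:3, dG_per_aa = v, charge_per_aa = -v),
    10, 2, "exact", electro_params(), NULL)
  ens2 <- ensemble_profile(list(mk(c(1, 2, 3)), mk(c(3, 2, 1)),
                                mk(c(2, 2, 2))))
  expect_equal(ens2$dG_mean, c(2, 2, 2))
  expect_equal(ens2$dG_sd, c(1, 0, 1))

  expect_warning(one <- ensemble_profile(list(sp)), "single")
  expect_true(all(one$dG_sd == 0))
  bad <- mk(c(1, 2, 3)); bad$profile$pH <- 4:6
  expect_error(ensemble_profile(list(mk(c(1, 2, 3)), bad)), "grid")
})

test_that("heat maps re-screen the interaction matrix per ionic strength", {
  one <- parse_structure(phstab:::make_single_residue("ASP"))
  hm0 <- heat_map(one, seq(2, 10, 1), c(0.01, 0.15))
  expect_lt(max(abs(hm0$dG_per_aa)), 1e-9)

  toy <- parse_structure(make_toy_domain(toy_spec(30, 3, 0)))
  grid <- seq(1, 10, 0.5)
  igrid <- c(0.01, 0.05, 0.15, 0.5)
  hm <- heat_map(toy, grid, igrid)
  at7 <- hm$dG_per_aa[which.min(abs(grid - 7)), ]
  expect_true(all(diff(abs(at7)) < 0))   # screening weakens stabilisation

  sp <- stability_profile(toy, electro_params(ionic_strength = 0.15),
                          ph_grid = grid)
  expect_equal(hm$dG_per_aa[, 3], sp$profile$dG_per_aa,
               tolerance = 1e-9, ignore_attr = TRUE)
})
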