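#' pH-dependent electrostatic folding free energy
#'
#' dG(pH) = G_fold(pH) - G_unf(pH), the contribution of ionisable-group
#' interactions to folded-state stability. The unfolded reference titrates
#' every site independently at its model pKa (no interactions), with the
#' closed-form free energy -RT sum_i ln(1 + 10^(pKa_i - pH)). The folded
#' state uses the screened interaction matrix: exactly, by enumeration over
#' microstates (up to 20 sites), or by Monte Carlo. The Monte Carlo path
#' anchors dG at pH = max(model pKa) + 6, where the fully deprotonated
#' microstate dominates and dG equals the deprotonated-charge interaction
#' energy, then integrates the proton-binding difference
#' d(dG)/dpH = ln10 RT (<X>_fold - <X>_unf) down the grid (trapezoid).
#'
#' @inheritParams enumerate_titration
#' @param method `"auto"` (exact up to 20 sites, else mc), `"exact"` or
#'   `"mc"`.
#' @param sweeps,burn_in,seed Monte Carlo settings (see [mc_titration()]).
#' @return Tibble with columns `pH` and `dG_kJ` (kJ/mol; negative =
#'   stabilising).
#' @export
#' @examples
#' s <- parse_structure(make_pair("ASP", "LYS", 4))
#' sites <- extract_ionisable_sites(s)
#' W <- build_interaction_matrix(sites)
#' folded_state_energy(sites, W)   # stabilised near neutral pH
folded_state_energy <- function(sites, W = NULL,
                                ph_grid = ph_grid_default(),
                                method = c("auto", "exact", "mc"),
                                sweeps = 1e5, burn_in = 1e4, seed = NULL,
                                temperature = NULL) {
  method <- match.arg(method)
  ti <- titration_inputs(sites, W)
  temperature <- temperature %||% ti$temperature
  rt <- rt_kj(temperature)
  if (method == "auto") method <- if (ti$n <= 20L) "exact" else "mc"

  g_unf <- function(ph) {
    -rt * vapply(ph, function(p) sum(log1p(10^(ti$pka - p))), 0)
  }

  if (method == "exact") {
    core <- exact_titration(sites, W, ph_grid, temperature)
    dg <- core$G - g_unf(ph_grid)
  } else {
    if (is.null(seed)) abort("the Monte Carlo path requires a seed")
    anchor <- max(max(ti$pka) + 6, max(ph_grid))
    step <- if (length(ph_grid) > 1) min(diff(sort(ph_grid))) else 0.25
    ext <- sort(unique(c(ph_grid,
                         if (anchor > max(ph_grid))
                           seq(max(ph_grid), anchor, by = step),
                         anchor)))
    tr <- mc_titration(sites, W, ext, sweeps = sweeps, burn_in = burn_in,
                       seed = seed, temperature = temperature)
    x_fold <- colSums(tr$mean_protonation)
    x_unf <- vapply(ext, function(p) sum(1 / (1 + 10^(p - ti$pka))), 0)
    slope <- LN10 * rt * (x_fold - x_unf)
    # at the anchor the fully deprotonated state dominates both states
    dg_anchor <- sum(ti$W[upper.tri(ti$W)] *
                       (ti$qd %o% ti$qd)[upper.tri(ti$W)])
    m <- length(ext)
    dg_ext <- numeric(m)
    dg_ext[m] <- dg_anchor
    for (k in (m - 1):1) {
      dg_ext[k] <- dg_ext[k + 1] -
        (ext[k + 1] - ext[k]) * (slope[k] + slope[k + 1]) / 2
    }
    dg <- dg_ext[match(ph_grid, ext)]
  }
  tibble(pH = ph_grid, dG_kJ = dg)
}

#' Stability profile of a structure
#'
#' The full pipeline: locate ionisable sites, build the screened interaction
#' matrix, titrate, and report the pH-dependent electrostatic contribution
#' to folded-state stability and the net charge, both normalised per amino
#' acid (residues with a CA atom) so different-sized proteins compare
#' directly.
#'
#' @param s A `phs_structure`.
#' @param params [electro_params()].
#' @param config [site_config()].
#' @param ph_grid pH values.
#' @param method,sweeps,burn_in,seed See [folded_state_energy()].
#' @param chains Optional chain subset.
#' @return A `stability_profile`: `profile` tibble (`pH`, `dG_per_aa`
#'   kJ/mol/residue, `charge_per_aa` e/residue), `n_residues`, `n_sites`,
#'   `method`, `params`, `mc_meta`.
#' @export
#' @examples
#' toy <- parse_structure(make_toy_domain(toy_spec(n_residues = 30,
#'                                                 n_salt_bridges = 3)))
#' sp <- stability_profile(toy)
#' tidy(sp)
stability_profile <- function(s, params = electro_params(),
                              config = site_config(),
                              ph_grid = ph_grid_default(),
                              method = c("auto", "exact", "mc"),
                              sweeps = 1e5, burn_in = 1e4, seed = NULL,
                              chains = NULL) {
  method <- match.arg(method)
  nres <- n_residues(s, chains)
  if (nres == 0L) abort("structure has no residues with CA atoms")
  sites <- extract_ionisable_sites(s, config, chains)

  if (nrow(sites) == 0L) {
    warn("no ionisable sites: returning an all-zero profile")
    prof <- tibble(pH = ph_grid, dG_per_aa = 0, charge_per_aa = 0)
    return(new_stability_profile(prof, nres, 0L, "exact", params, NULL))
  }

  W <- build_interaction_matrix(sites, params)
  used <- if (method == "auto") {
    if (nrow(sites) <= 20L) "exact" else "mc"
  } else method
  dg <- folded_state_energy(sites, W, ph_grid, method = used,
                            sweeps = sweeps, burn_in = burn_in, seed = seed)
  tr <- if (used == "exact") {
    enumerate_titration(sites, W, ph_grid)
  } else {
    mc_titration(sites, W, ph_grid, sweeps = sweeps, burn_in = burn_in,
                 seed = seed)
  }
  prof <- tibble(pH = ph_grid,
                 dG_per_aa = dg$dG_kJ / nres,
                 charge_per_aa = tr$mean_charge / nres)
  new_stability_profile(prof, nres, nrow(sites), used, params, tr$mc_meta)
}

new_stability_profile <- function(profile, n_residues, n_sites, method,
                                  params, mc_meta) {
  structure(list(profile = profile, n_residues = n_residues,
                 n_sites = n_sites, method = method, params = params,
                 mc_meta = mc_meta), class = "stability_profile")
}

#' @export
print.stability_profile <- function(x, ...) {
  p <- x$profile
  cat(sprintf("<stability_profile> %d residues, %d sites, %s method\n",
              x$n_residues, x$n_sites, x$method))
  cat(sprintf("  dG/aa at pH 7: %.4g kJ/mol; min %.4g at pH %.2f\n",
              p$dG_per_aa[which.min(abs(p$pH - 7))],
              min(p$dG_per_aa), p$pH[which.min(p$dG_per_aa)]))
  invisible(x)
}

#' Pointwise mean and spread of stability profiles
#'
#' Ensemble summary over a set of profiles on an identical pH grid (e.g. a
#' dataset of domains of one type): pointwise mean and sample standard
#' deviation (n - 1 denominator).
#'
#' @param profiles List of `stability_profile` objects.
#' @return Tibble with `pH`, `dG_mean`, `dG_sd`, `charge_mean`, `charge_sd`
#'   and `n_profiles`. A single profile yields SD 0 and a warning.
#' @export
ensemble_profile <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  grids <- lapply(profiles, function(p) p$profile$pH)
  if (!all(vapply(grids, identical, TRUE, grids[[1]])))
    abort("profiles must share an identical pH grid")
  n <- length(profiles)
  if (n == 1L) warn("single profile: SD reported as 0")
  dg <- vapply(profiles, function(p) p$profile$dG_per_aa,
               numeric(length(grids[[1]])))
  ch <- vapply(profiles, function(p) p$profile$charge_per_aa,
               numeric(length(grids[[1]])))
  dg <- matrix(dg, ncol = n); ch <- matrix(ch, ncol = n)
  sd0 <- function(m) if (n == 1L) rep(0, nrow(m)) else apply(m, 1, sd)
  tibble(pH = grids[[1]],
         dG_mean = rowMeans(dg), dG_sd = sd0(dg),
         charge_mean = rowMeans(ch), charge_sd = sd0(ch),
         n_profiles = n)
}

#' pH x ionic-strength stability heat map
#'
#' Re-runs the stability profile at each ionic strength (the interaction
#' matrix is rebuilt each time, since screening depends on the Debye
#' length).
#'
#' @inheritParams stability_profile
#' @param ionic_grid Ionic strengths, mol/L. Default: 10 log-spaced points
#'   from 0.001 to 0.5 M.
#' @param seed Seed used for every Monte Carlo run (fixed across the grid).
#' @return A `stability_heatmap`: `ph_grid`, `ionic_grid`, `dG_per_aa`
#'   matrix (rows = pH, columns = ionic strength), `n_residues`, `params`.
#' @export
heat_map <- function(s, ph_grid = ph_grid_default(),
                     ionic_grid = 10^seq(log10(0.001), log10(0.5),
                                         length.out = 10),
                     params = electro_params(), config = site_config(),
                     method = c("auto", "exact", "mc"),
                     sweeps = 1e5, burn_in = 1e4, seed = NULL,
                     chains = NULL) {
  stopifnot(length(ph_grid) >= 1, length(ionic_grid) >= 1)
  method <- match.arg(method)
  cols <- lapply(ionic_grid, function(I) {
    p <- electro_params(params$epsilon_r, I, params$temperature)
    stability_profile(s, p, config, ph_grid, method = method,
                      sweeps = sweeps, burn_in = burn_in, seed = seed,
                      chains = chains)$profile$dG_per_aa
  })
  m <- do.call(cbind, cols)
  dimnames(m) <- list(ph_grid, signif(ionic_grid, 4))
  structure(list(ph_grid = ph_grid, ionic_grid = ionic_grid,
                 dG_per_aa = m, n_residues = n_residues(s, chains),
                 params = params),
            class = "stability_heatmap")
}

#' @export
print.stability_heatmap <- function(x, ...) {
  cat(sprintf("<stability_heatmap> %d pH x %d ionic-strength points\n",
              length(x$ph_grid), length(x$ionic_grid)))
  invisible(x)
}

#' Write a stability profile to CSV
#'
#' @param sp A `stability_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(sp, path) {
  out <- sp$profile
  names(out) <- c("pH", "dG_per_aa_kJ_mol", "charge_per_aa_e")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
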