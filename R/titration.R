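#' Default pH grid
#'
#' pH 1 to 14 in steps of 0.25, the range over which ionisation states of
#' the common titratable groups are traversed.
#'
#' @param from,to,by Grid limits and step.
#' @return Numeric vector.
#' @export
ph_grid_default <- function(from = 1, to = 14, by = 0.25) seq(from, to, by = by)

# normalise sites + W into the vectors the samplers need
titration_inputs <- function(sites, W) {
  if (inherits(W, "interaction_matrix")) {
    stopifnot(identical(W$site_ids, sites$site_id))
    temperature <- W$params$temperature
    W <- W$W
  } else {
    temperature <- 298.15
  }
  n <- nrow(sites)
  if (is.null(W)) W <- matrix(0, n, n)
  stopifnot(nrow(W) == n, ncol(W) == n)
  list(n = n, pka = sites$model_pka, qd = sites$q_deprotonated,
       W = unname(as.matrix(W)), ids = sites$site_id,
       temperature = temperature)
}

#' Energy of a protonation microstate
#'
#' E(x, pH) = ln(10) RT sum_i x_i (pH - pKa_i) + sum_(i<j) W_ij q_i q_j,
#' with q_i = q_deprotonated_i + x_i. The first term is the proton-binding
#' free energy relative to the fully deprotonated state; the second the
#' screened Coulomb interaction energy.
#'
#' @param x Binary vector (1 = protonated), length matching `sites`.
#' @param pH pH value.
#' @param sites Site tibble ([extract_ionisable_sites()]).
#' @param W Interaction matrix ([build_interaction_matrix()]) or plain
#'   numeric matrix in kJ/mol; `NULL` for no interactions.
#' @param temperature K; taken from `W`'s parameters when available.
#' @return Energy in kJ/mol.
#' @export
microstate_energy <- function(x, pH, sites, W = NULL, temperature = NULL) {
  ti <- titration_inputs(sites, W)
  temperature <- temperature %||% ti$temperature
  stopifnot(length(x) == ti$n, all(x %in% c(0, 1)))
  rt <- rt_kj(temperature)
  q <- ti$qd + x
  LN10 * rt * sum(x * (pH - ti$pka)) +
    sum(ti$W[upper.tri(ti$W)] * (q %o% q)[upper.tri(ti$W)])
}

# Exact Boltzmann averages over all 2^N microstates; also returns the
# folded-state free energy G(pH) = -RT log Z relative to the fully
# deprotonated, non-interacting reference.
exact_titration <- function(sites, W, ph_grid, temperature = NULL) {
  ti <- titration_inputs(sites, W)
  temperature <- temperature %||% ti$temperature
  if (ti$n > 20L)
    abort("exact enumeration is limited to 20 sites; use mc_titration()")
  rt <- rt_kj(temperature)

  X <- as.matrix(expand.grid(rep(list(c(0, 1)), ti$n)))
  colnames(X) <- NULL
  Qs <- sweep(X, 2, ti$qd, "+")
  Eint <- rowSums((Qs %*% ti$W) * Qs) / 2
  a <- drop(X %*% ti$pka)          # sum_i x_i pKa_i
  np <- rowSums(X)                 # protons bound
  Qtot <- rowSums(Qs)

  P <- length(ph_grid)
  mean_prot <- matrix(NA_real_, ti$n, P,
                      dimnames = list(ti$ids, NULL))
  mean_charge <- mean_eint <- G <- numeric(P)
  for (p in seq_len(P)) {
    E <- LN10 * rt * (ph_grid[p] * np - a) + Eint
    m <- min(E)
    wts <- exp(-(E - m) / rt)
    Z <- sum(wts)
    wts <- wts / Z
    mean_prot[, p] <- drop(crossprod(X, wts))
    mean_charge[p] <- sum(Qtot * wts)
    mean_eint[p] <- sum(Eint * wts)
    G[p] <- m - rt * log(Z)
  }
  list(ph_grid = ph_grid, mean_protonation = mean_prot,
       mean_charge = mean_charge, mean_interaction_energy = mean_eint,
       G = G, temperature = temperature)
}

new_titration_result <- function(core, sites, method, mc_meta = NULL) {
  structure(list(
    ph_grid = core$ph_grid,
    mean_protonation = core$mean_protonation,
    mean_charge = core$mean_charge,
    mean_interaction_energy = core$mean_interaction_energy,
    method = method, mc_meta = mc_meta,
    site_ids = rownames(core$mean_protonation),
    sites = sites, temperature = core$temperature
  ), class = "titration_result")
}

#' Exact titration by microstate enumeration
#'
#' Boltzmann averages over all 2^N protonation microstates at each pH.
#' Limited to 20 sites; beyond that use [mc_titration()].
#'
#' @inheritParams microstate_energy
#' @param ph_grid pH values ([ph_grid_default()]).
#' @return A `titration_result` with per-site mean protonation, total mean
#'   charge (e) and mean interaction energy (kJ/mol) on the pH grid.
#' @export
#' @examples
#' s <- parse_structure(make_pair("ASP", "LYS", 4))
#' sites <- extract_ionisable_sites(s)
#' tr <- enumerate_titration(sites, build_interaction_matrix(sites))
#' apparent_pka(tr, 1)   # below the Asp model pKa: the pair stabilises
enumerate_titration <- function(sites, W = NULL,
                                ph_grid = ph_grid_default(),
                                temperature = NULL) {
  core <- exact_titration(sites, W, ph_grid, temperature)
  new_titration_result(core, sites, "exact")
}

#' Metropolis Monte Carlo titration
#'
#' Samples protonation microstates at each pH with single-site flips plus
#' paired flips of strongly coupled site pairs (screened interaction factor
#' above 2 RT), one independent chain per pH value. Reproducible given
#' `seed`.
#'
#' @inheritParams enumerate_titration
#' @param sweeps Post-burn-in sweeps; one sweep is N single-site attempts
#'   plus N/2 pair attempts.
#' @param burn_in Discarded initial sweeps.
#' @param seed Integer seed (required).
#' @return A `titration_result` with `method = "mc"` and `mc_meta`.
#' @export
mc_titration <- function(sites, W = NULL, ph_grid = ph_grid_default(),
                         sweeps = 1e5, burn_in = 1e4, seed,
                         temperature = NULL) {
  if (missing(seed)) abort("mc_titration() requires a seed")
  if (sweeps < 1 || burn_in < 1) abort("sweeps and burn_in must be >= 1")
  ti <- titration_inputs(sites, W)
  temperature <- temperature %||% ti$temperature
  rt <- rt_kj(temperature)

  coupled <- which(ti$W > 2 * rt & upper.tri(ti$W), arr.ind = TRUE)
  set.seed(seed)
  res <- mc_titrate_cpp(ti$pka, ti$qd, ti$W, ph_grid,
                        as.integer(sweeps), as.integer(burn_in), rt,
                        coupled - 1L)
  rownames(res$mean_protonation) <- ti$ids
  core <- list(ph_grid = ph_grid, mean_protonation = res$mean_protonation,
               mean_charge = drop(res$mean_charge),
               mean_interaction_energy = drop(res$mean_interaction_energy),
               temperature = temperature)
  new_titration_result(core, sites, "mc",
                       mc_meta = list(sweeps = sweeps, burn_in = burn_in,
                                      seed = seed))
}

#' @export
print.titration_result <- function(x, ...) {
  cat(sprintf("<titration_result> %d sites, pH %.2g..%.2g (%d points), %s\n",
              length(x$site_ids), min(x$ph_grid), max(x$ph_grid),
              length(x$ph_grid), x$method))
  if (x$method == "mc")
    cat(sprintf("  sweeps %g, burn-in %g, seed %d\n", x$mc_meta$sweeps,
                x$mc_meta$burn_in, x$mc_meta$seed))
  invisible(x)
}

#' Apparent pKa of a site
#'
#' The pH at which the site is half-protonated, by linear interpolation on
#' the titration grid. If the per-site curve crosses 0.5 more than once the
#' first crossing (lowest pH) is used and a warning notes the others; with
#' no crossing in the grid, `NA` is returned with a warning.
#'
#' @param tr A `titration_result`.
#' @param site Site index or site id.
#' @return pH of half-protonation, or `NA`.
#' @export
apparent_pka <- function(tr, site) {
  if (is.character(site)) site <- match(site, tr$site_ids)
  curve <- tr$mean_protonation[site, ]
  s <- curve - 0.5
  cross <- which(s[-length(s)] * s[-1] <= 0 & s[-length(s)] != s[-1])
  exact0 <- which(s == 0)
  if (length(exact0)) return(tr$ph_grid[exact0[1]])
  if (length(cross) == 0L) {
    warn(sprintf("site %s never crosses half-protonation on the grid",
                 tr$site_ids[site]))
    return(NA_real_)
  }
  if (length(cross) > 1L)
    warn(sprintf("site %s crosses half-protonation %d times; first used",
                 tr$site_ids[site], length(cross)))
  k <- cross[1]
  tr$ph_grid[k] + (0.5 - curve[k]) * (tr$ph_grid[k + 1] - tr$ph_grid[k]) /
    (curve[k + 1] - curve[k])
}

#' Write a titration result to CSV
#'
#' Rows are pH values; columns the per-site mean protonation plus the total
#' mean charge.
#'
#' @param tr A `titration_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(tr, path) {
  out <- data.frame(pH = tr$ph_grid, t(tr$mean_protonation),
                    total_charge_e = tr$mean_charge, check.names = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
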