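#' Electrostatic model parameters
#'
#' Uniform-dielectric Debye-Hueckel parameters: water-like relative
#' dielectric 78.4, ionic strength 0.15 M and 298.15 K by default.
#'
#' @param epsilon_r Relative dielectric constant (> 1).
#' @param ionic_strength Ionic strength, mol/L (>= 0).
#' @param temperature Temperature, K (> 0).
#' @return An `electro_params` list.
#' @export
electro_params <- function(epsilon_r = 78.4, ionic_strength = 0.15,
                           temperature = 298.15) {
  if (epsilon_r <= 1) abort("epsilon_r must exceed 1")
  if (ionic_strength < 0) abort("ionic_strength must be >= 0")
  if (temperature <= 0) abort("temperature must be positive")
  structure(list(epsilon_r = epsilon_r, ionic_strength = ionic_strength,
                 temperature = temperature), class = "electro_params")
}

#' Inverse Debye screening length
#'
#' kappa = sqrt(I)/3.04 per Angstrom in water at 298.15 K, with the full
#' kappa proportional to sqrt(I / (epsilon_r * T)) dependence.
#'
#' @param params An [electro_params()].
#' @return kappa in 1/Angstrom.
#' @export
#' @examples
#' debye_kappa(electro_params())          # ~0.1274 at 0.15 M
#' debye_kappa(electro_params(ionic_strength = 0))
debye_kappa <- function(params = electro_params()) {
  sqrt(params$ionic_strength) / 3.04 *
    sqrt((78.4 * 298.15) / (params$epsilon_r * params$temperature))
}

#' Screened Coulomb interaction factor for a unit-charge pair
#'
#' W(r) = (1389.35 / (epsilon_r * r)) * exp(-kappa r) kJ/mol, where
#' 1389.35 kJ A/mol = e^2 N_A / (4 pi eps0). Distances below 2 A are
#' clamped to 2 A with a warning (contact-distance guard); the sign of an
#' interaction enters through the charge product, so the factor itself is
#' positive.
#'
#' @param r Distance(s) in Angstrom, > 0.
#' @param params An [electro_params()].
#' @return kJ/mol per unit-charge pair, same length as `r`.
#' @export
#' @examples
#' pair_factor(4)    # ~2.66 kJ/mol at default parameters
pair_factor <- function(r, params = electro_params()) {
  if (any(r <= 0)) abort("distances must be positive")
  if (any(r < 2)) {
    warn("distances below 2 A clamped to the 2 A contact minimum")
    r <- pmax(r, 2)
  }
  kappa <- debye_kappa(params)
  COULOMB_KJ_A / (params$epsilon_r * r) * exp(-kappa * r)
}

#' Pairwise interaction matrix between ionisable sites
#'
#' Symmetric matrix of screened-Coulomb geometry factors, kJ/mol per
#' unit-charge pair, zero diagonal.
#'
#' @param sites Site tibble from [extract_ionisable_sites()].
#' @param params An [electro_params()].
#' @return An `interaction_matrix`: list with `site_ids`, `W` (N x N) and
#'   `params`.
#' @export
build_interaction_matrix <- function(sites, params = electro_params()) {
  n <- nrow(sites)
  if (n < 1L) abort("at least one site is required")
  xyz <- as.matrix(sites[, c("x", "y", "z")])
  W <- matrix(0, n, n, dimnames = list(sites$site_id, sites$site_id))
  if (n > 1L) {
    d <- as.matrix(stats::dist(xyz))
    coincident <- which(d < 1e-9 & upper.tri(d), arr.ind = TRUE)
    if (nrow(coincident) > 0L) {
      abort(sprintf("coincident site centres: %s and %s",
                    sites$site_id[coincident[1, 1]],
                    sites$site_id[coincident[1, 2]]))
    }
    off <- upper.tri(d)
    W[off] <- pair_factor(d[off], params)
    W <- W + t(W)
  }
  structure(list(site_ids = sites$site_id, W = W, params = params),
            class = "interaction_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf(
    "<interaction_matrix> %d sites, eps_r %.1f, I %.3g M, T %.2f K\n",
    length(x$site_ids), x$params$epsilon_r, x$params$ionic_strength,
    x$params$temperature))
  if (length(x$site_ids) > 1) {
    off <- x$W[upper.tri(x$W)]
    cat(sprintf("  off-diagonal range %.4g .. %.4g kJ/mol\n",
                min(off), max(off)))
  }
  invisible(x)
}

#' Write an interaction matrix to CSV
#'
#' @param im An `interaction_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interaction_csv <- function(im, path) {
  write.csv(as.data.frame(im$W), path, row.names = TRUE, quote = FALSE)
  invisible(path)
}
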