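#' Tidy a titration result
#'
#' @param x A `titration_result`.
#' @param ... Unused.
#' @return Long tibble: `pH`, `site_id`, `protonation`.
#' @export
tidy.titration_result <- function(x, ...) {
  m <- x$mean_protonation
  tibble(pH = rep(x$ph_grid, each = nrow(m)),
         site_id = rep(rownames(m), ncol(m)),
         protonation = as.vector(m))
}

#' @rdname tidy.titration_result
#' @export
glance.titration_result <- function(x, ...) {
  tibble(n_sites = length(x$site_ids), method = x$method,
         ph_min = min(x$ph_grid), ph_max = max(x$ph_grid),
         sweeps = x$mc_meta$sweeps %||% NA_real_,
         burn_in = x$mc_meta$burn_in %||% NA_real_,
         seed = x$mc_meta$seed %||% NA_integer_)
}

#' @rdname tidy.titration_result
#' @param object A `titration_result`.
#' @export
autoplot.titration_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$pH, .data$protonation,
                                  colour = .data$site_id)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "mean protonation", colour = "site") +
    ggplot2::theme_minimal()
}

#' Tidy a stability profile
#'
#' @param x A `stability_profile`.
#' @param ... Unused.
#' @return Tibble: `pH`, `dG_per_aa` (kJ/mol/residue), `charge_per_aa` (e).
#' @export
tidy.stability_profile <- function(x, ...) x$profile

#' @rdname tidy.stability_profile
#' @export
glance.stability_profile <- function(x, ...) {
  p <- x$profile
  tibble(n_residues = x$n_residues, n_sites = x$n_sites,
         method = x$method,
         dG_per_aa_pH7 = p$dG_per_aa[which.min(abs(p$pH - 7))],
         dG_per_aa_min = min(p$dG_per_aa),
         pH_min_dG = p$pH[which.min(p$dG_per_aa)])
}

#' @rdname tidy.stability_profile
#' @param object A `stability_profile`.
#' @export
autoplot.stability_profile <- function(object, ...) {
  p <- object$profile
  d <- tidyr::pivot_longer(p, -"pH", names_to = "quantity")
  labs <- c(dG_per_aa = "dG (kJ/mol/aa)", charge_per_aa = "charge (e/aa)")
  d$quantity <- labs[d$quantity]
  ggplot2::ggplot(d, ggplot2::aes(.data$pH, .data$value)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(y = NULL) +
    ggplot2::theme_minimal()
}

#' Tidy a stability heat map
#'
#' @param x A `stability_heatmap`.
#' @param ... Unused.
#' @return Long tibble: `pH`, `ionic_strength`, `dG_per_aa`.
#' @export
tidy.stability_heatmap <- function(x, ...) {
  tibble(pH = rep(x$ph_grid, times = length(x$ionic_grid)),
         ionic_strength = rep(x$ionic_grid, each = length(x$ph_grid)),
         dG_per_aa = as.vector(x$dG_per_aa))
}

#' @rdname tidy.stability_heatmap
#' @param object A `stability_heatmap`.
#' @export
autoplot.stability_heatmap <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$pH, .data$ionic_strength,
                                  fill = .data$dG_per_aa)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(y = "ionic strength (M)", fill = "dG/aa\n(kJ/mol)") +
    ggplot2::theme_minimal()
}
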