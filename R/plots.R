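#' Plot a displacement profile
#'
#' Per-residue C-alpha and maximum side-chain displacements along the
#' reported region.
#'
#' @param object A [displacement_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.displacement_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              c("ca_disp", "sc_disp"),
                              names_to = "atom_class",
                              values_to = "displacement") |>
    mutate(atom_class = dplyr::recode(.data$atom_class,
                                      ca_disp = "C-alpha",
                                      sc_disp = "side chain"))
  ggplot(long, aes(x = .data$seq_num, y = .data$displacement,
                   colour = .data$atom_class)) +
    geom_line(na.rm = TRUE) +
    geom_point(na.rm = TRUE) +
    labs(x = "residue number", y = "displacement (Å)",
         colour = NULL) +
    theme_minimal()
}

#' Plot a kinetics fit
#'
#' Observed substrate-velocity points with the fitted curve.
#'
#' @param object A [fit_kinetics()] result.
#' @param n_grid Curve resolution (default 200).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kinetics_fit <- function(object, n_grid = 200, ...) {
  est <- setNames(object$parameters$estimate, object$parameters$term)
  h <- if (object$model == "Hill") est[["hill_h"]] else 1
  k <- est[[if (object$model == "MM") "k_m" else "k_half"]]
  grid <- tibble(conc = seq(min(object$data$conc), max(object$data$conc),
                            length.out = n_grid))
  grid$velocity <- hill_fn(grid$conc, est[["v_max"]], k, h)
  ggplot(object$data, aes(x = .data$conc, y = .data$velocity)) +
    geom_point() +
    geom_line(data = grid) +
    labs(x = "substrate concentration", y = "velocity",
         title = paste0(object$model, " fit")) +
    theme_minimal()
}

#' Plot a melting-curve fit
#'
#' Normalised fluorescence with the fitted Boltzmann sigmoid; the vertical
#' line marks the melting temperature (inflection point).
#'
#' @param object A [fit_melt()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.melt_fit <- function(object, ...) {
  d <- object$normalized
  d$fitted <- object$fitted
  ggplot(d, aes(x = .data$temperature)) +
    geom_point(aes(y = .data$f_norm)) +
    geom_line(aes(y = .data$fitted)) +
    ggplot2::geom_vline(xintercept = object$t_m, linetype = "dashed") +
    labs(x = "temperature (°C)", y = "relative fluorescence",
         title = sprintf("Tm = %.2f °C", object$t_m)) +
    theme_minimal()
}
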