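#' Plot methylation trajectories across generations
#'
#' Homomethylation level against the cumulative division index, one line
#' per sex, generations shaded; the classic picture is a pre-ZGA plateau
#' followed by divergence toward the two sex-specific equilibria and a
#' jump back to the averaged zygotic level at each fertilization.
#'
#' @param sim An `mzt_sim`.
#' @param states Which state proportions to draw (subset of
#'   `c("X", "Y", "Z")`).
#' @return A ggplot object.
#' @export
plot_trajectory <- function(sim, states = "X") {
  stopifnot(inherits(sim, "mzt_sim"), all(states %in% c("X", "Y", "Z")))
  D <- sim$scenario$growth$D
  df <- sim$trajectory %>%
    dplyr::mutate(cumulative_division =
                    (.data$generation - 1L) * D + .data$division) %>%
    tidyr::pivot_longer(dplyr::all_of(states), names_to = "state",
                        values_to = "proportion")
  ggplot2::ggplot(df, ggplot2::aes(.data$cumulative_division,
                                   .data$proportion,
                                   colour = .data$sex,
                                   alpha = factor(.data$generation),
                                   linetype = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::scale_alpha_discrete(range = c(0.45, 1), name = "generation") +
    ggplot2::labs(x = "cumulative cell division", y = "proportion of sites",
                  title = sim$scenario$name) +
    ggplot2::theme_minimal()
}

#' Plot embryo growth and repressor decay
#'
#' Cell count, realized division rate and repressor amount across the
#' divisions of one generation.
#'
#' @param sim An `mzt_sim`.
#' @param generation Generation to plot (default 1).
#' @return A ggplot object.
#' @export
plot_growth <- function(sim, generation = 1L) {
  stopifnot(inherits(sim, "mzt_sim"))
  df <- sim$trajectory %>%
    dplyr::filter(.data$generation == !!generation, .data$sex == "male") %>%
    dplyr::select("division", "N", "mu", "rho") %>%
    tidyr::pivot_longer(-"division", names_to = "variable")
  ggplot2::ggplot(df, ggplot2::aes(.data$division, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "cell division", y = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot mzt_sim
#' @export
autoplot.mzt_sim <- function(object, ...) {
  plot_trajectory(object, ...)
}

#' Plot the retained rate triples of a parameter-space search
#'
#' Maintenance methylation against repair demethylation, coloured by the
#' de novo rate.
#'
#' @param object An `mzt_param_space`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mzt_param_space
#' @export
autoplot.mzt_param_space <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$alpha, .data$delta,
                                       colour = .data$beta)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(
      title = sprintf("rate triples with equilibrium X within %.3g of %.3g",
                      attr(object, "accuracy"), attr(object, "target_X")),
      x = "maintenance methylation (alpha)",
      y = "repair demethylation (delta)",
      colour = "de novo (beta)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
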