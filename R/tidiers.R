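#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulation into its long trajectory table
#'
#' @param x An `mzt_sim`.
#' @param ... Unused.
#' @return The trajectory tibble (one row per generation x division x sex).
#' @method tidy mzt_sim
#' @export
tidy.mzt_sim <- function(x, ...) {
  x$trajectory
}

#' One-row summary of a simulation
#'
#' @param x An `mzt_sim`.
#' @param ... Unused.
#' @return A one-row tibble: generations, divisions per generation, final
#'   male/female homomethylation levels, environment mode and seed.
#' @method glance mzt_sim
#' @export
glance.mzt_sim <- function(x, ...) {
  final <- dplyr::filter(x$trajectory,
                         .data$generation == x$n_generations,
                         .data$division == x$scenario$growth$D)
  tibble::tibble(
    n_generations = x$n_generations,
    divisions_per_generation = x$scenario$growth$D,
    X_final_male = final$X[final$sex == "male"],
    X_final_female = final$X[final$sex == "female"],
    env_mode = x$scenario$env$mode,
    seed = x$seed %||% NA_integer_
  )
}

#' @export
summary.mzt_sim <- function(object, ...) {
  summarize_simulation(object, ...)
}

#' Tidy an equilibrium result
#'
#' @param x An `mzt_fixed_point`.
#' @param ... Unused.
#' @return A one-row tibble with the stationary composition and the rates
#'   that produced it.
#' @method tidy mzt_fixed_point
#' @export
tidy.mzt_fixed_point <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(X_star = x$X_star, Y_star = x$Y_star, Z_star = x$Z_star),
    x$rates
  )
}

#' @method glance mzt_fixed_point
#' @export
glance.mzt_fixed_point <- function(x, ...) {
  tibble::tibble(converged = x$converged, iterations = x$iterations,
                 closed_form = x$iterations == 0L)
}

#' One-row summary of a parameter-space search
#'
#' @param x An `mzt_param_space`.
#' @param ... Unused.
#' @return A one-row tibble: the target level, search settings, number of
#'   retained rate triples and the range of their division counts.
#' @method glance mzt_param_space
#' @export
glance.mzt_param_space <- function(x, ...) {
  tibble::tibble(
    target_X = attr(x, "target_X"),
    accuracy = attr(x, "accuracy"),
    grid_step = attr(x, "grid_step"),
    n_triples = nrow(x),
    min_divisions = if (all(is.na(x$divisions))) NA_integer_
                    else min(x$divisions, na.rm = TRUE),
    max_divisions = if (all(is.na(x$divisions))) NA_integer_
                    else max(x$divisions, na.rm = TRUE)
  )
}
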