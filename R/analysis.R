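#' Equilibrium composition under constant post-ZGA kinetics
#'
#' The per-division methylation map (replication, repair, active
#' demethylation) at constant rates is affine and contracts toward a unique
#' fixed point. In the canonical case `zeta = 0` with
#' `alpha + rho_c * delta = 1`, the hemimethylated pool empties in one step
#' and the fixed point is the closed form
#' \deqn{X^* = \beta / (1 - \alpha + \beta), \quad Y^* = 0.}
#' Otherwise the map is iterated until the state moves less than 1e-12
#' between divisions.
#'
#' @param alpha,beta,delta,zeta Rates (see [rate_set()]).
#' @param rho_c Repressor effect held constant; defaults to its
#'   late-development limit 1.
#' @return An object of class `mzt_fixed_point`: list with `X_star`,
#'   `Y_star`, `Z_star`, `converged`, `iterations` and the rates used.
#' @examples
#' fixed_point(0.99, 0.04, 0.01)$X_star # 0.80
#' fixed_point(0.99, 0.10, 0.01)$X_star # 0.9090909...
#' @export
fixed_point <- function(alpha, beta, delta, zeta = 0, rho_c = 1) {
  validate_rate_set(tibble::tibble(alpha = alpha, beta = beta, delta = delta,
                                   zeta = zeta))
  if (alpha + rho_c * delta > 1 + 1e-12) {
    stop("alpha + rho_c * delta must not exceed 1", call. = FALSE)
  }
  if (zeta == 0 && abs(alpha + rho_c * delta - 1) < 1e-12) {
    X <- beta / (1 - alpha + beta)
    res <- list(X_star = X, Y_star = 0, Z_star = 1 - X,
                converged = TRUE, iterations = 0L)
  } else {
    st <- methyl_state(1, 0, 0)
    converged <- FALSE
    it <- 0L
    for (it in seq_len(1e5L)) {
      nxt <- active_demethylate(
        repair_sites(replicate_sites(st), alpha, beta, delta, rho_c), zeta)
      if (max(abs(unlist(nxt) - unlist(st))) < 1e-12) {
        converged <- TRUE
        st <- nxt
        break
      }
      st <- nxt
    }
    if (!converged) stop("fixed-point iteration did not converge", call. = FALSE)
    res <- list(X_star = st$X, Y_star = st$Y, Z_star = st$Z,
                converged = TRUE, iterations = it)
  }
  res$rates <- tibble::tibble(alpha = alpha, beta = beta, delta = delta,
                              zeta = zeta, rho_c = rho_c)
  class(res) <- "mzt_fixed_point"
  res
}

#' @export
print.mzt_fixed_point <- function(x, ...) {
  cat(sprintf("<mzt_fixed_point> X* = %.6f  Y* = %.6f  Z* = %.6f (%s)\n",
              x$X_star, x$Y_star, x$Z_star,
              if (x$iterations == 0) "closed form"
              else paste0(x$iterations, " iterations")))
  invisible(x)
}

# Closed-form fixed point of the zeta-free map, vectorized over rate
# vectors (used by the parameter-space explorer). With w = 1 - alpha -
# rho_c * delta the stationarity conditions reduce to
#   Y* = w X* / (1 - w/2),
#   X* [1 - (alpha - beta) - (alpha - beta) w / (2 - w)] = beta.
fixed_point_closed <- function(alpha, beta, delta, rho_c = 1) {
  w <- 1 - alpha - rho_c * delta
  ab <- alpha - beta
  denom <- 1 - ab - ab * w / (2 - w)
  X <- beta / denom
  Y <- w * X / (1 - w / 2)
  list(X = X, Y = Y, Z = 1 - X - Y)
}

#' Division at which a trajectory settles at a methylation level
#'
#' Returns the smallest division index at which `|X - target| < tol` and
#' the trajectory stays within tolerance for every later recorded
#' division. The canonical reporting accuracy is 0.01, i.e. the division at
#' which the methylation level rounds to the target at two decimals
#' (`tol = 0.005`).
#'
#' @param x A trajectory tibble (from [run_generation()] or
#'   `sim$trajectory`) or an `mzt_sim`.
#' @param sex Which sex's lineage to inspect.
#' @param target Methylation level defining equilibrium (e.g. the rounded
#'   fixed point of the sex's post-ZGA rates).
#' @param tol Half-width of the equilibrium band.
#' @param generation Generation to inspect; defaults to the last one
#'   present.
#' @return The division index, or `NA` (with a warning) if the trajectory
#'   never settles within the band.
#' @examples
#' sim <- run_simulation(scenario_preset("table1_default"))
#' divisions_to_equilibrium(sim, "female", target = 0.91) # 67
#' @export
divisions_to_equilibrium <- function(x, sex, target, tol = 0.005,
                                     generation = NULL) {
  traj <- if (inherits(x, "mzt_sim")) x$trajectory else x
  g <- generation %||% max(traj$generation)
  rows <- dplyr::arrange(
    dplyr::filter(traj, .data$generation == g, .data$sex == !!sex),
    .data$division)
  if (nrow(rows) == 0) stop("no trajectory rows for that sex/generation",
                            call. = FALSE)
  inside <- abs(rows$X - target) < tol
  stays <- rev(cumprod(rev(inside))) == 1
  if (!any(stays)) {
    warning("trajectory never settles within tolerance of the target")
    return(NA_integer_)
  }
  rows$division[which(stays)[1]]
}

#' ZGA onset division
#'
#' The division at which the pre- to post-ZGA rate transition crosses its
#' logistic midpoint: the first `d` with
#' `rho_power * rho0 / rho >= 1 / nu_t`, using the repressor amount driving
#' that division. When no repressor is loaded (`rho0 = 0`) the trigger is
#' the nucleocytoplasmic ratio itself, `nu <= nu_t`.
#'
#' @param x An `mzt_sim`, or a trajectory tibble together with `growth`.
#' @param generation Generation to inspect (default: first).
#' @param growth The [growth_config()] of the run (required for plain
#'   trajectory input).
#' @return The onset division index, or `NA` (with a warning) if the
#'   trigger is never reached within the recorded divisions.
#' @examples
#' sim <- run_simulation(scenario_preset("table1_default"))
#' zga_onset(sim) # 45
#' @export
zga_onset <- function(x, generation = NULL, growth = NULL) {
  if (inherits(x, "mzt_sim")) {
    growth <- x$scenario$growth
    x <- x$trajectory
  }
  if (is.null(growth)) stop("supply `growth` with a plain trajectory",
                            call. = FALSE)
  g <- generation %||% min(x$generation)
  rows <- dplyr::arrange(
    dplyr::filter(x, .data$generation == g, .data$sex == "male"),
    .data$division)
  zga_onset_trajectory(rows, growth)
}

zga_onset_trajectory <- function(rows, growth) {
  crossed <- if (growth$rho0 > 0) {
    growth$rho_power * growth$rho0 / rows$rho >= 1 / growth$nu_t
  } else {
    rows$nu <= growth$nu_t
  }
  hit <- which(crossed)
  if (length(hit) == 0) {
    warning("ZGA trigger never reached within the recorded divisions")
    return(NA_integer_)
  }
  rows$division[hit[1]]
}

#' Explore the (alpha, beta, delta) space compatible with a gametic level
#'
#' Scans the grid of maintenance-methylation (`alpha`), de novo
#' methylation (`beta`) and repair-demethylation (`delta`) rates, with
#' active demethylation fixed at `zeta = 0`, and keeps the triples whose
#' equilibrium homomethylation level lies within `accuracy` of
#' `target_X`. For each retained triple the number of divisions needed to
#' settle at the equilibrium from a standard zygotic starting level is
#' computed by simulating the constant-rate map.
#'
#' High target levels admit only narrow rate combinations (maintenance must
#' almost fully compensate replication losses), whereas low targets are
#' reachable from a broad swath of the rate space.
#'
#' @param target_X Target homomethylation level in `[0, 1]`.
#' @param accuracy Retention half-band around the target.
#' @param grid_step Grid resolution on each rate axis.
#' @param start_X Homomethylation level of the standard starting state
#'   (default: the two-generation zygotic average of the canonical run).
#' @param tol Equilibrium half-width for the division counts.
#' @param max_divisions Cap on the simulated divisions per triple.
#' @param compute_divisions Set `FALSE` to skip the per-triple division
#'   counts (faster for large grids).
#' @return An object of class `mzt_param_space`: a tibble of retained
#'   triples with columns `alpha`, `beta`, `delta`, `X_star` and
#'   `divisions` (NA when not computed or not settled), carrying the
#'   search settings as attributes.
#' @examples
#' ps <- explore_parameter_space(0.80, grid_step = 0.05)
#' nrow(ps)
#' @export
explore_parameter_space <- function(target_X, accuracy = 0.01,
                                    grid_step = 0.01,
                                    start_X = 0.854545,
                                    tol = 0.005,
                                    max_divisions = 2000L,
                                    compute_divisions = TRUE) {
  stopifnot(target_X >= 0, target_X <= 1, accuracy > 0, grid_step > 0,
            start_X >= 0, start_X <= 1)
  ax <- seq(0, 1, by = grid_step)
  grid <- tidyr::expand_grid(alpha = ax, beta = ax, delta = ax)
  grid <- dplyr::filter(grid, .data$alpha + .data$delta <= 1 + 1e-12)
  fp <- fixed_point_closed(grid$alpha, grid$beta, grid$delta)
  grid$X_star <- fp$X
  kept <- dplyr::filter(grid, abs(.data$X_star - target_X) <= accuracy)

  kept$divisions <- NA_integer_
  if (compute_divisions && nrow(kept) > 0) {
    X <- rep(start_X, nrow(kept))
    Y <- rep(0, nrow(kept))
    last_out <- integer(nrow(kept))
    for (d in seq_len(max_divisions)) {
      Yd <- X + Y / 2
      Zd <- 1 - X - Y / 2
      Xn <- kept$alpha * Yd + kept$beta * Zd
      Yn <- (1 - kept$alpha - kept$delta) * Yd
      X <- Xn
      Y <- Yn
      out <- abs(X - kept$X_star) >= tol
      last_out[out] <- d
      if (!any(out) && d > 1) break
    }
    settled <- abs(X - kept$X_star) < tol
    kept$divisions <- ifelse(settled, last_out + 1L, NA_integer_)
  }

  structure(kept,
            class = c("mzt_param_space", class(kept)),
            target_X = target_X, accuracy = accuracy,
            grid_step = grid_step, start_X = start_X, tol = tol,
            empty = nrow(kept) == 0)
}

#' Net (de-)methylation enzyme activity between two developmental stages
#'
#' Converts a change in global homomethylation level into an absolute
#' enzymatic speed: `A = (X_S1 - X_S0) * L_n * H / T_d`, in CpG sites
#' converted per unit of `T_d` (time or cell divisions). Positive `A`
#' means net methylation, negative net demethylation.
#'
#' @param X_S0,X_S1 Global homomethylation proportions at the earlier and
#'   later stage.
#' @param L_n Haploid genome-wide CpG count.
#' @param H Ploidy (2 for diploids).
#' @param T_d Interval between the stages, in cell divisions or time units.
#' @return A tibble echoing the inputs with the activity column `A`.
#' @examples
#' # zebrafish 32-cell -> 128-cell stages:
#' methylation_activity(0.85, 0.87, 24.2e6, 2, 2)$A # 484000
#' @export
methylation_activity <- function(X_S0, X_S1, L_n, H, T_d) {
  if (any(T_d <= 0)) stop("T_d must be positive", call. = FALSE)
  if (any(L_n <= 0) || any(H < 1)) {
    stop("L_n must be positive and H >= 1", call. = FALSE)
  }
  if (any(c(X_S0, X_S1) < 0) || any(c(X_S0, X_S1) > 1)) {
    stop("methylation proportions must lie in [0, 1]", call. = FALSE)
  }
  tibble::tibble(X_S0 = X_S0, X_S1 = X_S1, L_n = L_n, H = H, T_d = T_d,
                 A = (X_S1 - X_S0) * L_n * H / T_d)
}
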