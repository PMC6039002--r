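#' Construct a methylation-state composition
#'
#' The genome-wide composition over the three CpG methylation states:
#' homomethylated (`X`, both strands), hemimethylated (`Y`, one strand) and
#' unmethylated (`Z`). Components must be proportions summing to 1.
#'
#' Vectorized: supplying equal-length vectors yields one row per state,
#' which is convenient for building trajectories.
#'
#' @param X,Y,Z Proportions in `[0, 1]` with `X + Y + Z = 1`.
#' @return A tibble with columns `X`, `Y`, `Z`.
#' @examples
#' methyl_state(0.8, 0, 0.2)
#' @export
methyl_state <- function(X, Y, Z) {
  st <- tibble::tibble(X = as.numeric(X), Y = as.numeric(Y), Z = as.numeric(Z))
  validate_methyl_state(st)
  st
}

validate_methyl_state <- function(st, tol = 1e-9) {
  vals <- c(st$X, st$Y, st$Z)
  if (any(!is.finite(vals)) || any(vals < -tol) || any(vals > 1 + tol)) {
    stop("methylation proportions must lie in [0, 1]", call. = FALSE)
  }
  if (any(abs(st$X + st$Y + st$Z - 1) > tol)) {
    stop("methylation proportions must sum to 1", call. = FALSE)
  }
  invisible(st)
}

#' Semiconservative DNA replication of methylation states
#'
#' Replication dilutes methylation: every homomethylated site becomes
#' hemimethylated on the daughter strands, hemimethylated sites split
#' evenly into hemi- and unmethylated, and unmethylated sites stay
#' unmethylated. So `(X, Y, Z) -> (0, X + Y/2, Z + Y/2)`.
#'
#' @param state A methylation-state tibble (any number of rows).
#' @return The post-replication state; the total is conserved.
#' @export
replicate_sites <- function(state) {
  tibble::tibble(X = 0 * state$X,
                 Y = state$X + state$Y / 2,
                 Z = state$Z + state$Y / 2)
}

#' Repair (maintenance) methylation and demethylation
#'
#' Acting on the post-replication composition (no homomethylated sites):
#' hemimethylated sites are re-methylated to homomethylated at rate `alpha`
#' or demethylated at rate `delta` (scaled by the repressor effect
#' `rho_c`), while unmethylated sites gain de novo methylation at rate
#' `beta`:
#' \deqn{X' = \alpha Y + \beta Z,\quad
#'       Y' = (1 - \alpha - \rho_c \delta) Y,\quad
#'       Z' = (1 - \beta) Z + \rho_c \delta Y.}
#'
#' @param state Post-replication state (rows with `X = 0`).
#' @param alpha,beta,delta Rates in `[0, 1]` with
#'   `alpha + rho_c * delta <= 1`.
#' @param rho_c Repressor effect in `[0, 1]`.
#' @return The repaired state; the total is conserved.
#' @export
repair_sites <- function(state, alpha, beta, delta, rho_c = 1) {
  if (any(alpha + rho_c * delta > 1 + 1e-12)) {
    stop("alpha + rho_c * delta exceeds 1: would create a negative ",
         "hemimethylated proportion", call. = FALSE)
  }
  if (any(beta > 1) || any(c(alpha, beta, delta) < 0) || any(rho_c < 0) ||
      any(rho_c > 1)) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  tibble::tibble(X = alpha * state$Y + beta * state$Z,
                 Y = (1 - alpha - rho_c * delta) * state$Y,
                 Z = (1 - beta) * state$Z + rho_c * delta * state$Y)
}

#' Active demethylation
#'
#' Homomethylated sites lose methylation on both strands at rate `zeta`:
#' `(X, Y, Z) -> ((1 - zeta) X, Y, Z + zeta X)`.
#'
#' @param state A methylation-state tibble.
#' @param zeta Active demethylation rate in `[0, 1]`.
#' @return The state after active demethylation; the total is conserved.
#' @export
active_demethylate <- function(state, zeta) {
  if (any(zeta < 0) || any(zeta > 1)) {
    stop("zeta must lie in [0, 1]", call. = FALSE)
  }
  tibble::tibble(X = (1 - zeta) * state$X,
                 Y = state$Y,
                 Z = state$Z + zeta * state$X)
}

#' One full cell division of the coupled embryo/methylation system
#'
#' The per-division update used by [run_generation()]. The repressor effect
#' and the four instantaneous rates are evaluated from the repressor amount
#' at the start of the division; the three methylation sub-steps
#' (replication, repair, active demethylation) are then applied in order;
#' finally the cell count and the repressor are advanced. Methylation at
#' division `d` therefore depends on the repressor at division `d`, not
#' `d + 1`.
#'
#' @param state Methylation state entering the division (one row).
#' @param embryo A list with components `N`, `rho`, `rho0` describing the
#'   embryo entering the division.
#' @param growth A [growth_config()].
#' @param sex A [sex_config()] providing pre- and post-ZGA rates.
#' @return A list with components:
#'   \describe{
#'     \item{state}{methylation state after the division,}
#'     \item{embryo}{list `N`, `rho`, `rho0`, `nu`, `mu` after the division,}
#'     \item{rates}{one-row tibble of the instantaneous `alpha`, `beta`,
#'       `delta`, `zeta` and `rho_c` used.}
#'   }
#' @export
division_step <- function(state, embryo, growth, sex) {
  rho <- embryo$rho
  rho0 <- embryo$rho0
  nu <- nucleocytoplasmic_ratio(embryo$N)
  rho_c <- repressor_effect(rho, rho0)

  pre <- sex$pre_zga
  post <- sex$post_zga
  tr <- function(p0, p1, Q) {
    transition_rate(p0, p1, Q, growth$rho_power, rho0, rho, growth$nu_t,
                    nu = nu)
  }
  alpha <- tr(pre$alpha, post$alpha, growth$Q_alpha)
  beta <- tr(pre$beta, post$beta, growth$Q_beta)
  delta <- tr(pre$delta, post$delta, growth$Q_delta)
  zeta <- tr(pre$zeta, post$zeta, growth$Q_zeta)

  st <- replicate_sites(state)
  st <- repair_sites(st, alpha, beta, delta, rho_c)
  st <- active_demethylate(st, zeta)

  mu <- realized_division_rate(rho, growth$r)
  N_new <- update_cell_count(embryo$N, mu, growth$K)
  rho_new <- decay_repressor(rho, growth$rho_deg)

  list(
    state = st,
    embryo = list(N = N_new, rho = rho_new, rho0 = rho0,
                  nu = nucleocytoplasmic_ratio(N_new), mu = mu),
    rates = tibble::tibble(alpha = alpha, beta = beta, delta = delta,
                           zeta = zeta, rho_c = rho_c)
  )
}
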