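#' Advance the embryo cell count by one division
#'
#' One step of discrete logistic growth: `N + mu * N * (1 - N / K)`. The
#' count is real-valued (a deterministic mean-field description of
#' cleavage); rounding, if wanted, belongs to reporting.
#'
#' @param N Current cell count, in `[1, K]`.
#' @param mu Realized division rate, in `(0, 1]`.
#' @param K Equilibrium cell number.
#' @return The cell count after the division; never below `N` nor above `K`.
#' @examples
#' update_cell_count(1, 0.2, 1024)
#' @export
update_cell_count <- function(N, mu, K) {
  if (any(!is.finite(N)) || any(N < 1) || any(N > K)) {
    stop("N must lie in [1, K]", call. = FALSE)
  }
  if (any(mu <= 0) || any(mu > 1)) {
    stop("mu must lie in (0, 1]", call. = FALSE)
  }
  N + mu * N * (1 - N / K)
}

#' Realized cell division rate under the parental repressor
#'
#' The repressor speeds up early cleavage: `mu = (1 + rho) * r`, so
#' `rho = 1` doubles the intrinsic rate and `rho = 0` recovers it.
#'
#' @param rho Current repressor amount (>= 0).
#' @param r Intrinsic division rate (> 0).
#' @return The realized rate `mu`.
#' @export
realized_division_rate <- function(rho, r) {
  if (any(rho < 0) || any(r <= 0)) {
    stop("rho must be >= 0 and r > 0", call. = FALSE)
  }
  (1 + rho) * r
}

#' Degrade the parental repressor by one division
#'
#' Geometric decay at rate `rho_deg`: after `d` divisions from `rho0` the
#' amount is exactly `rho0 * (1 - rho_deg)^d`.
#'
#' @param rho Current repressor amount (>= 0).
#' @param rho_deg Degradation rate per division, in `[0, 1]`.
#' @return The repressor amount after one division.
#' @export
decay_repressor <- function(rho, rho_deg) {
  if (any(rho < 0)) stop("rho must be >= 0", call. = FALSE)
  if (any(rho_deg < 0) || any(rho_deg > 1)) {
    stop("rho_deg must lie in [0, 1]", call. = FALSE)
  }
  rho * (1 - rho_deg)
}

#' Repressing effect of the parental repressor on methylation
#'
#' The effect grows as the repressor is titrated away:
#' `(rho0 - rho) / rho0`, i.e. 0 at the start of a generation and -> 1 as
#' the repressor vanishes. With no repressor loaded (`rho0 = 0`) the effect
#' is defined as 1.
#'
#' @param rho Current repressor amount.
#' @param rho0 Initial repressor amount.
#' @return The effect, in `[0, 1]`.
#' @export
repressor_effect <- function(rho, rho0) {
  if (length(rho0) == 1) rho0 <- rep(rho0, length(rho))
  if (any(rho < 0) || any(rho0 < 0)) stop("negative repressor", call. = FALSE)
  if (any(rho > rho0 + 1e-12)) {
    stop("rho exceeds its initial value rho0", call. = FALSE)
  }
  ifelse(rho0 > 0, (rho0 - rho) / rho0, 1)
}

#' Nucleocytoplasmic ratio of the embryo
#'
#' Cleavage divides a fixed cytoplasmic volume among ever more nuclei, so
#' the ratio is `1 / N`.
#'
#' @param N Cell count (>= 1).
#' @return The ratio, in `(0, 1]`.
#' @export
nucleocytoplasmic_ratio <- function(N) {
  if (any(N < 1)) stop("N must be >= 1", call. = FALSE)
  1 / N
}

#' Instantaneous (de-)methylation rate along the pre/post-ZGA transition
#'
#' The rate moves from its pre-ZGA to its post-ZGA value along a logistic
#' in the repressor ratio:
#' `pre + (post - pre) / (1 + exp(-Q * (rho_power * rho0 / rho - 1 / nu_t)))`.
#' The midpoint is reached when `rho_power * rho0 / rho = 1 / nu_t`. The
#' exponent argument is clamped to +/- 700 so the logistic saturates to
#' `pre` or `post` exactly instead of overflowing (at canonical defaults the
#' generation starts at an argument of +9900).
#'
#' When `rho0 = 0` the repressor ratio is undefined; the transition then
#' falls back to the nucleocytoplasmic trigger itself: `pre` while
#' `nu > nu_t` and `post` once `nu <= nu_t` (supply `nu`).
#'
#' @param pre,post Pre- and post-ZGA rate values.
#' @param Q Transition slope (> 0).
#' @param rho_power Magnitude of the repressor effect on the trigger.
#' @param rho0 Initial repressor amount.
#' @param rho Current repressor amount (> 0 when `rho0 > 0`).
#' @param nu_t Nucleocytoplasmic threshold.
#' @param nu Current nucleocytoplasmic ratio; only consulted when
#'   `rho0 = 0`.
#' @return The instantaneous rate, bounded between `pre` and `post`.
#' @export
transition_rate <- function(pre, post, Q, rho_power, rho0, rho, nu_t,
                            nu = NULL) {
  stopifnot(Q > 0, nu_t > 0)
  if (rho0 == 0) {
    if (is.null(nu)) {
      stop("nu is required when rho0 = 0 (ratio-triggered switch)",
           call. = FALSE)
    }
    return(ifelse(nu <= nu_t, post, pre))
  }
  if (any(rho == 0)) {
    stop("rho = 0 with rho0 > 0: repressor ratio undefined", call. = FALSE)
  }
  arg <- Q * (rho_power * rho0 / rho - 1 / nu_t)
  arg <- pmin(pmax(arg, -700), 700)
  pre + (post - pre) / (1 + exp(-arg))
}
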