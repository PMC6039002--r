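#' Construct a validated set of (de-)methylation rates
#'
#' A rate set holds the four per-division conversion rates acting on CpG
#' methylation states: maintenance (repair) methylation `alpha`
#' (hemi -> homo), de novo methylation `beta` (un -> homo), repair
#' demethylation `delta` (hemi -> un) and active demethylation `zeta`
#' (homo -> un).
#'
#' All rates must lie in `[0, 1]` and `alpha + delta <= 1`, so that the
#' hemimethylated pool can never be depleted below zero during the repair
#' step regardless of the repressor effect.
#'
#' @param alpha Maintenance methylation rate.
#' @param beta De novo methylation rate.
#' @param delta Repair demethylation rate.
#' @param zeta Active demethylation rate.
#' @return A one-row tibble with columns `alpha`, `beta`, `delta`, `zeta`.
#' @examples
#' rate_set(alpha = 0.99, beta = 0.04, delta = 0.01, zeta = 0)
#' @export
rate_set <- function(alpha, beta, delta, zeta = 0) {
  rs <- tibble::tibble(alpha = as.numeric(alpha), beta = as.numeric(beta),
                       delta = as.numeric(delta), zeta = as.numeric(zeta))
  validate_rate_set(rs)
  rs
}

validate_rate_set <- function(rs, where = "rate_set") {
  vals <- unlist(rs[c("alpha", "beta", "delta", "zeta")])
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1)) {
    stop(where, ": all rates must be finite and in [0, 1]", call. = FALSE)
  }
  if (any(rs$alpha + rs$delta > 1 + 1e-12)) {
    stop(where, ": alpha + delta must not exceed 1", call. = FALSE)
  }
  invisible(rs)
}

#' Per-sex methylation kinetics configuration
#'
#' Bundles one sex's pre-ZGA and post-ZGA rate sets together with the
#' intervals of additive environmental variation applied (when an
#' environment model is active) to the post-ZGA `alpha` and `delta` at each
#' fertilization.
#'
#' @param sex `"male"` or `"female"`.
#' @param pre_zga,post_zga Rate sets from [rate_set()]. Pre-ZGA rates default
#'   to perfect maintenance (`alpha = 1`, others 0), which keeps the
#'   methylation level `X + Y` constant across cleavage divisions.
#' @param alpha_env_range,delta_env_range Length-2 numeric intervals of
#'   additive perturbation for the post-ZGA rates.
#' @return A list of class `sex_config`.
#' @export
sex_config <- function(sex,
                       post_zga,
                       pre_zga = rate_set(1, 0, 0, 0),
                       alpha_env_range = c(-0.01, 0.01),
                       delta_env_range = c(-0.01, 0.01)) {
  sex <- match.arg(sex, c("male", "female"))
  validate_rate_set(pre_zga, "pre_zga")
  validate_rate_set(post_zga, "post_zga")
  for (rg in list(alpha_env_range, delta_env_range)) {
    if (length(rg) != 2 || any(!is.finite(rg)) || rg[1] > rg[2]) {
      stop("environmental ranges must be finite intervals c(min, max)",
           call. = FALSE)
    }
  }
  structure(
    list(sex = sex, pre_zga = pre_zga, post_zga = post_zga,
         alpha_env_range = as.numeric(alpha_env_range),
         delta_env_range = as.numeric(delta_env_range)),
    class = "sex_config"
  )
}

#' Embryo growth and ZGA-transition configuration
#'
#' Parameters of the discrete logistic growth of the embryo, the geometric
#' decay of the parental repressor, and the logistic transition of
#' (de-)methylation rates from pre- to post-ZGA values.
#'
#' Defaults reproduce the canonical simulation scenario: `D = 250` divisions
#' per generation, intrinsic division rate `r = 0.1`, equilibrium cell
#' number `K = 1024`, initial repressor `rho0 = 1` (doubling the early
#' division rate) degrading at `rho_deg = 0.1` per division, transition
#' slope `Q = 100` for all four rates, and a nucleocytoplasmic threshold
#' `nu_t = 0.01` (reached at 100 cells).
#'
#' @param r Intrinsic cell division rate (> 0).
#' @param K Equilibrium cell number (>= 1).
#' @param rho0 Initial amount of parental repressor (>= 0).
#' @param rho_deg Repressor degradation rate per division, in `[0, 1]`.
#' @param rho_power Magnitude of the repressor effect on triggering ZGA.
#' @param nu_t Nucleocytoplasmic-ratio threshold, in `(0, 1]`.
#' @param Q_alpha,Q_beta,Q_delta,Q_zeta Slopes of the pre- to post-ZGA rate
#'   transitions (> 0).
#' @param D Number of cell divisions per generation (>= 1).
#' @param N0 Cell count of the zygote; `1/N0` is the starting
#'   nucleocytoplasmic ratio.
#' @return A list of class `growth_config`.
#' @export
growth_config <- function(r = 0.1, K = 1024, rho0 = 1.0, rho_deg = 0.1,
                          rho_power = 1.0, nu_t = 0.01,
                          Q_alpha = 100, Q_beta = 100, Q_delta = 100,
                          Q_zeta = 100, D = 250L, N0 = 1) {
  stopifnot(r > 0, K >= 1, rho0 >= 0, rho_deg >= 0, rho_deg <= 1,
            rho_power > 0, nu_t > 0, nu_t <= 1,
            Q_alpha > 0, Q_beta > 0, Q_delta > 0, Q_zeta > 0,
            D >= 1, N0 >= 1, N0 <= K)
  structure(
    list(r = r, K = K, rho0 = rho0, rho_deg = rho_deg,
         rho_power = rho_power, nu_t = nu_t,
         Q_alpha = Q_alpha, Q_beta = Q_beta, Q_delta = Q_delta,
         Q_zeta = Q_zeta, D = as.integer(D), N0 = N0),
    class = "growth_config"
  )
}

#' Environmental variation model for transgenerational rate drift
#'
#' Describes how post-ZGA `alpha` and `delta` change at each fertilization.
#' In `"random"` mode each flagged sex receives independent uniform draws
#' from its configured intervals; in `"directional"` mode a constant shift
#' is added each generation; `"none"` leaves rates untouched.
#'
#' By default perturbations accumulate (a random walk on the current rates);
#' set `accumulate = FALSE` to perturb the fixed base rates independently
#' each generation instead.
#'
#' @param mode One of `"none"`, `"random"`, `"directional"`.
#' @param perturb_sexes Character vector of sexes the perturbation applies to.
#' @param accumulate Logical; random-walk (`TRUE`) vs i.i.d. around the base.
#' @param alpha_shift,delta_shift Constant per-generation shifts used in
#'   `"directional"` mode.
#' @return A list of class `env_model`.
#' @export
env_model <- function(mode = c("none", "random", "directional"),
                      perturb_sexes = c("male", "female"),
                      accumulate = TRUE,
                      alpha_shift = 0, delta_shift = 0) {
  mode <- match.arg(mode)
  perturb_sexes <- match.arg(perturb_sexes, c("male", "female"),
                             several.ok = TRUE)
  stopifnot(is.logical(accumulate), length(accumulate) == 1,
            is.finite(alpha_shift), is.finite(delta_shift))
  structure(
    list(mode = mode, perturb_sexes = perturb_sexes,
         accumulate = accumulate,
         alpha_shift = alpha_shift, delta_shift = delta_shift),
    class = "env_model"
  )
}

#' Assemble a simulation scenario
#'
#' A scenario is the complete input of [run_simulation()]: growth/ZGA
#' parameters, both sexes' kinetic rates, the environmental model, the
#' number of generations, and the zygotic methylation state each sex starts
#' from in generation 1 (both default to fully homomethylated).
#'
#' @param growth A [growth_config()].
#' @param male,female [sex_config()] objects.
#' @param env An [env_model()].
#' @param n_generations Number of generations to simulate.
#' @param initial_male,initial_female Zygotic [methyl_state()] rows.
#' @param name Scenario label carried through to outputs.
#' @return A list of class `mzt_scenario`.
#' @seealso [scenario_preset()] for ready-made parameterizations.
#' @export
scenario <- function(growth = growth_config(),
                     male = sex_config("male", rate_set(0.99, 0.04, 0.01, 0)),
                     female = sex_config("female", rate_set(0.99, 0.1, 0.01, 0)),
                     env = env_model("none"),
                     n_generations = 2L,
                     initial_male = methyl_state(1, 0, 0),
                     initial_female = methyl_state(1, 0, 0),
                     name = "scenario") {
  stopifnot(inherits(growth, "growth_config"),
            inherits(male, "sex_config"), inherits(female, "sex_config"),
            inherits(env, "env_model"), n_generations >= 1)
  if (male$sex != "male" || female$sex != "female") {
    stop("`male` and `female` must carry matching sex labels", call. = FALSE)
  }
  validate_methyl_state(initial_male)
  validate_methyl_state(initial_female)
  structure(
    list(name = name, growth = growth, male = male, female = female,
         env = env, n_generations = as.integer(n_generations),
         initial = list(male = initial_male, female = initial_female)),
    class = "mzt_scenario"
  )
}

#' Ready-made scenario presets
#'
#' * `"table1_default"` — the canonical parameterization: post-ZGA rates
#'   `alpha = 0.99`, `delta = 0.01`, `zeta = 0` for both sexes, with
#'   `beta = 0.04` (male, equilibrium X = 0.80) and `beta = 0.1` (female,
#'   equilibrium X = 0.909...).
#' * `"zebrafish"` — alias of the default; the two equilibria match the
#'   gametic methylation levels reported for zebrafish (sperm 0.91,
#'   oocyte 0.80).
#' * `"human"` — `beta` re-derived so the fixed points equal the human
#'   gametic levels (sperm 0.54, metaphase-II oocyte 0.48) at the same
#'   maintenance rates.
#' * `"hypothetical_low"` — both sexes converge to X = 0.30, a hypothetical
#'   low-methylation gamete.
#'
#' The human and hypothetical `beta` values are pinned by inverting the
#' equilibrium relation X* = beta / (1 - alpha + beta) at
#' `alpha = 0.99`, `delta = 0.01`.
#'
#' @param name Preset identifier.
#' @param ... Overrides passed on to [scenario()] (e.g. `n_generations`).
#' @return An `mzt_scenario`.
#' @examples
#' sc <- scenario_preset("table1_default")
#' sc$growth$D
#' @export
scenario_preset <- function(name = c("table1_default", "zebrafish", "human",
                                     "hypothetical_low"), ...) {
  name <- match.arg(name)
  beta_for <- function(target, alpha = 0.99) target * (1 - alpha) / (1 - target)
  sexes <- switch(name,
    table1_default = ,
    zebrafish = list(male = 0.04, female = 0.1),
    human = list(male = beta_for(0.54), female = beta_for(0.48)),
    hypothetical_low = list(male = beta_for(0.30), female = beta_for(0.30))
  )
  args <- list(
    male = sex_config("male", rate_set(0.99, sexes$male, 0.01, 0)),
    female = sex_config("female", rate_set(0.99, sexes$female, 0.01, 0)),
    name = name
  )
  args <- utils::modifyList(args, list(...))
  do.call(scenario, args)
}

#' @export
print.mzt_scenario <- function(x, ...) {
  cat("<mzt_scenario>", x$name, "\n")
  cat("  generations:", x$n_generations,
      " divisions/generation:", x$growth$D, "\n")
  cat("  growth: r =", x$growth$r, " K =", x$growth$K,
      " rho0 =", x$growth$rho0, " rho_deg =", x$growth$rho_deg,
      " nu_t =", x$growth$nu_t, "\n")
  for (s in c("male", "female")) {
    p <- x[[s]]$post_zga
    cat(sprintf("  %s post-ZGA: alpha=%g beta=%g delta=%g zeta=%g\n",
                s, p$alpha, p$beta, p$delta, p$zeta))
  }
  cat("  env mode:", x$env$mode, "\n")
  invisible(x)
}
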