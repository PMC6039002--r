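#' Simulate one generation (zygote to gamete) for both sexes
#'
#' Runs `D` cell divisions for each sex as two parallel lineages from their
#' zygotic methylation states. Growth parameters are shared between sexes
#' by default, but embryo state is tracked per sex so sex-specific growth
#' remains possible.
#'
#' Each trajectory row describes one division: the driving variables
#' (`nu`, `rho`, `rho_c`, `mu` and the instantaneous rates) are those at
#' the start of the division, while `N`, `X`, `Y`, `Z` are its results.
#'
#' @param zygotes A list with `male` and `female` [methyl_state()] rows
#'   (identical from generation 2 onward, as both are offspring of one
#'   fertilization).
#' @param growth A [growth_config()].
#' @param sexes A list with `male` and `female` [sex_config()]s.
#' @param generation Generation index recorded in the output.
#' @return A tibble with one row per division and sex and columns
#'   `generation`, `division`, `sex`, `N`, `nu`, `rho`, `rho_c`, `mu`,
#'   `alpha`, `beta`, `delta`, `zeta`, `X`, `Y`, `Z`.
#' @examples
#' sc <- scenario_preset("table1_default")
#' gen1 <- run_generation(sc$initial, sc$growth,
#'                        list(male = sc$male, female = sc$female))
#' dplyr::filter(gen1, division == 250)
#' @export
run_generation <- function(zygotes, growth, sexes, generation = 1L) {
  stopifnot(all(c("male", "female") %in% names(zygotes)),
            all(c("male", "female") %in% names(sexes)))
  D <- growth$D
  out <- vector("list", 2L)
  for (s in c("male", "female")) {
    state <- zygotes[[s]]
    validate_methyl_state(state)
    embryo <- list(N = growth$N0, rho = growth$rho0, rho0 = growth$rho0)
    rec <- matrix(NA_real_, nrow = D, ncol = 13L)
    for (d in seq_len(D)) {
      nu_in <- nucleocytoplasmic_ratio(embryo$N)
      rho_in <- embryo$rho
      step <- division_step(state, embryo, growth, sexes[[s]])
      rec[d, ] <- c(step$embryo$N, nu_in, rho_in, step$rates$rho_c,
                    step$embryo$mu, step$rates$alpha, step$rates$beta,
                    step$rates$delta, step$rates$zeta,
                    step$state$X, step$state$Y, step$state$Z, d)
      state <- step$state
      embryo <- step$embryo
    }
    out[[if (s == "male") 1L else 2L]] <- tibble::tibble(
      generation = as.integer(generation), division = as.integer(rec[, 13]),
      sex = s, N = rec[, 1], nu = rec[, 2], rho = rec[, 3],
      rho_c = rec[, 4], mu = rec[, 5], alpha = rec[, 6], beta = rec[, 7],
      delta = rec[, 8], zeta = rec[, 9], X = rec[, 10], Y = rec[, 11],
      Z = rec[, 12]
    )
  }
  dplyr::bind_rows(out)
}

#' Fertilization: average the parental methylation states
#'
#' The zygote of the next generation starts at the component-wise mean of
#' the two parental gametic compositions. Fertilization is gated on the
#' generation having completed its `D` divisions; supply `division` and
#' `D` to enforce the gate.
#'
#' @param male,female Final [methyl_state()] rows of the two parents.
#' @param division,D Optionally, the division reached and the divisions per
#'   generation; an error is raised if `division != D` (fertilization
#'   before the generation completes).
#' @return A one-row methylation-state tibble.
#' @examples
#' fertilize(methyl_state(1, 0, 0), methyl_state(0, 0, 1))
#' @export
fertilize <- function(male, female, division = NULL, D = NULL) {
  if (!is.null(division) && !is.null(D) && division != D) {
    stop("fertilization before division D: generation not complete",
         call. = FALSE)
  }
  validate_methyl_state(male)
  validate_methyl_state(female)
  methyl_state((male$X + female$X) / 2,
               (male$Y + female$Y) / 2,
               (male$Z + female$Z) / 2)
}

#' Apply one generation of environmental variation to a sex's rates
#'
#' In `"random"` mode, independent uniform draws from the sex's configured
#' intervals are added to the post-ZGA `alpha` and `delta`; in
#' `"directional"` mode the model's constant shifts are added. Perturbed
#' rates are clamped to `[0, 1]`; a draw leaving `alpha + delta > 1` is
#' redrawn (up to 100 times) so the feasible set is sampled uniformly
#' rather than biased by clamping.
#'
#' Sexes not listed in the environment model, and all pre-ZGA rates, are
#' returned untouched.
#'
#' @param sex A [sex_config()].
#' @param env An [env_model()].
#' @return A `sex_config` with (possibly) perturbed post-ZGA rates.
#' @export
perturb_rates <- function(sex, env) {
  if (env$mode == "none" || !(sex$sex %in% env$perturb_sexes)) {
    return(sex)
  }
  post <- sex$post_zga
  if (env$mode == "directional") {
    alpha <- min(max(post$alpha + env$alpha_shift, 0), 1)
    delta <- min(max(post$delta + env$delta_shift, 0), 1)
    if (alpha + delta > 1) {
      stop("directional shift yields alpha + delta > 1", call. = FALSE)
    }
  } else {
    for (attempt in seq_len(100L)) {
      alpha <- post$alpha + stats::runif(1, sex$alpha_env_range[1],
                                         sex$alpha_env_range[2])
      delta <- post$delta + stats::runif(1, sex$delta_env_range[1],
                                         sex$delta_env_range[2])
      alpha <- min(max(alpha, 0), 1)
      delta <- min(max(delta, 0), 1)
      if (alpha + delta <= 1) break
      if (attempt == 100L) {
        stop("could not draw valid perturbed rates in 100 attempts",
             call. = FALSE)
      }
    }
  }
  sex$post_zga <- rate_set(alpha, post$beta, delta, post$zeta)
  sex
}

#' Run the full multi-generation simulation
#'
#' Chains [run_generation()] -> [fertilize()] -> [perturb_rates()]: each
#' generation runs both sexes from a common zygote (generation 1 may start
#' each sex from its own configured state), fertilization averages the two
#' final states into the next zygote, the embryo resets (`N` to `N0`,
#' repressor to `rho0`), and — if an environment model is active — the
#' post-ZGA rates drift before the next generation.
#'
#' @param scn An [scenario()] or [scenario_preset()].
#' @param n_generations Number of generations; defaults to the scenario's.
#' @param seed Optional integer seed making environmental draws (and hence
#'   the whole run) reproducible.
#' @return An object of class `mzt_sim`: a list with
#'   \describe{
#'     \item{trajectory}{long tibble, one row per generation x division x
#'       sex (see [run_generation()] for columns),}
#'     \item{rate_history}{tibble of the post-ZGA rates in effect for each
#'       generation and sex,}
#'     \item{zygotes}{tibble of each generation's starting state per sex,}
#'     \item{scenario, seed}{the inputs, echoed.}
#'   }
#' @examples
#' sim <- run_simulation(scenario_preset("table1_default"))
#' summarize_simulation(sim)
#' @export
run_simulation <- function(scn, n_generations = NULL, seed = NULL) {
  stopifnot(inherits(scn, "mzt_scenario"))
  n_gen <- as.integer(n_generations %||% scn$n_generations)
  stopifnot(n_gen >= 1)
  if (!is.null(seed)) set.seed(seed)

  sexes <- list(male = scn$male, female = scn$female)
  base_sexes <- sexes
  zyg <- scn$initial
  traj <- vector("list", n_gen)
  rates <- vector("list", n_gen)
  zygs <- vector("list", n_gen)

  for (g in seq_len(n_gen)) {
    rates[[g]] <- dplyr::bind_rows(lapply(c("male", "female"), function(s) {
      dplyr::bind_cols(tibble::tibble(generation = g, sex = s),
                       sexes[[s]]$post_zga)
    }))
    zygs[[g]] <- dplyr::bind_rows(lapply(c("male", "female"), function(s) {
      dplyr::bind_cols(tibble::tibble(generation = g, sex = s), zyg[[s]])
    }))
    gen <- run_generation(zyg, scn$growth, sexes, generation = g)
    traj[[g]] <- gen

    if (g < n_gen) {
      final <- dplyr::filter(gen, .data$division == scn$growth$D)
      zygote <- fertilize(
        dplyr::select(dplyr::filter(final, .data$sex == "male"),
                      "X", "Y", "Z"),
        dplyr::select(dplyr::filter(final, .data$sex == "female"),
                      "X", "Y", "Z"),
        division = scn$growth$D, D = scn$growth$D
      )
      zyg <- list(male = zygote, female = zygote)
      from <- if (scn$env$accumulate) sexes else base_sexes
      sexes <- list(male = perturb_rates(from$male, scn$env),
                    female = perturb_rates(from$female, scn$env))
    }
  }

  structure(
    list(trajectory = dplyr::bind_rows(traj),
         rate_history = dplyr::bind_rows(rates),
         zygotes = dplyr::bind_rows(zygs),
         scenario = scn, n_generations = n_gen, seed = seed),
    class = "mzt_sim"
  )
}

#' @export
print.mzt_sim <- function(x, ...) {
  cat("<mzt_sim>", x$scenario$name, "--", x$n_generations,
      "generation(s) x", x$scenario$growth$D, "divisions x 2 sexes\n")
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  print(utils::tail(summarize_simulation(x), 4L))
  invisible(x)
}

#' Per-generation, per-sex summary of a simulation
#'
#' For each generation and sex: the final methylation composition, the ZGA
#' onset division, the division at which the methylation level settles at
#' its equilibrium (the post-ZGA fixed point rounded to the reporting
#' accuracy of 0.01; see [divisions_to_equilibrium()]), and the division at
#' which the cell count first rounds to the equilibrium number `K`.
#'
#' @param sim An `mzt_sim`.
#' @param tol Half-width used for equilibrium detection.
#' @return A tibble with one row per generation x sex.
#' @export
summarize_simulation <- function(sim, tol = 0.005) {
  stopifnot(inherits(sim, "mzt_sim"))
  gr <- sim$scenario$growth
  purrr::map_dfr(seq_len(sim$n_generations), function(g) {
    purrr::map_dfr(c("male", "female"), function(s) {
      rows <- dplyr::filter(sim$trajectory, .data$generation == g,
                            .data$sex == s)
      rts <- dplyr::filter(sim$rate_history, .data$generation == g,
                           .data$sex == s)
      fp <- fixed_point(rts$alpha, rts$beta, rts$delta, rts$zeta)
      target <- round(fp$X_star, 2)
      final <- rows[nrow(rows), ]
      tibble::tibble(
        generation = g, sex = s,
        X_final = final$X, Y_final = final$Y, Z_final = final$Z,
        X_star = fp$X_star,
        zga_onset = zga_onset_trajectory(rows, gr),
        divisions_to_equilibrium =
          divisions_to_equilibrium(rows, sex = s, target = target,
                                   tol = tol, generation = g),
        cell_count_equilibrium =
          { hit <- which(rows$N >= gr$K - 0.5); if (length(hit)) hit[1]
            else NA_integer_ }
      )
    })
  })
}
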