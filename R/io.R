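#' Load a scenario from a YAML or JSON configuration file
#'
#' Keys omitted from the file are filled from the `"table1_default"`
#' preset; unknown keys are rejected by name rather than silently ignored,
#' and all scenario invariants are re-validated, so an empty file yields
#' exactly the default scenario.
#'
#' The configuration schema mirrors [as_scenario_list()]: top-level keys
#' `name`, `n_generations`, `growth`, `male`, `female`, `env`, `initial`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `mzt_scenario`.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg)) cfg <- list()
  scenario_from_list(cfg)
}

#' Serialize a scenario to YAML
#'
#' @param scn An `mzt_scenario`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [load_scenario()]; `load_scenario(write_scenario(s, f))`
#'   reconstructs `s`.
#' @export
write_scenario <- function(scn, path) {
  stopifnot(inherits(scn, "mzt_scenario"))
  yaml::write_yaml(as_scenario_list(scn), path, precision = 15L)
  invisible(path)
}

#' Represent a scenario as a plain nested list
#'
#' The list form used by the configuration files: per-sex rates are flat
#' keys `alpha0..zeta0` (pre-ZGA) and `alpha1..zeta1` (post-ZGA), with
#' `alpha_env`/`delta_env` intervals; initial states are `[X, Y, Z]`
#' triples.
#'
#' @param scn An `mzt_scenario`.
#' @return A nested list suitable for [yaml::write_yaml()].
#' @export
as_scenario_list <- function(scn) {
  sex_list <- function(sc) {
    list(alpha0 = sc$pre_zga$alpha, beta0 = sc$pre_zga$beta,
         delta0 = sc$pre_zga$delta, zeta0 = sc$pre_zga$zeta,
         alpha1 = sc$post_zga$alpha, beta1 = sc$post_zga$beta,
         delta1 = sc$post_zga$delta, zeta1 = sc$post_zga$zeta,
         alpha_env = sc$alpha_env_range, delta_env = sc$delta_env_range)
  }
  list(
    name = scn$name,
    n_generations = scn$n_generations,
    growth = scn$growth[setdiff(names(scn$growth), NULL)],
    male = sex_list(scn$male),
    female = sex_list(scn$female),
    env = list(mode = scn$env$mode, perturb_sexes = scn$env$perturb_sexes,
               accumulate = scn$env$accumulate,
               alpha_shift = scn$env$alpha_shift,
               delta_shift = scn$env$delta_shift),
    initial = list(male = as.numeric(scn$initial$male[1, ]),
                   female = as.numeric(scn$initial$female[1, ]))
  )
}

scenario_from_list <- function(cfg) {
  defaults <- as_scenario_list(scenario_preset("table1_default"))
  check_keys <- function(given, allowed, where) {
    extra <- setdiff(names(given), allowed)
    if (length(extra)) {
      stop("unknown configuration key", if (length(extra) > 1) "s", " in ",
           where, ": ", paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  check_keys(cfg, names(defaults), "config")
  for (section in c("growth", "male", "female", "env", "initial")) {
    if (!is.null(cfg[[section]])) {
      check_keys(cfg[[section]], names(defaults[[section]]), section)
    }
  }
  merged <- utils::modifyList(defaults, cfg)

  build_sex <- function(lbl) {
    s <- merged[[lbl]]
    sex_config(lbl,
               pre_zga = rate_set(s$alpha0, s$beta0, s$delta0, s$zeta0),
               post_zga = rate_set(s$alpha1, s$beta1, s$delta1, s$zeta1),
               alpha_env_range = s$alpha_env,
               delta_env_range = s$delta_env)
  }
  gr <- merged$growth
  init <- function(v) methyl_state(v[1], v[2], v[3])
  scenario(
    growth = growth_config(r = gr$r, K = gr$K, rho0 = gr$rho0,
                           rho_deg = gr$rho_deg, rho_power = gr$rho_power,
                           nu_t = gr$nu_t, Q_alpha = gr$Q_alpha,
                           Q_beta = gr$Q_beta, Q_delta = gr$Q_delta,
                           Q_zeta = gr$Q_zeta, D = gr$D, N0 = gr$N0),
    male = build_sex("male"), female = build_sex("female"),
    env = env_model(merged$env$mode,
                    perturb_sexes = merged$env$perturb_sexes,
                    accumulate = merged$env$accumulate,
                    alpha_shift = merged$env$alpha_shift,
                    delta_shift = merged$env$delta_shift),
    n_generations = merged$n_generations,
    initial_male = init(merged$initial$male),
    initial_female = init(merged$initial$female),
    name = merged$name
  )
}

trajectory_columns <- c("generation", "division", "sex", "N", "nu", "rho",
                        "rho_c", "mu", "alpha", "beta", "delta", "zeta",
                        "X", "Y", "Z")

#' Write simulation outputs to disk
#'
#' Writes into `dir`: `trajectory.tsv` (long format, one row per
#' generation x division x sex, columns in the fixed order `generation,
#' division, sex, N, nu, rho, rho_c, mu, alpha, beta, delta, zeta, X, Y,
#' Z`, floats at 10 significant digits), `summary.tsv`
#' (from [summarize_simulation()]) and `metadata.json` (scenario echo,
#' seed, package version). Re-running with the same simulation reproduces
#' the files byte for byte.
#'
#' @param sim An `mzt_sim`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_trajectory <- function(sim, dir) {
  stopifnot(inherits(sim, "mzt_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  traj <- dplyr::select(sim$trajectory,
                        dplyr::all_of(trajectory_columns))
  traj <- dplyr::mutate(traj, dplyr::across(dplyr::where(is.double),
                                            ~ signif(.x, 10)))
  files <- c(trajectory = file.path(dir, "trajectory.tsv"),
             summary = file.path(dir, "summary.tsv"),
             metadata = file.path(dir, "metadata.json"))
  readr::write_tsv(traj, files["trajectory"])
  smry <- dplyr::mutate(summarize_simulation(sim),
                        dplyr::across(dplyr::where(is.double),
                                      ~ signif(.x, 10)))
  readr::write_tsv(smry, files["summary"])
  meta <- list(scenario = as_scenario_list(sim$scenario),
               n_generations = sim$n_generations,
               seed = sim$seed,
               package_version = as.character(utils::packageVersion("mztdyn")))
  jsonlite::write_json(meta, files["metadata"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(files)
}

#' Read a trajectory table written by [write_trajectory()]
#'
#' @param path Path to a `trajectory.tsv`.
#' @return A tibble with the documented trajectory columns.
#' @export
read_trajectory <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    generation = "i", division = "i", sex = "c",
    .default = readr::col_double()
  ))
}
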