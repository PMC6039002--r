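# Shared fixtures: canonical scenario objects and random-input generators
# used by the property-style tests.

default_scenario <- function(...) scenario_preset("table1_default", ...)

# scenario whose rates sit at their post-ZGA values from division 1
# (no repressor; nucleocytoplasmic trigger satisfied immediately)
post_zga_scenario <- function(D = 250L, beta_male = 0.04, beta_female = 0.1) {
  scenario(
    growth = growth_config(rho0 = 0, nu_t = 1, D = D),
    male = sex_config("male", rate_set(0.99, beta_male, 0.01, 0)),
    female = sex_config("female", rate_set(0.99, beta_female, 0.01, 0)),
    n_generations = 1L
  )
}

# n random valid methylation states (rows sum to 1)
random_states <- function(n) {
  raw <- matrix(stats::runif(3 * n), ncol = 3)
  raw <- raw / rowSums(raw)
  methyl_state(raw[, 1], raw[, 2], raw[, 3])
}

# n random rate draws honouring alpha + delta <= 1
random_rates <- function(n) {
  alpha <- stats::runif(n)
  tibble::tibble(
    alpha = alpha,
    beta = stats::runif(n),
    delta = stats::runif(n, 0, 1 - alpha),
    zeta = stats::runif(n),
    rho_c = stats::runif(n)
  )
}

# iterate the three-sub-step map at constant rates, vectorized over draws,
# until the state stops moving; independent long-run oracle for fixed points
iterate_map <- function(state, rates, rho_c = 1, tol = 1e-13,
                        max_iter = 2e5L) {
  st <- state
  for (i in seq_len(max_iter)) {
    nxt <- active_demethylate(
      repair_sites(replicate_sites(st), rates$alpha, rates$beta,
                   rates$delta, rho_c),
      rates$zeta)
    if (max(abs(unlist(nxt) - unlist(st))) < tol) return(nxt)
    st <- nxt
  }
  st
}
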