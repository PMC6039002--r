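test_that("fixed point reproduces the gametic equilibria and degenerate cases", {
  expect_equal(fixed_point(0.99, 0.04, 0.01)$X_star, 0.80)
  expect_equal(fixed_point(0.99, 0.1, 0.01)$X_star, 0.1 / 0.11)
  expect_equal(fixed_point(0.5, 0, 0.3)$X_star, 0, tolerance = 1e-10)
  expect_error(fixed_point(0.9, 0.1, 0.2), "exceed")
})

test_that("closed form and iterative solver agree with a long-run oracle", {
  # closed-form branch: alpha + delta = 1, zeta = 0
  set.seed(3)
  alpha <- stats::runif(30, 0.2, 0.999)
  beta <- stats::runif(30)
  for (i in seq_len(30)) {
    fp <- fixed_point(alpha[i], beta[i], 1 - alpha[i])
    expect_identical(fp$iterations, 0L)
    expect_equal(fp$X_star, beta[i] / (1 - alpha[i] + beta[i]))
  }
  # iterative branch against independent vectorized iteration
  set.seed(4)
  rates <- random_rates(40)
  rates$zeta <- rates$zeta * 0.5
  states <- methyl_state(rep(1, 40), rep(0, 40), rep(0, 40))
  oracle <- iterate_map(states, rates)
  for (i in c(1, 5, 12, 27, 40)) {
    fp <- fixed_point(rates$alpha[i], rates$beta[i], rates$delta[i],
                      rates$zeta[i])
    expect_equal(fp$X_star, oracle$X[i], tolerance = 1e-6)
    expect_equal(fp$Y_star, oracle$Y[i], tolerance = 1e-6)
    # one application of the map moves the fixed point < 1e-10
    nxt <- active_demethylate(
      repair_sites(replicate_sites(
        methyl_state(fp$X_star, fp$Y_star, fp$Z_star)),
        rates$alpha[i], rates$beta[i], rates$delta[i], 1),
      rates$zeta[i])
    expect_lt(abs(nxt$X - fp$X_star), 1e-10)
  }
})

test_that("equilibrium detection returns the first division that stays in band", {
  sim <- run_simulation(default_scenario())
  expect_equal(divisions_to_equilibrium(sim, "female", 0.91), 67L)
  expect_equal(divisions_to_equilibrium(sim, "male", 0.80), 91L)
  # a trajectory that starts at the fixed point settles at division 1
  flat <- run_simulation(post_zga_scenario(D = 50L),
                         n_generations = 1L)
  flat$trajectory <- dplyr::mutate(flat$trajectory, X = 0.8)
  expect_equal(divisions_to_equilibrium(flat, "male", 0.8), 1L)
  expect_warning(
    out <- divisions_to_equilibrium(sim, "male", 0.5, generation = 1),
    "never settles")
  expect_true(is.na(out))
})

test_that("ZGA onset follows the repressor-ratio midpoint and its edge cases", {
  sim <- run_simulation(default_scenario())
  expect_equal(zga_onset(sim), 45L)
  expect_equal(zga_onset(sim, generation = 2), 45L)

  frozen <- scenario(growth = growth_config(rho_deg = 0, D = 60L),
                     n_generations = 1L)
  expect_warning(out <- zga_onset(run_simulation(frozen)), "never reached")
  expect_true(is.na(out))

  immediate <- scenario(growth = growth_config(nu_t = 1, D = 10L),
                        n_generations = 1L)
  expect_equal(zga_onset(run_simulation(immediate)), 1L)
})

test_that("parameter-space explorer retains exactly the compatible triples", {
  ps <- explore_parameter_space(0.80, grid_step = 0.05, accuracy = 0.01)
  expect_true(all(abs(ps$X_star - 0.80) <= 0.01))
  # the canonical triple sits on the 0.01 grid
  fine <- explore_parameter_space(0.80, grid_step = 0.01, accuracy = 0.005,
                                  compute_divisions = FALSE)
  hit <- dplyr::filter(fine, alpha == 0.99, beta == 0.04, delta == 0.01)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$X_star, 0.80)

  # target 0: every beta = 0 triple qualifies except the neutral
  # alpha = 1, delta = 0 map, whose equilibrium is not unique
  zero <- explore_parameter_space(0, grid_step = 0.25, accuracy = 1e-9,
                                  compute_divisions = FALSE)
  expect_true(all(zero$beta == 0))
  expect_equal(nrow(zero), sum(outer(seq(0, 1, 0.25), seq(0, 1, 0.25),
                                     "+") <= 1) - 1L)
})

test_that("retained triples re-simulate to their target and stricter targets shrink the set", {
  set.seed(5)
  ps <- explore_parameter_space(0.91, grid_step = 0.05, accuracy = 0.01)
  start <- methyl_state(rep(0.854545, nrow(ps)), rep(0, nrow(ps)),
                        rep(1 - 0.854545, nrow(ps)))
  resim <- iterate_map(start, tibble::tibble(alpha = ps$alpha,
                                             beta = ps$beta,
                                             delta = ps$delta, zeta = 0))
  expect_true(all(abs(resim$X - 0.91) <= 0.01 + 1e-9))

  lo <- explore_parameter_space(0.30, grid_step = 0.05,
                                compute_divisions = FALSE)
  expect_gt(nrow(lo), nrow(ps)) # high levels demand narrower rate ranges
})

test_that("division counts from the explorer match a direct simulation", {
  ps <- explore_parameter_space(0.80, grid_step = 0.01, accuracy = 1e-9)
  row <- dplyr::filter(ps, alpha == 0.99, beta == 0.04, delta == 0.01)
  # directly iterate the constant-rate map from the standard start state
  st <- methyl_state(0.854545, 0, 1 - 0.854545)
  d <- 0L
  repeat {
    d <- d + 1L
    st <- repair_sites(replicate_sites(st), 0.99, 0.04, 0.01, 1)
    if (abs(st$X - 0.8) < 0.005) break
  }
  expect_equal(row$divisions, d)
  # on the alpha + delta = 1 slice the hemi pool empties each division and
  # the gap to equilibrium decays exactly geometrically with factor
  # (alpha - beta); the explorer's counts must match that closed form
  fast <- explore_parameter_space(0.80, grid_step = 0.05, accuracy = 0.01)
  expect_false(any(is.na(fast$divisions)))
  collapsed <- dplyr::filter(fast, alpha + delta == 1)
  expect_gt(nrow(collapsed), 3)
  predicted <- purrr::pmap_int(collapsed, function(alpha, beta, X_star,
                                                  divisions, ...) {
    gap <- abs(0.854545 - X_star)
    lambda <- abs(alpha - beta)
    d <- 0L
    while (gap >= 0.005) {
      gap <- gap * lambda
      d <- d + 1L
    }
    max(d, 1L)
  })
  expect_equal(collapsed$divisions, predicted)
})

test_that("net enzymatic activity scales with the level change, genome size and interval", {
  zf <- methylation_activity(0.85, 0.87, 24.2e6, 2, 2)
  expect_equal(zf$A, 48.4e4)
  expect_equal(methylation_activity(0.8, 0.8, 24.2e6, 2, 5)$A, 0)
  expect_equal(methylation_activity(0.85, 0.87, 24.2e6, 2, 4)$A, zf$A / 2)
  expect_equal(methylation_activity(0.87, 0.85, 24.2e6, 2, 2)$A, -zf$A)
  expect_equal(methylation_activity(0.85, 0.87, 48.4e6, 2, 2)$A, 2 * zf$A)
  expect_error(methylation_activity(0.85, 0.87, 24.2e6, 2, 0), "positive")
})
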