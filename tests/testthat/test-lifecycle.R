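test_that("a generation holds the zygotic level until ZGA, then diverges by sex", {
  sc <- default_scenario()
  gen <- run_generation(sc$initial, sc$growth,
                        list(male = sc$male, female = sc$female))
  expect_equal(nrow(gen), 2 * 250)
  expect_true(all(abs(gen$X + gen$Y + gen$Z - 1) < 1e-12))
  # plateau at the zygotic level for every pre-ZGA division
  pre <- dplyr::filter(gen, division < 40)
  expect_true(all(abs(pre$X - 1) < 1e-12))
  # afterwards each sex heads to its own equilibrium
  final <- dplyr::filter(gen, division == 250)
  expect_equal(final$X[final$sex == "male"], 0.8, tolerance = 1e-4)
  expect_equal(final$X[final$sex == "female"], 0.9090909, tolerance = 1e-4)
  # cell count is nondecreasing and capped at K; repressor nonincreasing
  male <- dplyr::filter(gen, sex == "male")
  expect_true(all(diff(male$N) >= 0) && all(male$N <= 1024))
  expect_true(all(diff(male$rho) <= 0))
})

test_that("a generation shorter than the ZGA onset leaves the zygote state untouched", {
  sc <- default_scenario()
  sc$growth$D <- 30L
  init <- list(male = methyl_state(0.7, 0, 0.3),
               female = methyl_state(0.7, 0, 0.3))
  gen <- run_generation(init, sc$growth,
                        list(male = sc$male, female = sc$female))
  expect_true(all(abs(gen$X - 0.7) < 1e-12))
  expect_true(all(abs(gen$Y) < 1e-12))
})

test_that("constant post-ZGA kinetics converge to the analytic equilibrium", {
  sim <- run_simulation(post_zga_scenario())
  final <- dplyr::filter(tidy(sim), division == 250)
  expect_equal(final$X[final$sex == "male"], 0.8, tolerance = 1e-6)
  expect_equal(final$X[final$sex == "female"], 0.1 / 0.11, tolerance = 1e-6)
})

test_that("fertilization averages parental states and is gated on division D", {
  expect_equal(fertilize(methyl_state(1, 0, 0), methyl_state(0, 0, 1)),
               methyl_state(0.5, 0, 0.5))
  s <- methyl_state(0.3, 0.3, 0.4)
  expect_equal(fertilize(s, s), s)
  expect_equal(
    fertilize(methyl_state(0.8, 0, 0.2),
              methyl_state(0.909091, 0, 0.090909)),
    methyl_state(0.8545455, 0, 0.1454545),
    tolerance = 1e-6
  )
  expect_error(fertilize(s, s, division = 100, D = 250), "not complete")
  expect_silent(fertilize(s, s, division = 250, D = 250))
})

test_that("the generation-2 zygote carries the averaged gametic methylation", {
  sim <- run_simulation(default_scenario())
  z2 <- dplyr::filter(sim$zygotes, generation == 2)
  expect_equal(z2$X, c(0.8545455, 0.8545455), tolerance = 1e-5)
  expect_equal(z2$X[1], z2$X[2]) # both sexes share one zygote
})

test_that("rate perturbation respects its interval, the feasible set, and flags", {
  male <- sex_config("male", rate_set(0.99, 0.04, 0.01, 0),
                     alpha_env_range = c(-0.01, 0.01),
                     delta_env_range = c(-0.01, 0.01))
  expect_identical(perturb_rates(male, env_model("none")), male)
  env_f <- env_model("random", perturb_sexes = "female")
  expect_identical(perturb_rates(male, env_f), male)

  set.seed(99)
  env <- env_model("random")
  draws <- replicate(500, perturb_rates(male, env)$post_zga$alpha)
  expect_true(all(abs(draws - 0.99) <= 0.01 + 1e-12))
  expect_gt(stats::sd(draws), 0)

  # an interval that cannot yield alpha + delta <= 1 errors after redraws
  stuck <- sex_config("male", rate_set(0.99, 0.04, 0.01, 0),
                      alpha_env_range = c(0.2, 0.3),
                      delta_env_range = c(0.2, 0.3))
  set.seed(1)
  expect_error(perturb_rates(stuck, env), "100 attempts")

  shifted <- perturb_rates(male, env_model("directional",
                                           alpha_shift = -0.005,
                                           delta_shift = 0.005))
  expect_equal(shifted$post_zga$alpha, 0.985)
  expect_equal(shifted$post_zga$delta, 0.015)
})

test_that("simulations are deterministic under a fixed seed", {
  sc <- default_scenario(env = env_model("random"), n_generations = 3L)
  sc$growth$D <- 80L
  a <- run_simulation(sc, seed = 42)
  b <- run_simulation(sc, seed = 42)
  expect_identical(a$trajectory, b$trajectory)
  c <- run_simulation(sc, seed = 43)
  expect_false(identical(b$rate_history, c$rate_history))
})

test_that("without environmental variation the generations settle into a steady cycle", {
  # rates are constant, so successive generation records contract toward a
  # fixed transgenerational cycle at ~(alpha - beta)^(D - onset) ~ 3e-5
  # per generation: generation 2 vs 3 differ only through residual
  # convergence memory, and 3 vs 4 by ~3e-5 times less again
  sc <- default_scenario(n_generations = 4L)
  sim <- run_simulation(sc)
  expect_equal(dplyr::n_distinct(dplyr::select(sim$rate_history,
                                               -generation)), 2L)
  X <- lapply(2:4, function(g) {
    dplyr::filter(tidy(sim), generation == g)$X
  })
  d23 <- max(abs(X[[1]] - X[[2]]))
  d34 <- max(abs(X[[2]] - X[[3]]))
  expect_lt(d23, 1e-5)
  expect_lt(d34, 1e-9)
  expect_lt(d34, d23 / 100)
})

test_that("perturbing one sex never touches the other sex's rates", {
  sc <- default_scenario(env = env_model("random", perturb_sexes = "female"),
                         n_generations = 6L)
  sc$growth$D <- 60L
  sim <- run_simulation(sc, seed = 7)
  male_rates <- dplyr::filter(sim$rate_history, sex == "male")
  expect_true(all(male_rates$alpha == 0.99 & male_rates$delta == 0.01))
  female_rates <- dplyr::filter(sim$rate_history, sex == "female")
  expect_gt(stats::sd(female_rates$alpha), 0)
})
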