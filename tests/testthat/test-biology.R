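test_that("mortality and linear rate laws evaluate to their printed values", {
  expect_equal(mortality_pvortex(5, 0), 0)
  expect_equal(mortality_pvortex(0, 2), 0.6)
  expect_equal(mortality_pvortex(1, 1), 0.06)
  expect_equal(mortality_ecoli(0), 1)
  # decreasing in n over [0, n0]
  n <- seq(0, 2, by = 0.1)
  expect_true(all(diff(mortality_ecoli(n)) < 0))
  expect_lt(mortality_ecoli(1e6), 1e-6)
  expect_equal(linear_rate(0, 0.7), 0)
  expect_equal(linear_rate(2, 0.9), 1.8)
})

test_that("default parameters carry the standard table and validate", {
  p <- default_params()
  expect_equal(p$D1_explore, 0.35)
  expect_equal(p$D1_build, 0.0125)
  expect_equal(p$C2, 6)
  expect_equal(p$bbar_max, 0.033)
  expect_equal(p$bbar_min, 0.007)
  p3 <- default_params(three_species = TRUE)
  expect_equal(p3$n0, 0.5)
  expect_equal(p3$bbar_max, 0.04)
  expect_equal(p3$CX, 10)
  expect_error(default_params(bbar_min = 0.05), "bbar_min")
  expect_error(default_params(lambda1 = -1), "non-negative")
  expect_error(default_params(nonsense = 1), "unknown")
  expect_warning(default_params(D2 = 0.2), "D2")
})

test_that("phase coefficients swap jointly at a switch", {
  p <- default_params()
  b <- phase_coeffs(p, "builder"); e <- phase_coeffs(p, "explorer")
  expect_equal(b, list(D1 = 0.0125, beta1 = 0.9, k = 1))
  expect_equal(e, list(D1 = 0.35, beta1 = 0.7, k = 0))
})

test_that("mean colony density averages over the support only", {
  m <- get_mesh(10, seed = 2)
  cfg <- phase_config()
  n <- nrow(m$nodes)
  expect_equal(mean_colony_density(rep(0.5, n), NULL, cfg, m), 0.5)
  empty <- mean_colony_density(rep(1e-8, n), NULL, cfg, m)
  expect_equal(as.numeric(empty), 0)
  expect_true(attr(empty, "empty_support"))
  # half the domain at 0.04, rest zero: support excludes the zeros
  b <- ifelse(m$nodes[, 1] < 5, 0.04, 0)
  expect_equal(mean_colony_density(b, NULL, cfg, m), 0.04)
  # b1_plus_b2 rule uses the summed density
  cfg2 <- phase_config(rule = "b1_plus_b2")
  expect_equal(cfg2$bbar_min, 0.029)
  expect_equal(cfg2$bbar_max, 0.066)
  expect_equal(mean_colony_density(rep(0.02, n), rep(0.03, n), cfg2, m), 0.05)
  expect_error(mean_colony_density(rep(0.02, n), NULL, cfg2, m), "b2")
})

test_that("the phase switch is hysteretic at the table thresholds", {
  cfg <- phase_config()
  expect_identical(phase_update(0.02, "builder", cfg), "builder")
  expect_identical(phase_update(0.02, "explorer", cfg), "explorer")
  expect_identical(phase_update(0.034, "builder", cfg), "explorer")
  expect_identical(phase_update(0.033, "builder", cfg), "builder")
  expect_identical(phase_update(0.006, "explorer", cfg), "builder")
  expect_identical(phase_update(0.007, "explorer", cfg), "explorer")
})

test_that("dead-mass accumulation preserves live + dead under pure death", {
  m <- get_mesh(8, seed = 2)
  # n = 0 kills reproduction; uniform fields kill diffusion
  st <- model_state(m, b1 = 0.4, b2 = 0.3, n = 0, a = 1)
  tot0 <- total_mass(st$s1 + st$b1, m)
  for (i in 1:200) st <- step_model(st, cfg = integrator_config(dt = 0.01))
  expect_lt(st$b1[1], 0.4)                    # death happened
  expect_true(all(diff(c(0, st$s1[1])) >= 0)) # monotone accumulator
  expect_equal(total_mass(st$s1 + st$b1, m), tot0, tolerance = 1e-12)
  expect_equal(accumulate_dead(1, 2, 0, 0.1), 1)
  expect_equal(accumulate_dead(1, 2, 0.5, 0.1), 1.1)
})

test_that("the model nesting chain holds on random states", {
  m <- get_mesh(8, seed = 3)
  n <- nrow(m$nodes)
  set.seed(11)
  b1 <- runif(n); b2 <- runif(n); nf <- runif(n, 0, 2); af <- runif(n, 0, 2)
  p3 <- default_params(three_species = TRUE)
  p2 <- default_params()

  # three species with X = 0 reduces to two species
  st3 <- model_state(m, b1 = b1, b2 = b2, n = nf, a = af, X = 0, params = p3)
  st2 <- model_state(m, b1 = b1, b2 = b2, n = nf, a = af, params = p3)
  d3 <- rhs_three_species(st3)
  d2 <- rhs_two_species(st2)
  for (f in c("b1", "b2", "n", "a")) expect_equal(d3[[f]], d2[[f]])
  expect_equal(d3$X, rep(0, n))

  # two species with b2 = 0, a = 0 reduces to the single-species model
  st2b <- model_state(m, b1 = b1, b2 = 0, n = nf, a = 0, params = p2)
  st1 <- model_state(m, b1 = b1, n = nf, a = 0, params = p2)
  d2b <- rhs_two_species(st2b)
  d1 <- rhs_single(st1)
  expect_equal(d2b$b1, d1$b1)
  expect_equal(d2b$n, d1$n)
  expect_equal(d2b$b2, rep(0, n))

  # rX = 0 removes the algal growth enhancement
  p0 <- default_params(three_species = TRUE, rX = 0)
  st30 <- model_state(m, b1 = b1, b2 = b2, n = nf, a = af,
                      X = runif(n), params = p0)
  d30 <- rhs_three_species(st30)
  st20 <- model_state(m, b1 = b1, b2 = b2, n = nf, a = af, params = p0)
  d20 <- rhs_two_species(st20)
  expect_equal(d30$b1 - d20$b1, rep(0, n), tolerance = 1e-14)
})

test_that("algae mass decays at rate muX without nutrients", {
  m <- get_mesh(8, seed = 3)
  p3 <- default_params(three_species = TRUE)
  st <- model_state(m, b1 = 0, b2 = 0, n = 0, a = 0, X = 0.5, params = p3)
  for (i in 1:100) st <- step_model(st, cfg = integrator_config(dt = 0.01))
  expect_equal(st$X[1], 0.5 * (1 - 0.01 * p3$muX)^100, tolerance = 1e-10)
})

test_that("the literal algae-diffusion variant changes only the X equation", {
  m <- get_mesh(8, seed = 3)
  n <- nrow(m$nodes)
  set.seed(12)
  b1 <- runif(n); b2 <- runif(n); X <- runif(n)
  pA <- default_params(three_species = TRUE)
  pB <- default_params(three_species = TRUE, algae_diffusion_literal = TRUE)
  dA <- rhs_three_species(model_state(m, b1, b2, 1, 1, X = X, params = pA))
  dB <- rhs_three_species(model_state(m, b1, b2, 1, 1, X = X, params = pB))
  expect_equal(dA$b1, dB$b1)
  expect_gt(max(abs(dA$X - dB$X)), 1e-8)
  # the two variants differ exactly by the transport terms applied to b2 - X
  expect_equal(dB$X - dA$X,
               pA$DX * laplacian(b2 - X, m) +
                 nonlinear_divergence(b1, pA$CX * (b2 - X), m),
               tolerance = 1e-12)
})

test_that("antibiotic mass is non-increasing (diffusion conserves, sink only)", {
  m <- get_mesh(16, seed = 4)
  scn <- make_scenario("mixed", horizon = 0.5)
  d <- run_scenario(scn, m, record_every = 50L)
  expect_true(all(diff(d$series$mass_a) <= 1e-12))
})
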