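test_that("the smoothed disk is a C2 radial indicator", {
  m <- get_mesh(32, seed = 1)
  d <- smoothed_disk(m, r0 = 6, band = 2)
  ctr <- m$domain / 2
  r <- sqrt((m$nodes[, 1] - ctr[1])^2 + (m$nodes[, 2] - ctr[2])^2)
  expect_equal(max(d), 1)
  expect_true(all(d[r < 4.9] == 1))
  expect_true(all(d[r > 7.1] == 0))
  # radial monotonicity of the ramp
  o <- order(r)
  expect_true(all(diff(d[o]) <= 1e-12))
  # C2 smoothness of the ramp polynomial: value/derivative/curvature vanish
  # at s = 0 and level off at s = 1 (numeric differentiation)
  s <- c(1e-5, 1 - 1e-5)
  f <- vortexsim:::ramp_c2
  d1 <- (f(s + 1e-5) - f(s - 1e-5)) / 2e-5
  d2 <- (f(s + 1e-5) - 2 * f(s) + f(s - 1e-5)) / 1e-10
  expect_lt(abs(d1[1]), 1e-6); expect_lt(abs(d1[2] - 0), 1e-3)
  expect_lt(abs(d2[1]), 1e-2); expect_lt(abs(d2[2]), 1e-2)
})

test_that("the scenario catalogue builds the documented initial states", {
  m <- get_mesh(32, seed = 1)
  p <- default_params()
  pv <- make_scenario("pv_only")$init(m)
  expect_equal(sum(pv$b2), 0)
  ec <- make_scenario("ec_only")$init(m)
  expect_equal(sum(ec$b1), 0)
  expect_gt(total_mass(ec$b2, m), 0)

  mx <- make_scenario("mixed")
  icm <- mx$init(m)
  expect_equal(icm$b1, icm$b2)
  # mean over the support is ~1 (slightly below, from the smoothing ramp)
  bb <- mean_colony_density(icm$b1, icm$b2, mx$phase_cfg, m)
  expect_gt(bb, 0.7); expect_lte(bb, 1)

  hp <- make_scenario("half_plane_antibiotic")$init(m)
  right <- m$nodes[, 1] > m$domain[1] / 2 + 2 * m$h
  expect_equal(sum(hp$a[right]), 0)               # no antibiotic on the right
  left <- m$nodes[, 1] < m$domain[1] / 2 - 2 * m$h
  expect_true(all(hp$a[left] == 1))

  tc <- make_scenario("two_colonies")$init(m)
  lab <- vortexsim:::components_cpp(nrow(m$nodes), m$edges$i, m$edges$j,
                                    tc$b1 > 1e-6)
  expect_equal(max(lab), 2)

  ts <- make_scenario("three_species")
  expect_true(ts$params$three_species)
  expect_equal(ts$params$n0, 0.5)
  expect_equal(ts$init(m)$X, ts$init(m)$b1)

  s2 <- make_scenario("s2_rule")
  expect_identical(s2$phase_cfg$rule, "b1_plus_b2")
  expect_equal(s2$phase_cfg$bbar_max, 0.066)
})

test_that("colony_radius matches its definition", {
  m <- get_mesh(32, seed = 1)
  d <- smoothed_disk(m, r0 = 6)
  # support reaches r0 + band/2 = 7; the 95th percentile sits just inside
  r <- colony_radius(d, NULL, m)
  expect_gt(r, 6.5); expect_lt(r, 7.1)
  expect_equal(colony_radius(rep(0, nrow(m$nodes)), NULL, m), 0)
  # two disjoint disks: radius covers both (documented behavior)
  tc <- make_scenario("two_colonies")$init(m)
  r2 <- colony_radius(tc$b1, tc$b2, m, center = colMeans(tc$centers))
  expect_gt(r2, 0.18 * m$domain[1])
})

test_that("cross sections and radial profiles respect symmetry", {
  m <- get_mesh(32, seed = 1)
  ctr <- m$domain / 2
  r2 <- (m$nodes[, 1] - ctr[1])^2 + (m$nodes[, 2] - ctr[2])^2
  g <- exp(-r2 / 50)
  for (ang in c(0, pi / 3)) {
    cs <- cross_section(g, m, angle = ang)
    expect_equal(cs$value, exp(-cs$s^2 / 50), tolerance = 0.02)
  }
  flat <- cross_section(rep(2, nrow(m$nodes)), m)
  expect_true(all(flat$value == 2))
  rp <- radial_profile(rep(3, nrow(m$nodes)), m)
  expect_equal(rp$value, rep(3, nrow(rp)), tolerance = 1e-12)
  rpg <- radial_profile(g, m, nbins = 24, rmax = 14)
  expect_equal(rpg$value, exp(-rpg$r^2 / 50), tolerance = 0.05)
})

test_that("count_rings counts alternating bands", {
  r <- seq(0.5, 29.5, by = 1)
  flat <- data.frame(r = r, value = rep(1, 30))
  expect_equal(count_rings(flat, smooth = 0), 1L)
  blob <- data.frame(r = r, value = exp(-r / 5))
  expect_equal(count_rings(blob, smooth = 0), 1L)
  # four positive lobes of a clipped cosine over [0.5, 29.5], period 9.54
  four <- data.frame(r = r, value = pmax(cos(r / 4.77 * pi), 0))
  expect_equal(count_rings(four, smooth = 0), 4L)
  none <- data.frame(r = r, value = rep(0, 30))
  expect_equal(count_rings(none, smooth = 0), 0L)
})

test_that("run_scenario produces consistent, deterministic diagnostics", {
  m <- get_mesh(32, seed = 1)
  scn <- make_scenario("mixed", horizon = 0.4)
  d1 <- run_scenario(scn, m, record_every = 100L,
                     snapshot_times = c(0.2, 0.4))
  expect_s3_class(d1, "colony_diagnostics")
  expect_equal(nrow(d1$series), 5)                   # t = 0 + 4 records
  expect_equal(length(d1$snapshots), 2)
  expect_equal(d1$snapshots[[2]]$t, 0.4, tolerance = 1e-12)
  expect_true(all(is.finite(d1$snapshots[[1]]$accumulated)))
  # bit-identical re-run (determinism contract)
  d2 <- run_scenario(scn, m, record_every = 100L,
                     snapshot_times = c(0.2, 0.4))
  expect_identical(d1$series, d2$series)
  expect_identical(d1$state$b1, d2$state$b1)
})

test_that("the Crank-Nicolson scenario path agrees with forward Euler", {
  m <- get_mesh(16, seed = 4)
  scn <- make_scenario("mixed", horizon = 0.05)
  fe <- run_scenario(scn, m, record_every = 10L)
  cn <- run_scenario(scn, m,
                     cfg = integrator_config(dt = 0.005,
                                             scheme = "crank_nicolson",
                                             gs_tol = 1e-12),
                     record_every = 2L)
  expect_true(all(is.finite(cn$state$b1)))
  # short-horizon solutions of the two schemes agree to leading order
  expect_lt(max(abs(cn$state$b1 - fe$state$b1)), 5e-3)
  expect_lt(max(abs(cn$state$n - fe$state$n)), 5e-3)
  expect_error(
    run_scenario(make_scenario("two_colonies", horizon = 0.01), m,
                 cfg = integrator_config(scheme = "crank_nicolson")),
    "forward-Euler")
})

test_that("two-colony bookkeeping tracks components until the merge", {
  m <- get_mesh(32, seed = 1)
  d <- run_scenario(make_scenario("two_colonies", horizon = 0.2), m,
                    record_every = 20L)
  expect_equal(d$series$ncomp[1], 2L)
  sm <- synchronization_metric(d)
  expect_true(sm$merged)
  expect_true(all(d$series$ncomp[d$series$t >= sm$t_merge] == 1L))
})

test_that("identical twin colonies keep identical phases by symmetry", {
  # both components see the same initial data, so their per-component
  # phases can never diverge and the global phase is never 'mixed'
  m <- get_mesh(32, seed = 1)
  d <- run_scenario(make_scenario("two_colonies", horizon = 0.1), m,
                    record_every = 10L)
  expect_false(any(d$series$phase == "mixed"))
})

test_that("the sensitivity perturbations carry the stated magnitudes", {
  p <- s1_perturbations()
  expect_equal(p$a0_minus$a0, 1)       # -50% of 2
  expect_equal(p$a0_plus$a0, 3)        # +50%
  expect_equal(p$bbarmax_plus$bbar_max, 0.0396, tolerance = 1e-12)
  expect_equal(p$C2_minus$C2, 4)
  expect_equal(p$D2_plus$D2, 1.2e-4)
  expect_equal(length(p), 10)
})
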