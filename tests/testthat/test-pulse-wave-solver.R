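test_that("the rest state is a fixed point of the time stepper", {
  net <- desk_net()
  wf <- zero_wave()
  cfg <- desk_config(net, wf, elements = 2, degree = 2)
  st <- dg_step(net, wf, cfg, n_steps = 400)
  expect_lt(max(abs(st$uh)), 1e-12)
  # area coefficients: constant mode stores A0 / phi0, higher modes stay 0
  Np <- cfg$degree + 1
  A0 <- rep(net$arteries$area, each = cfg$elements)
  const_mode <- st$Ah[seq(1, length(st$Ah), by = Np)]
  expect_lt(max(abs(const_mode * drop(legendre_basis(0, 0)) - A0) / A0), 1e-12)
})

test_that("zero inflow leaves every sensor record at zero", {
  net <- desk_net()
  wf <- zero_wave()
  cfg <- desk_config(net, wf)
  sim <- simulate_flow(net, wf, cfg, sensor_config(c(1, 6, 7), "end"))
  expect_equal(max(abs(sim$velocity)), 0, tolerance = 1e-12)
})

test_that("discrete mass change equals the accumulated boundary flux", {
  # frictionless single vessel: the scheme is locally conservative, so the
  # total volume change must match the AB2-weighted boundary-flux integral
  net <- single_artery_net(fluid = blood_fluid(viscosity = 0))
  wf <- desk_wave()
  cfg <- desk_config(net, wf, elements = 4, degree = 2)
  v_init <- with(net$arteries, sum(area * length))  # exact rest volume
  st <- dg_step(net, wf, cfg, n_steps = 100)
  expect_equal(state_volume(st, net, cfg) - st$mass_influx, v_init,
               tolerance = 1e-12)

  # on a branching network the identity additionally absorbs the junction
  # mass imbalance, which the Newton solve keeps at roundoff
  net7 <- desk_net()
  cfg7 <- desk_config(net7, wf, elements = 2, degree = 2)
  stA <- dg_step(net7, wf, cfg7, n_steps = 600)
  v7 <- with(net7$arteries, sum(area * length))
  expect_equal(state_volume(stA, net7, cfg7) - stA$mass_influx, v7,
               tolerance = 1e-9)
  expect_lt(stA$diagnostics$junction_mass_residual, 1e-10)
})

test_that("junction coupling satisfies the physical conditions", {
  rho <- 1060
  A0 <- c(6e-6, 3.5e-6, 3e-6)
  B <- c(2e7, 3e7, 3.2e7)
  c0 <- sqrt(B / (2 * rho)) * A0^0.25

  # rest characteristics reproduce the rest state
  sol <- junction_solve(A0, B, W1_parent = 4 * c0[1],
                        W2_children = -4 * c0[2:3], density = rho)
  expect_equal(sol$area, A0, tolerance = 1e-10)
  expect_equal(sol$velocity, rep(0, 3), tolerance = 1e-10)

  # identical daughters with identical data get identical states
  A0s <- c(6e-6, 3e-6, 3e-6); Bs <- c(2e7, 3e7, 3e7)
  c0s <- sqrt(Bs / (2 * rho)) * A0s^0.25
  sol <- junction_solve(A0s, Bs, W1_parent = 4 * c0s[1] + 0.4,
                        W2_children = -4 * c0s[2:3] + 0.1, density = rho)
  expect_equal(sol$area[2], sol$area[3])
  expect_equal(sol$velocity[2], sol$velocity[3])

  # randomized physical trials: plug the solution back into the printed
  # coupling conditions and check the residuals in SI units
  set.seed(99)
  for (k in 1:20) {
    W1 <- 4 * c0[1] + runif(1, -0.5, 0.8)
    W2 <- -4 * c0[2:3] + runif(2, -0.5, 0.5)
    sol <- junction_solve(A0, B, W1, W2, density = rho)
    A <- sol$area; u <- sol$velocity
    expect_lt(abs(A[1] * u[1] - A[2] * u[2] - A[3] * u[3]), 1e-10)
    p <- B * (sqrt(A) - sqrt(A0))
    expect_lt(abs(p[1] + rho * u[1]^2 / 2 - p[2] - rho * u[2]^2 / 2), 1e-7)
    expect_lt(abs(p[1] + rho * u[1]^2 / 2 - p[3] - rho * u[3]^2 / 2), 1e-7)
    # outgoing characteristics are held exactly
    cs <- sqrt(B / (2 * rho)) * A^0.25
    expect_equal(u[1] + 4 * cs[1], W1, tolerance = 1e-10)
    expect_equal(u[2:3] - 4 * cs[2:3], W2, tolerance = 1e-10)
  }
})

test_that("the terminal boundary is absorbing", {
  # travelling-pulse regime: a narrow pulse (width ~0.3 m) in a long
  # frictionless vessel passes the midpoint at ~0.31 s and exits at ~0.6 s;
  # a reflected wave would return to the midpoint around 0.9 s
  net <- artery_network(
    data.frame(id = 1, parent = 0, length = 3, area = 5e-6,
               stiffness = 2 * 1060 * 25 / sqrt(5e-6)),
    fluid = blood_fluid(viscosity = 0))
  wf <- inflow_waveform(period = 1.2, n_cycles = 1, peak = 0.3,
                        systole_fraction = 0.05, n_harmonics = 64)
  cfg <- desk_config(net, wf, elements = 24, degree = 2,
                     final_time = 1.2, sample_period = 0.004)
  sim <- simulate_flow(net, wf, cfg, sensor_config(1, "1.5"))
  v <- sim$velocity[, 1]
  t <- sim$times
  peak <- max(abs(v))
  expect_gt(peak, 0.2)
  expect_lt(max(abs(v[t > 0.8])), 0.01 * peak)
})

test_that("the inflow waveform is periodic and bounded", {
  wf <- desk_wave()
  t <- seq(0, 1.1, length.out = 57)
  expect_equal(waveform_velocity(wf, t), waveform_velocity(wf, t + wf$period),
               tolerance = 1e-12)
  expect_lt(max(abs(waveform_velocity(wf, t))), 1)
})

test_that("sampling bookkeeping and determinism hold", {
  net <- single_artery_net()
  wf <- inflow_waveform(n_cycles = 3)
  cfg <- desk_config(net, wf, elements = 1, degree = 1, final_time = 3.328)
  sens <- sensor_config(1, "end")
  sim1 <- simulate_flow(net, wf, cfg, sens)
  expect_equal(nrow(sim1$velocity), 52)
  expect_equal(sim1$times[1], 0.064)
  expect_equal(diff(sim1$times), rep(0.064, 51), tolerance = 1e-12)
  sim2 <- simulate_flow(net, wf, cfg, sens)
  expect_identical(sim1$velocity, sim2$velocity)
})

test_that("solution self-converges under mesh refinement", {
  net <- single_artery_net(length = 0.24)
  wf <- pulse_wave()
  xs <- seq(0.005, 0.235, length.out = 60)
  sol_at <- function(ne) {
    cfg <- resolve_solver(solver_config(elements = ne, degree = 2, cfl = 0.25,
                                        final_time = 0.192), net, wf)
    st <- dg_step(net, wf, cfg, n_steps = cfg$n_steps)
    evaluate_field(st, net, cfg, 1, xs)
  }
  ref <- sol_at(16)
  errs <- sapply(c(2, 4, 8), function(ne) sqrt(mean((sol_at(ne) - ref)^2)))
  expect_true(all(diff(errs) < 0))
})

test_that("downstream sensors are sensitive to a stiffness defect", {
  net <- desk_net()
  wf <- desk_wave()
  cfg <- desk_config(net, wf)
  sens <- sensor_config(c(1, 7), "end")
  v0 <- simulate_flow(net, wf, cfg, sens)$velocity
  v1 <- simulate_flow(apply_defect(net, defect_spec(6, "stiffness", 0.5)),
                      wf, cfg, sens)$velocity
  expect_gt(max(abs(v0 - v1)), 1e-3)
})

test_that("blow-ups and CFL violations raise informative errors", {
  net <- desk_net()
  wf <- desk_wave()
  d <- apply_defect(net, defect_spec(6, "area", 0.02))
  cfg <- desk_config(net, wf)
  expect_error(simulate_flow(d, wf, cfg, sensor_config(1, "end")),
               "blow-up.*artery")
  big <- solver_config(elements = 1, degree = 1, dt = 0.016,
                       check_cfl_every = 10)
  expect_error(simulate_flow(net, wf, resolve_solver(big, net, wf),
                             sensor_config(1, "end")),
               "CFL|blow-up")
  expect_error(simulate_flow(net, wf, cfg, sensor_config(42, "end")),
               "unknown artery")
})
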