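test_that("history buffer has capacity round(L/dt) + 1 and honors the mode", {
  p <- model_params()
  s <- state_vector(B = 1e8, R = 1e7, P_G = 1e4, P_W = 1e3, E = 5)
  spec <- simulation_spec(p, s, t_end = 1, dt = 1e-3)
  buf <- initialize_history(spec)
  expect_identical(nrow(buf$states), 10001L)
  expect_true(all(t(buf$states) == unname(s)))
  spec0 <- simulation_spec(p, s, t_end = 1, dt = 1e-3,
                           history_mode = "zero-phage")
  buf0 <- initialize_history(spec0)
  past <- buf0$states[1:10000, ]
  expect_true(all(past[, c("P_G", "P_W", "I_G", "I_W")] == 0))
  expect_true(all(past[, "B"] == s[["B"]] & past[, "E"] == s[["E"]]))
  expect_equal(current_state(buf0), s)  # the t = 0 record keeps the phage
})

test_that("dt must divide the lysis time", {
  p <- model_params()
  s <- state_vector(B = 1e6)
  expect_error(simulation_spec(p, s, t_end = 10, dt = 0.0007), "divide")
  expect_error(simulation_spec(p, s, t_end = 10, dt = 0.003), "divide")
  expect_silent(simulation_spec(p, s, t_end = 10, dt = 1e-3))
  expect_message(simulation_spec(p, s, t_end = 10, dt = 0.01), "coarser")
})

test_that("a single Euler step reproduces hand-computed updates", {
  # zero state is absorbing
  p <- model_params()
  spec <- simulation_spec(p, state_vector(), t_end = 1, dt = 1e-3)
  buf <- euler_step(initialize_history(spec), p)
  expect_true(all(current_state(buf) == 0))

  # pure washout decay of phage when adsorption is off
  pk0 <- model_params(k = 0)
  spec <- simulation_spec(pk0, state_vector(P_G = 1e6), t_end = 1, dt = 1e-3)
  buf <- euler_step(initialize_history(spec), pk0)
  expect_equal(current_state(buf)[["P_G"]], 1e6 * (1 - 0.05 * 1e-3))

  # full-state step equals current + dt * hand-substituted rates
  pf <- model_params(b_G = 20, b_W = 20)
  s <- state_vector(B = 1e8, R = 1e8, P_G = 1e5, P_W = 1e5)
  spec <- simulation_spec(pf, s, t_end = 1, dt = 1e-3)
  buf <- euler_step(initialize_history(spec), pf)
  expect_equal(current_state(buf), s + 1e-3 * derivative_field(s, s, pf))
})

test_that("compiled integrator agrees with the R-level stepper", {
  p <- model_params()
  s <- state_vector(B = 1e8, R = 1e8, P_G = 1e5, P_W = 1e5, E = 10)
  spec <- suppressMessages(
    simulation_spec(p, s, t_end = 0.5, dt = 0.1, output_thin = 1L))
  traj <- suppressMessages(run_simulation(spec))
  buf <- initialize_history(spec)
  for (i in 1:5) buf <- euler_step(buf, p)
  expect_equal(unname(current_state(buf)),
               as.numeric(traj[6, c("B", "R", "P_G", "P_W",
                                    "I_G", "I_W", "E")]),
               tolerance = 1e-14)
})

test_that("phage-free logistic-washout equilibrium is reached within 1%", {
  p <- model_params()
  spec <- simulation_spec(p, state_vector(B = 1e6), t_end = 2000)
  traj <- run_simulation(spec)
  expect_equal(tail(traj$B, 1), p$C * (1 - p$w / p$v), tolerance = 0.01)
})

test_that("with adsorption off, phage decay matches the closed form to 0.1%", {
  p <- model_params(k = 0)
  spec <- simulation_spec(p, state_vector(P_G = 1e6), t_end = 20)
  traj <- run_simulation(spec)
  expect_equal(tail(traj$P_G, 1), 1e6 * exp(-p$w * 20), tolerance = 1e-3)
})

test_that("identical specs give bit-identical, non-negative trajectories", {
  spec <- simulation_spec(model_params(), default_two_phage_state(),
                          t_end = 200)
  t1 <- run_simulation(spec)
  t2 <- run_simulation(spec)
  expect_identical(t1, t2)
  expect_true(all(as.matrix(t1[, c("B", "R", "P_G", "P_W",
                                   "I_G", "I_W", "E")]) >= 0))
  expect_true(all(diff(t1$time) > 0))
})

test_that("the delayed burst term echoes exactly L minutes after infection", {
  # phage introduced at t = 0 with an empty infection history: the first
  # delayed lysis (and so the first enzyme) appears one step after t = L
  p <- model_params()
  spec <- simulation_spec(p, state_vector(B = 1e8, P_G = 1e6),
                          t_end = 12, history_mode = "zero-phage",
                          output_thin = 1L)
  traj <- run_simulation(spec)
  first_E <- traj$time[min(which(traj$E > 0))]
  expect_equal(first_E, p$L + spec$dt, tolerance = 1e-9)
})

test_that("halving the step from 2e-3 to 1e-3 moves endpoints by < 1%", {
  t_fine <- run_scenario("gm_lower_burst", dt = 1e-3)
  t_coarse <- suppressMessages(run_scenario("gm_lower_burst", dt = 2e-3))
  for (col in c("B", "P_G", "P_W")) {
    a <- tail(t_fine[[col]], 1)
    b <- tail(t_coarse[[col]], 1)
    expect_lt(abs(a - b) / abs(a), 0.01)
  }
})

test_that("exactly symmetric competitions stay pinned at frequency 0.5", {
  p <- apply_burst_preset(model_params(), "equal")
  spec <- simulation_spec(p, default_two_phage_state(), t_end = 1500)
  traj <- run_simulation(spec)
  expect_identical(traj$P_G, traj$P_W)
  expect_true(all(traj$gm_frequency == 0.5))
})

test_that("scenario presets are validated and set phage compositions", {
  expect_error(run_scenario("fig1x"), "arg")
  wild <- run_scenario("wild_alone", t_end = 2)
  expect_true(all(wild$P_G == 0) && any(wild$P_W > 0))
  gm <- run_scenario("gm_alone", t_end = 2)
  expect_true(all(gm$P_W == 0) && any(gm$P_G > 0))
})
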