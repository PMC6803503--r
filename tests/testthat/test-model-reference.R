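test_that("rate functions hit their closed-form anchor points", {
  expect_equal(evaluate_rate("n_inf", -29.5), 0.5)
  expect_equal(evaluate_rate("h_inf", -59.4), 0.5)
  expect_equal(evaluate_rate("m_inf", -34.5), 0.5)
  expect_equal(evaluate_rate("tau_h", -33.5), 0.725)
  expect_equal(evaluate_rate("alpha_M", -20), 0.01)
  # both tau_n branches meet at V = -10: 0.25 + 4.375 e^0
  expect_equal(evaluate_rate("tau_n", -10), 4.625)
  expect_equal(evaluate_rate("tau_n", -10 - 1e-12),
               evaluate_rate("tau_n", -10 + 1e-12), tolerance = 1e-9)
  # removable singularity of beta_c: 0.02u / (u/5) -> 0.1
  expect_equal(evaluate_rate("beta_c", -8.9), 0.1)
  expect_equal(evaluate_rate("beta_c", -8.9 + 1e-5), 0.1, tolerance = 1e-5)
  expect_equal(evaluate_rate("n_inf", 0), 1 / (1 + exp(-2.95)))
  expect_error(evaluate_rate("bogus", 0))
  expect_error(evaluate_rate("n_inf", Inf))
})

test_that("rate functions match the independent oracle on a voltage grid", {
  V <- seq(-100, 40, by = 0.37)
  for (k in rate_kinds())
    expect_equal(evaluate_rate(k, V), oracle_rates[[k]](V), tolerance = 1e-12)
})

test_that("ionic currents follow the conductance forms", {
  p <- purkinje_params()
  # zero driving force kills the potassium current
  s <- neuron_state(V = -95, n = 0.7, h = 0.3, c = 0.2, M = 0.1)
  expect_equal(unname(ionic_currents(s, p)["I_K"]), 0)
  # all gates zero leaves only the leak
  s0 <- neuron_state(V = -50, n = 0, h = 0, c = 0, M = 0)
  cur <- ionic_currents(s0, p)
  expect_equal(unname(cur[c("I_K", "I_Na", "I_Ca", "I_M")]), rep(0, 4))
  expect_equal(unname(cur["I_L"]), 2 * (-50 + 70))
  # a generic state matches term-by-term hand evaluation
  s1 <- neuron_state(V = -40, n = 0.3, h = 0.6, c = 0.1, M = 0.5)
  m <- 1 / (1 + exp(-(-40 + 34.5) / 10))
  expect_equal(unname(ionic_currents(s1, p)),
               c(10 * 0.3^4 * (-40 + 95), 125 * m^3 * 0.6 * (-40 - 50),
                 1 * 0.1^2 * (-40 - 125), 0.75 * 0.5 * (-40 + 95),
                 2 * (-40 + 70)), tolerance = 1e-12)
})

test_that("euler_step matches the hand-computed right-hand side", {
  p <- purkinje_params()
  s <- neuron_state(V = -52.3, n = 0.21, h = 0.47, c = 0.33, M = 0.41)
  expect_equal(unclass(euler_step(s, p, I = -25)), oracle_step(s, p, -25),
               tolerance = 1e-12)
  # leak-only equilibrium is a true fixed point of the V equation
  pl <- purkinje_params(g_K = 0, g_Na = 0, g_Ca = 0, g_M = 0)
  se <- neuron_state(V = -70, n = 0, h = 0, c = 0, M = 0)
  expect_equal(euler_step(se, pl, I = 0)[["V"]], -70)
  # Euler scaling: the step displacement is linear in dt
  for (dt in c(0.004, 0.002, 0.001)) {
    pd <- purkinje_params(dt = dt)
    d <- max(abs(unclass(euler_step(s, pd, -25)) - unclass(s)))
    expect_lt(d, 1.1 * dt * 30) # |RHS| bounded on this state
  }
  expect_error(euler_step(neuron_state(0, 0, 0, 0, 0) * NA))
})

test_that("steady_init puts every gate at its steady state", {
  s <- steady_init(-29.5)
  expect_equal(s[["n"]], 0.5)
  expect_equal(steady_init(-59.4)[["h"]], 0.5)
  s65 <- steady_init(-65)
  ac <- oracle_rates$alpha_c(-65); bc <- oracle_rates$beta_c(-65)
  aM <- oracle_rates$alpha_M(-65); bM <- oracle_rates$beta_M(-65)
  expect_equal(unclass(s65),
               c(V = -65, n = oracle_rates$n_inf(-65),
                 h = oracle_rates$h_inf(-65), c = ac / (ac + bc),
                 M = aM / (aM + bM)), tolerance = 1e-12)
  expect_true(all(unclass(s65)[-1] > 0 & unclass(s65)[-1] < 1))
})

test_that("simulation is deterministic and respects trace invariants", {
  a <- simulate_purkinje(-35, 100, transient_discard = 0)
  b <- simulate_purkinje(-35, 100, transient_discard = 0)
  expect_identical(a$V, b$V) # bit-identical rerun
  expect_equal(unique(round(diff(a$t), 12)), 0.004)
  # duration 0 returns only the initial state
  z <- simulate_purkinje(-35, 0, transient_discard = 0)
  expect_equal(nrow(z), 1)
  expect_equal(z$V, -65)
})

test_that("gates stay in [0,1] and V stays in a finite window along trajectories", {
  for (I in c(-25, -35)) {
    tr <- cached_trace(I, 2200)
    g <- as.matrix(tr[, c("n", "h", "c", "M")])
    expect_true(all(g >= 0 & g <= 1))
    expect_true(all(tr$V > -100 & tr$V < 60))
  }
})
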