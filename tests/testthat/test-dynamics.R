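test_that("leak-only fast subsystem has the analytic fixed point", {
  pl <- purkinje_params(g_K = 0, g_Na = 0, g_Ca = 0, g_M = 0)
  fp <- fast_fixed_points(M = 0.5, I = -25, params = pl)
  # g_L (V - E_L) + I = 0  ->  V = E_L - I/g_L = -57.5
  expect_equal(nrow(fp), 1)
  expect_equal(fp$V, -57.5, tolerance = 1e-6)
  expect_identical(fixed_point_stability(fp$V, 0.5, -25, pl), "attracting")
  # a window containing no sign change is empty
  expect_equal(nrow(fast_fixed_points(0.5, -25, pl, V_window = c(0, 40))), 0)
})

test_that("root count equals an independent dense-grid sign-change count", {
  for (M in c(0.32, 0.40, 0.55)) {
    fp <- fast_fixed_points(M, -33.09485)
    Vg <- seq(-100, 40, by = 0.002) # 5x finer than the scanner
    p <- purkinje_params()
    ninf <- oracle_rates$n_inf(Vg); hinf <- oracle_rates$h_inf(Vg)
    minf <- oracle_rates$m_inf(Vg)
    ac <- oracle_rates$alpha_c(Vg); bc <- oracle_rates$beta_c(Vg)
    cinf <- ac / (ac + bc)
    res <- -(10 * ninf^4 * (Vg + 95) + 125 * minf^3 * hinf * (Vg - 50) +
               cinf^2 * (Vg - 125) + 0.75 * M * (Vg + 95) + 2 * (Vg + 70) +
               (-33.09485))
    expect_equal(nrow(fp), sum(diff(sign(res)) != 0),
                 label = paste("root count at M =", M))
    expect_true(all(abs(fp$residual) < 1e-6))
  }
})

test_that("stability classification agrees with forward simulation", {
  # the depolarized branch at small M is attracting: a clamped simulation
  # started nearby converges to it or to a limit cycle around it; the
  # hyperpolarized fixed point at large M is attracting and quiescent
  env_hi <- limit_cycle_envelope(M = 0.62, I = -33.09485)
  expect_identical(env_hi$type, "fixed_point")
  fp_hi <- fast_fixed_points(0.62, -33.09485, stability = TRUE)
  expect_true("attracting" %in% fp_hi$stability)
  # the clamped fixed-point voltage matches the attracting root
  att <- fp_hi$V[fp_hi$stability == "attracting"]
  expect_lt(min(abs(att - env_hi$V_min)), 0.5)
  # at small M the fast subsystem oscillates
  env_lo <- limit_cycle_envelope(M = 0.40, I = -33.09485)
  expect_identical(env_lo$type, "limit_cycle")
  expect_gt(env_lo$V_max - env_lo$V_min, 20)
})

test_that("stability flips across a detected fold", {
  bd_counts <- vapply(c(0.32, 0.36), function(M)
    nrow(fast_fixed_points(M, -33.09485)), integer(1))
  expect_identical(bd_counts, c(1L, 3L)) # fold between
  fp3 <- fast_fixed_points(0.36, -33.09485, stability = TRUE)
  expect_gt(length(unique(fp3$stability)), 1)
})

test_that("limit-cycle envelope is an attractor property (phase-independent)", {
  # two different sampling phases of the same attracting orbit
  e1 <- limit_cycle_envelope(0.40, -33.09485, duration = 600, discard = 400)
  e2 <- limit_cycle_envelope(0.40, -33.09485, duration = 700, discard = 500)
  expect_equal(e1$V_max, e2$V_max, tolerance = 0.5)
  expect_equal(e1$V_min, e2$V_min, tolerance = 0.5)
})

test_that("bifurcation structure: fold inside the burst's slow-variable range, both backends", {
  Mg <- seq(0.30, 0.60, by = 0.005)
  bd <- bifurcation_diagram(-33.09485, Mg)
  expect_gte(length(bd$folds), 1)
  Mrange <- range(bd$trajectory$M)
  expect_true(any(bd$folds > Mrange[1] & bd$folds < Mrange[2]))
  bfx <- bifurcation_diagram(-33.09485, Mg, backend = "cordic")
  expect_identical(length(bfx$folds), length(bd$folds))
  expect_equal(bfx$folds, bd$folds, tolerance = 0.02)
  # leak-only degenerate model: one straight attracting branch, no folds
  pl <- purkinje_params(g_K = 0, g_Na = 0, g_Ca = 0, g_M = 0)
  bl <- bifurcation_diagram(-25, seq(0.3, 0.6, 0.05), params = pl,
                            trajectory_duration = 300, stability = TRUE)
  expect_equal(length(bl$folds), 0)
  expect_true(all(bl$fixed_points$stability == "attracting"))
  expect_equal(diff(range(bl$fixed_points$V)), 0, tolerance = 1e-6)
})
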