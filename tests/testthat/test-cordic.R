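test_that("angle bases follow the mode definitions", {
  expect_equal(angle_base(cordic_config("linear", iterations = 3)), c(4, 2, 1))
  expect_equal(angle_base(cordic_config("circular", iterations = 1)), pi / 4)
  hyp <- cordic_config("hyperbolic", iterations = 4)
  expect_equal(angle_base(hyp),
               atanh(2^-c(1, 2, 3, 4, 4))) # iteration 4 repeated
})

test_that("hyperbolic convergence bound requires the repeat schedule", {
  # with repeats 4, 13, 40 the angle sum converges to the quoted 1.1182
  expect_equal(max_angle(cordic_config("hyperbolic", iterations = Inf)),
               1.1182, tolerance = 5e-5)
  # without repeats it stalls near 1.056: the bound is unreachable
  no_rep <- cordic_config("hyperbolic", iterations = Inf,
                          repeat_schedule = integer(0))
  expect_lt(max_angle(no_rep), 1.06)
  expect_equal(max_angle(cordic_config("hyperbolic", iterations = 1)),
               atanh(0.5))
  expect_equal(max_angle(cordic_config("linear", iterations = 12)),
               8 * (1 - 2^-12))
})

test_that("rotation reproduces hyperbolic and circular references", {
  hyp <- cordic_config("hyperbolic", iterations = 30)
  Ah <- cordic_gain_of(hyp)
  r <- cordic_rotate(hyp, 1 / Ah, 0, 0.5)
  expect_equal(r$X, cosh(0.5), tolerance = 2^-29)
  expect_equal(r$Y, sinh(0.5), tolerance = 2^-29)
  circ <- cordic_config("circular", iterations = 30)
  Ac <- cordic_gain_of(circ)
  rc <- cordic_rotate(circ, 1 / Ac, 0, pi / 6)
  expect_equal(rc$X, cos(pi / 6), tolerance = 2^-28)
  expect_equal(rc$Y, sin(pi / 6), tolerance = 2^-28)
  # Z0 = 0 only applies the gain
  r0 <- cordic_rotate(hyp, 1, 1, 0)
  expect_equal(r0$Z, 0, tolerance = max_angle(hyp) * 2^-29)
  expect_error(cordic_rotate(hyp, 1, 0, 3), "convergence")
})

test_that("merged exponential core is exactly X+Y of the unmerged rotation", {
  cfg <- cordic_config("hyperbolic", iterations = 10)
  Ah <- cordic_gain_of(cfg)
  set.seed(42)
  z <- runif(1e4, -max_angle(cfg), max_angle(cfg))
  merged <- exp_core_merged(z, cfg)
  rot <- cordic_rotate(cfg, 1 / Ah, 0, z)
  # the identity is exact in real arithmetic; double evaluation of the two
  # differently-associated recursions agrees to rounding error
  expect_lt(max(abs(merged - (rot$X + rot$Y)) / abs(merged)), 1e-13)
  expect_equal(exp_core_merged(0, cfg), 1, tolerance = 2^-10)
})

test_that("gain identity holds on every sign path", {
  # prod(1 + q_i 2^-i) = A_h * exp(sum q_i atanh 2^-i) for all sign choices
  s <- c(1, 2, 3, 4, 4)
  Ah <- prod(sqrt(1 - 2^(-2 * s)))
  paths <- as.matrix(expand.grid(rep(list(c(-1, 1)), length(s))))
  for (r in seq_len(nrow(paths))) {
    q <- paths[r, ]
    expect_equal(prod(1 + q * 2^-s), Ah * exp(sum(q * atanh(2^-s))),
                 tolerance = 1e-12)
  }
})

test_that("range extension splits theta/ln2 with floor semantics", {
  expect_equal(range_extend(log(2)), list(A = 1, b = 0))
  expect_equal(range_extend(0), list(A = 0, b = 0))
  r1 <- range_extend(1)
  expect_equal(r1$A, 1)
  expect_equal(r1$b, 1 / log(2) - 1, tolerance = 1e-15)
  rm <- range_extend(-0.5)
  expect_equal(rm$A, -1)
  expect_equal(rm$b, -0.5 / log(2) + 1, tolerance = 1e-15)
  th <- runif(100, -20, 20)
  rr <- range_extend(th)
  expect_true(all(rr$b >= 0 & rr$b < 1))
  expect_true(all(rr$b * log(2) < 1.1182))
})

test_that("full-range exponential meets its error bound on a dense grid", {
  cfg <- cordic_config("hyperbolic", iterations = 10)
  expect_equal(cordic_exp(0, cfg), 1, tolerance = 2^-10)
  expect_lt(abs(cordic_exp(-5, cfg) - exp(-5)) / exp(-5), 1e-3)
  th <- seq(-8, 8, by = 0.01)
  rel <- abs(cordic_exp(th, cfg) - exp(th)) / exp(th)
  expect_lt(max(rel), 2^-9)
})

test_that("linear-mode division meets the 2^(n-iters+1) bound on random pairs", {
  cfg <- cordic_config("linear", iterations = 20, range_exponent = 2)
  expect_lte(abs(cordic_div(3, 4, cfg) - 0.75), 2^-17)
  expect_lte(abs(cordic_div(0, 5, cfg)), 2^-17)
  x <- runif(50, 0.1, 5)
  expect_lte(max(abs(cordic_div(x, x, cfg) - 1)), 2^-17)
  set.seed(99)
  num <- runif(1e4, -6, 6)
  den <- runif(1e4, 0.8, 8) * sample(c(-1, 1), 1e4, replace = TRUE)
  keep <- abs(num / den) < 7.9
  err <- abs(cordic_div(num[keep], den[keep], cfg) - num[keep] / den[keep])
  expect_lte(max(err), 2^(2 - 20 + 1))
  expect_error(cordic_div(1, 0, cfg), "zero")
  expect_error(cordic_div(10, 1, cfg), "convergence")
})

test_that("fixed-point CORDIC primitives agree with their real-mode versions", {
  fx <- cordic_config("hyperbolic", iterations = 10, arithmetic = "fixed")
  re <- cordic_config("hyperbolic", iterations = 10)
  th <- seq(-6, 3, by = 0.05)
  expect_equal(cordic_exp(th, fx), cordic_exp(th, re),
               tolerance = 64 * 2^-15) # quantization + truncation budget
  # fixed-point results lie exactly on the 2^-15 grid
  expect_true(all(cordic_exp(th, fx) * 2^15 == round(cordic_exp(th, fx) * 2^15)))
  dfx <- cordic_config("linear", iterations = 20, arithmetic = "fixed")
  dre <- cordic_config("linear", iterations = 20)
  expect_equal(cordic_div(c(1, 2, 3), c(3, 5, 4), dfx),
               cordic_div(c(1, 2, 3), c(3, 5, 4), dre), tolerance = 16 * 2^-15)
})
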