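make_trace <- function(t, V) {
  tr <- data.frame(t = t, V = V)
  class(tr) <- c("pc_trace", "data.frame")
  tr
}

test_that("spike detection finds constructed peaks and nothing in flat traces", {
  t <- seq(0, 100, by = 0.1)
  expect_equal(nrow(detect_spikes(make_trace(t, rep(-60, length(t))))), 0)
  # sawtooth crossing threshold 5 times with peaks at known positions
  V <- -60 + 60 * (((t / 20) %% 1) > 0.5) * (((t / 20) %% 1) - 0.5) * 2
  s <- detect_spikes(make_trace(t, V), threshold = -20)
  expect_equal(nrow(s), 5)
  expect_equal(s$t, c(19.9, 39.9, 59.9, 79.9, 99.9), tolerance = 0.2)
  # refractory merging collapses twin crossings
  V2 <- rep(-60, length(t)); V2[c(100, 103)] <- 0
  expect_equal(nrow(detect_spikes(make_trace(t, V2), refractory = 1)), 1)
})

test_that("detected spike period matches a brute-force local-maxima scan", {
  tr <- cached_trace(-35, 1200)
  s <- detect_spikes(tr)
  pk <- oracle_peaks(tr)
  # brute force finds every sample-level maximum above threshold;
  # compare mean periods
  expect_equal(mean(diff(s$t)), mean(diff(pk)), tolerance = 1e-6)
})

test_that("synchronous spike search honours the tolerance", {
  a <- structure(data.frame(t = c(1, 2, 3), amp = 0),
                 class = c("spike_train", "data.frame"))
  expect_equal(find_sync_spike(a, a)[c("i", "j")], list(i = 1L, j = 1L))
  b <- a; b$t <- b$t + 0.5
  expect_error(find_sync_spike(a, b, tol = 0.1), "tolerance")
  expect_equal(find_sync_spike(a, b, tol = 0.6)$j, 1L)
  expect_error(find_sync_spike(a[0, ], a))
})

test_that("absolute-error statistics follow their definitions", {
  st <- abs_error_stats(1:5, 1:5)
  expect_equal(st$mAE, 0)
  expect_equal(st$RMSE, 0)
  st2 <- abs_error_stats(c(1, 2, 3), c(1.5, 2.5, 3.5))
  expect_equal(st2$mAE, 0.5)
  expect_equal(st2$RMSE, 0.5)
  expect_equal(st2$AE, rep(0.5, 3))
  expect_error(abs_error_stats(1:3, 1:4))
  # mAE >= RMSE always; both zero iff identical
  set.seed(3)
  x <- rnorm(100); y <- x + rnorm(100, 0, 0.1)
  st3 <- abs_error_stats(x, y)
  expect_gte(st3$mAE, st3$RMSE)
  expect_gt(st3$RMSE, 0)
})

test_that("spike-timing error averages relative interval differences", {
  mk <- function(t) structure(data.frame(t = t, amp = 0),
                              class = c("spike_train", "data.frame"))
  a <- mk(seq(0, 210, by = 10))
  expect_equal(err_t(a, a), 0)
  b <- mk(seq(0, 212.1, by = 10.1))
  expect_equal(err_t(a, b, n_pairs = 20, tol = 0.05), 0.01, tolerance = 1e-10)
  # asymmetric in the reference: the denominator changes
  expect_equal(err_t(b, a, n_pairs = 20, tol = 0.05), 0.1 / 10.1,
               tolerance = 1e-10)
  expect_error(err_t(mk(c(0, 1)), mk(c(0, 1)), n_pairs = 0))
})

test_that("waveform correlation behaves like standard Pearson", {
  t <- seq(0, 20, by = 0.004)
  V <- -40 + 25 * sin(2 * pi * t) # crosses -20 each cycle
  a <- make_trace(t, V)
  expect_equal(corr_traces(a, a), 1)
  # phase-inverted copy anticorrelates strongly over whole cycles
  b <- make_trace(t, -80 - V)
  s <- detect_spikes(a); sb <- detect_spikes(b)
  expect_equal(cor(V[1:100], (-80 - V)[1:100]), -1)
  expect_error(corr_traces(make_trace(t, rep(0, length(t))), a))
})

test_that("mode classification separates the five regimes at their stated currents", {
  expect_identical(classify_mode(cached_trace(-25, 2200)), "bursting_I")
  expect_identical(classify_mode(cached_trace(-30, 2200)), "bursting_II")
  expect_identical(classify_mode(cached_trace(-33.09485, 2200)), "bursting_am")
  expect_identical(classify_mode(cached_trace(-33.1, 2200)),
                   "amplitude_modulation")
  expect_identical(classify_mode(cached_trace(-35, 2200)), "fast_spiking")
  expect_error(classify_mode(make_trace(0:10, rep(-60, 11))), "spikes")
})
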