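#' Configuration of the CORDIC/fixed-point model backend
#'
#' Widths and iteration counts of the hardware-faithful arithmetic: 15
#' fraction bits, 8 integer bits for the state datapath and 14 on the
#' `h_inf` exponential path (whose intermediate reaches ~8000), 10 CORDIC
#' iterations for exponentials and 20 for divisions with range exponent 2.
#'
#' Euler state accumulators hold the full precision of the dt-product (a
#' fraction of `2 * frac_bits`); every arithmetic tap reads the
#' `frac_bits` truncation.  With bare `frac_bits` state registers and floor
#' rounding the slow variable's sub-LSB increments would be lost and the
#' burst cycle destroyed (see the package vignette).
#'
#' @param frac_bits Fraction width of the working format.
#' @param int_bits Integer width of the state datapath (incl. sign).
#' @param int_bits_hinf Integer width of the `h_inf` exponential node.
#' @param exp_iterations Hyperbolic CORDIC iterations for exponentials.
#' @param div_iterations Linear CORDIC iterations for divisions.
#' @param range_exponent Linear-mode range exponent n.
#' @param overflow `"error"` stops on a datapath overflow, `"ignore"`
#'   counts overflow events in the arithmetic report.
#' @return An object of class `"cordic_model_config"`.
#' @export
cordic_model_config <- function(frac_bits = 15, int_bits = 8,
                                int_bits_hinf = 14, exp_iterations = 10,
                                div_iterations = 20, range_exponent = 2,
                                overflow = c("error", "ignore")) {
  overflow <- match.arg(overflow)
  structure(list(frac_bits = as.integer(frac_bits),
                 int_bits = as.integer(int_bits),
                 int_bits_hinf = as.integer(int_bits_hinf),
                 exp_iterations = as.integer(exp_iterations),
                 div_iterations = as.integer(div_iterations),
                 range_exponent = as.integer(range_exponent),
                 overflow = overflow),
            class = "cordic_model_config")
}

as_trace <- function(lst, I, dt, backend) {
  tr <- data.frame(t = lst$t, V = lst$V, n = lst$n, h = lst$h,
                   c = lst$c, M = lst$M)
  attr(tr, "I") <- I
  attr(tr, "dt") <- dt
  attr(tr, "backend") <- backend
  attr(tr, "arithmetic_report") <- lst$report
  class(tr) <- c("pc_trace", "data.frame")
  tr
}

#' Simulate the Purkinje cell model
#'
#' Explicit-Euler integration of the five-channel model under a constant
#' injected current, with either the double-precision reference backend or
#' the bit-accurate CORDIC fixed-point backend.  The run is deterministic:
#' identical inputs give bit-identical traces.
#'
#' The injected current enters the voltage equation with a minus sign, so
#' negative `I` depolarizes; the model's spiking regimes live around
#' `I = -25` (bursting) to `I = -35` (fast spiking).
#'
#' @param I Injected current (uA/cm^2).
#' @param duration Simulated time (ms), `>= 0`.
#' @param params A [purkinje_params()].
#' @param init Initial [neuron_state()].
#' @param transient_discard Initial span dropped from the returned trace
#'   (ms).  Use 0 when comparing backends spike-by-spike from a common
#'   initial condition.
#' @param backend `"reference"` or `"cordic"`.
#' @param config A [cordic_model_config()] (CORDIC backend only).
#' @return A `"pc_trace"` data frame with columns `t`, `V`, `n`, `h`, `c`,
#'   `M`; attributes `I`, `dt`, `backend` and, for the CORDIC backend, an
#'   `arithmetic_report` (extreme magnitudes, overflow events, operation
#'   tallies).
#' @examples
#' tr <- simulate_purkinje(-35, duration = 50, transient_discard = 0)
#' range(tr$V)
#' @export
simulate_purkinje <- function(I, duration = 2000, params = purkinje_params(),
                              init = steady_init(-65), transient_discard = 200,
                              backend = c("reference", "cordic"),
                              config = cordic_model_config()) {
  backend <- match.arg(backend)
  if (duration < 0) stop("duration must be >= 0")
  stopifnot(inherits(params, "purkinje_params"))
  lst <- cpp_simulate(unclass(params), I, duration,
                      min(transient_discard, duration), unclass(init),
                      if (backend == "reference") 0L else 1L,
                      config$frac_bits, config$exp_iterations,
                      config$div_iterations, config$range_exponent,
                      config$int_bits, config$int_bits_hinf,
                      if (config$overflow == "error") 0L else 1L,
                      FALSE, 0)
  as_trace(lst, I, params[["dt"]], backend)
}

#' @export
print.pc_trace <- function(x, ...) {
  cat(sprintf("Purkinje trace: %d samples, t in [%g, %g] ms, I = %g, %s backend\n",
              nrow(x), if (nrow(x)) min(x$t) else NA, if (nrow(x)) max(x$t) else NA,
              attr(x, "I"), attr(x, "backend")))
  invisible(x)
}

#' One synchronous Euler step
#'
#' Advances a state by a single Euler step: all updates are computed from
#' the step-k values only (the software image of the pipeline's buffered
#' synchronous update).  `n` and `h` relax as `(x_inf - x)/tau_x * dt`;
#' `c` and `M` as `(alpha (1 - x) - beta x) * dt`; every ionic term and the
#' injected current enter the voltage update with a minus sign.
#'
#' @param state A [neuron_state()].
#' @param params A [purkinje_params()].
#' @param I Injected current (uA/cm^2).
#' @param backend `"reference"` or `"cordic"`; the CORDIC backend
#'   quantizes the state, steps with the fixed-point datapath and returns
#'   the working-precision taps.
#' @param config A [cordic_model_config()].
#' @return The next [neuron_state()].
#' @export
euler_step <- function(state, params = purkinje_params(), I = 0,
                       backend = c("reference", "cordic"),
                       config = cordic_model_config()) {
  backend <- match.arg(backend)
  if (!all(is.finite(unclass(state)))) stop("state must be finite")
  lst <- cpp_simulate(unclass(params), I, params[["dt"]], 0, unclass(state),
                      if (backend == "reference") 0L else 1L,
                      config$frac_bits, config$exp_iterations,
                      config$div_iterations, config$range_exponent,
                      config$int_bits, config$int_bits_hinf, 1L, FALSE, 0)
  neuron_state(V = lst$V[2], n = lst$n[2], h = lst$h[2],
               c = lst$c[2], M = lst$M[2])
}

#' Evaluate a rate function on the CORDIC fixed-point datapath
#'
#' Each nonlinear function is composed exclusively of the fixed-point
#' primitives: CORDIC exponentials for every `e^(.)`, CORDIC divisions for
#' every ratio (including the `1/(1 + e^x)` sigmoids and `beta_c`'s
#' ratio), shift-add constant multipliers, and functional shift
#' multipliers -- no native multiply, divide, exponential or table lookup.
#' Results therefore lie exactly on the `2^-frac_bits` grid.
#'
#' @param kind One of [rate_kinds()].
#' @param V Membrane potential (mV), vectorized.
#' @param config A [cordic_model_config()].
#' @param params A [purkinje_params()] (reversal/conductance constants are
#'   not used by the rate laws but fix the quantization of `dt`).
#' @return Numeric vector of fixed-point rate values.
#' @examples
#' evaluate_rate_cordic("n_inf", -29.5) # 0.5 within quantization
#' @export
evaluate_rate_cordic <- function(kind, V, config = cordic_model_config(),
                                 params = purkinje_params()) {
  kind <- match.arg(kind, rate_kinds())
  cpp_rate_cordic(match(kind, rate_kinds()), V, unclass(params),
                  config$frac_bits, config$exp_iterations,
                  config$div_iterations, config$range_exponent,
                  config$int_bits_hinf)
}
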