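#' CORDIC engine configuration
#'
#' The unified CORDIC iteration supports three rotation modes through the
#' coordinate parameter m: hyperbolic (m = -1, angle base `atanh(2^-i)`,
#' schedule starting at i = 1 with convergence repeats), linear (m = 0,
#' angle base `2^(n-i)` scaled by the range exponent n, schedule from
#' i = 0) and circular (m = +1, `atan(2^-i)`, from i = 0).  Defaults follow
#' the hardware build: 10 iterations for exponentials, 20 for divisions
#' with n = 2.
#'
#' The hyperbolic schedule repeats iterations 4, 13, 40, ... (k -> 3k + 1);
#' only with these repeats does the angle sum converge to the quoted
#' bound ~1.1182 (without them it is ~1.056).
#'
#' @param mode `"hyperbolic"`, `"linear"` or `"circular"`.
#' @param iterations Number of distinct iteration indices; `Inf` (allowed
#'   for angle sums) uses 60, beyond double-precision convergence.
#' @param range_exponent Linear-mode range exponent n.
#' @param repeat_schedule Hyperbolic indices iterated twice.
#' @param arithmetic `"real"` (double precision) or `"fixed"` (Q-format).
#' @param frac_bits Fraction width for `arithmetic = "fixed"`.
#' @return An object of class `"cordic_config"`.
#' @examples
#' cordic_config("hyperbolic", iterations = 10)
#' @export
cordic_config <- function(mode = c("hyperbolic", "linear", "circular"),
                          iterations = if (match.arg(mode) == "linear") 20 else 10,
                          range_exponent = 2,
                          repeat_schedule = c(4, 13, 40),
                          arithmetic = c("real", "fixed"),
                          frac_bits = 15) {
  mode <- match.arg(mode)
  arithmetic <- match.arg(arithmetic)
  if (!is.infinite(iterations) && iterations < 1) stop("iterations must be >= 1")
  structure(list(mode = mode, iterations = iterations,
                 range_exponent = range_exponent,
                 repeat_schedule = repeat_schedule,
                 arithmetic = arithmetic, frac_bits = frac_bits),
            class = "cordic_config")
}

#' @export
print.cordic_config <- function(x, ...) {
  cat(sprintf("CORDIC config: %s mode, %s iterations, n = %d, %s arithmetic\n",
              x$mode, format(x$iterations), x$range_exponent, x$arithmetic))
  invisible(x)
}

# iteration indices including hyperbolic repeats
cordic_schedule <- function(cfg) {
  iters <- if (is.infinite(cfg$iterations)) 60 else cfg$iterations
  if (cfg$mode == "hyperbolic") {
    idx <- seq_len(iters)
    reps <- cfg$repeat_schedule[cfg$repeat_schedule <= iters]
    sort(c(idx, reps))
  } else {
    seq_len(iters) - 1L
  }
}

# hyperbolic rotation gain A_h over the schedule (repeats included)
cordic_gain <- function(cfg) {
  s <- cordic_schedule(cfg)
  if (cfg$mode == "hyperbolic") prod(sqrt(1 - 2^(-2 * s)))
  else if (cfg$mode == "circular") prod(sqrt(1 + 2^(-2 * s)))
  else 1
}

#' Angle base of a CORDIC schedule
#'
#' One micro-rotation angle per scheduled iteration, repeats included.
#'
#' @param cfg A [cordic_config()].
#' @return Numeric vector of angles.
#' @examples
#' angle_base(cordic_config("linear", iterations = 3))   # 4 2 1 (n = 2)
#' angle_base(cordic_config("circular", iterations = 1)) # pi/4
#' @export
angle_base <- function(cfg) {
  s <- cordic_schedule(cfg)
  switch(cfg$mode,
         hyperbolic = atanh(2^(-s)),
         linear = 2^(cfg$range_exponent - s),
         circular = atan(2^(-s)))
}

#' Convergence range of a CORDIC schedule
#'
#' The largest rotation angle the schedule can absorb: the sum of all its
#' micro-angles.  With the standard repeat schedule the hyperbolic bound
#' converges to ~1.1182.
#'
#' @param cfg A [cordic_config()].
#' @return The angle sum.
#' @examples
#' max_angle(cordic_config("hyperbolic", iterations = Inf)) # ~1.1182
#' @export
max_angle <- function(cfg) sum(angle_base(cfg))

#' General CORDIC rotation/vectoring
#'
#' Double-precision CORDIC iteration in any mode.  Rotation mode drives the
#' accumulated angle Z to zero (`q_i = sign(Z_i)`, ties toward +1);
#' vectoring mode drives Y to zero (`q_i = -sign(X_i Y_i)`).  Outputs carry
#' the mode's accumulated gain (e.g. hyperbolic
#' `X = A_h (X0 cosh Z0 + Y0 sinh Z0)`); initialize at `1/A_h` to
#' compensate, with `A_h = ` [cordic_gain_of()].
#'
#' @param cfg A [cordic_config()].
#' @param X0,Y0,Z0 Initial vector and angle accumulator.
#' @param vectoring Drive Y (instead of Z) to zero.
#' @return List with elements `X`, `Y`, `Z`.
#' @export
cordic_rotate <- function(cfg, X0, Y0, Z0, vectoring = FALSE) {
  s <- cordic_schedule(cfg)
  th <- angle_base(cfg)
  m <- switch(cfg$mode, hyperbolic = -1, linear = 0, circular = 1)
  fct <- if (cfg$mode == "linear") 2^(cfg$range_exponent - s) else 2^(-s)
  if (!vectoring && any(abs(Z0) > max_angle(cfg) + 1e-12))
    stop("|Z0| exceeds the convergence range; range-extend the argument first")
  X <- X0; Y <- Y0; Z <- Z0
  for (j in seq_along(s)) {
    q <- if (vectoring) ifelse(X * Y >= 0, -1, 1) else ifelse(Z >= 0, 1, -1)
    Xn <- X - m * q * Y * fct[j]
    Y <- Y + q * X * fct[j]
    X <- Xn
    Z <- Z - q * th[j]
  }
  list(X = X, Y = Y, Z = Z)
}

#' @rdname cordic_rotate
#' @export
cordic_gain_of <- function(cfg) cordic_gain(cfg)

#' Merged-iteration exponential core
#'
#' Because the hyperbolic X and Y recursions are identical up to the
#' coupling term, their sum S = X + Y iterates autonomously as
#' `S_{i+1} = S_i + q_i S_i 2^-i`; with `S_0 = 1/A_h` the result is `e^z`.
#' This halves the datapath without changing any result: in exact
#' arithmetic it equals X + Y of the unmerged rotation on the same
#' schedule.
#'
#' @param z Argument(s); must lie within [max_angle()] of the hyperbolic
#'   schedule.
#' @param cfg A hyperbolic [cordic_config()]; `arithmetic = "fixed"` runs
#'   the Q-format datapath.
#' @return Approximation of `exp(z)`.
#' @export
exp_core_merged <- function(z, cfg = cordic_config("hyperbolic")) {
  if (cfg$mode != "hyperbolic") stop("exponential core requires hyperbolic mode")
  if (any(abs(z) > max_angle(cfg) + 1e-12))
    stop("argument outside the hyperbolic convergence range")
  if (cfg$arithmetic == "fixed")
    return(cpp_exp_core_fx(z, cfg$frac_bits, as.integer(cfg$iterations)))
  s <- cordic_schedule(cfg)
  th <- atanh(2^(-s))
  S <- rep(1 / cordic_gain(cfg), length(z)); Z <- z
  for (j in seq_along(s)) {
    q <- ifelse(Z >= 0, 1, -1)
    S <- S + q * S * 2^(-s[j])
    Z <- Z - q * th[j]
  }
  S
}

#' Range extension for the exponential
#'
#' Splits `theta/ln2 = A + b` with `A = floor(theta/ln2)` and `b` in
#' `[0, 1)`, so `e^theta = 2^A * e^(b ln2)`: the integer part becomes a pure
#' bit shift and `b * ln2 < 1.1182` stays inside the hyperbolic convergence
#' range.
#'
#' @param theta Finite argument(s).
#' @return List with integer part `A` and fractional part `b`.
#' @examples
#' range_extend(log(2)) # A = 1, b = 0
#' @export
range_extend <- function(theta) {
  if (!all(is.finite(theta))) stop("theta must be finite")
  A <- floor(theta / log(2))
  list(A = A, b = theta / log(2) - A)
}

#' Full-range CORDIC exponential
#'
#' `e^theta = 2^A * exp_core_merged(b ln2)` with the [range_extend()]
#' split.  In fixed-point arithmetic the `2^A` factor is a pure shift.
#'
#' @param theta Argument(s).
#' @param cfg A hyperbolic [cordic_config()].
#' @return Approximation of `exp(theta)`.
#' @examples
#' cordic_exp(0)  # 1
#' cordic_exp(-5) # ~ e^-5
#' @export
cordic_exp <- function(theta, cfg = cordic_config("hyperbolic")) {
  if (cfg$mode != "hyperbolic") stop("exponential requires hyperbolic mode")
  if (cfg$arithmetic == "fixed")
    return(cpp_cordic_exp_fx(theta, cfg$frac_bits, as.integer(cfg$iterations)))
  r <- range_extend(theta)
  2^r$A * exp_core_merged(r$b * log(2), cfg)
}

#' Linear-mode CORDIC division
#'
#' Vectoring in linear mode: Y starts at the numerator, X at the
#' denominator, and driving Y to zero accumulates the quotient in Z against
#' the angle base `2^(n-i)`.  The quotient must satisfy
#' `|numer/denom| < 2^(n+1)`; the result is within `2^(n-iterations+1)` of
#' the true quotient.
#'
#' @param numer,denom Numerator(s) and denominator(s); `denom != 0`.
#' @param cfg A linear [cordic_config()].
#' @return Approximate quotient(s).
#' @examples
#' cordic_div(3, 4) # ~0.75
#' @export
cordic_div <- function(numer, denom, cfg = cordic_config("linear")) {
  if (cfg$mode != "linear") stop("division requires linear mode")
  if (any(denom == 0)) stop("division by zero")
  n <- cfg$range_exponent
  if (any(abs(numer / denom) >= 2^(n + 1)))
    stop("quotient outside the linear convergence range 2^(n+1)")
  if (cfg$arithmetic == "fixed")
    return(cpp_cordic_div_fx(numer, denom, cfg$frac_bits,
                             as.integer(cfg$iterations), as.integer(n)))
  X <- denom; Y <- numer; Z <- numeric(length(numer))
  for (i in seq_len(cfg$iterations) - 1) {
    q <- ifelse((Y >= 0) == (X >= 0), -1, 1)
    Y <- Y + q * X * 2^(n - i)
    Z <- Z - q * 2^(n - i)
  }
  Z
}
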