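# Fast-slow decomposition: the fast subsystem is (V, n, h, c) with the slow
# M-current gate frozen as a bifurcation parameter.

# steady-state current balance of the fast subsystem (gates at their
# V-steady-states, M frozen); roots are the fast fixed points
fast_residual <- function(V, M, I, params = purkinje_params(),
                          backend = c("reference", "cordic"),
                          config = cordic_model_config()) {
  backend <- match.arg(backend)
  p <- unclass(params)
  r <- if (backend == "reference") function(k) evaluate_rate(k, V)
       else function(k) evaluate_rate_cordic(k, V, config, params)
  ninf <- r("n_inf"); hinf <- r("h_inf"); minf <- r("m_inf")
  ac <- r("alpha_c"); bc <- r("beta_c")
  cinf <- ac / (ac + bc)
  -(p[["g_K"]] * ninf^4 * (V - p[["E_K"]]) +
    p[["g_Na"]] * minf^3 * hinf * (V - p[["E_Na"]]) +
    p[["g_Ca"]] * cinf^2 * (V - p[["E_Ca"]]) +
    p[["g_M"]] * M * (V - p[["E_M"]]) +
    p[["g_L"]] * (V - p[["E_L"]]) + I)
}

#' Fixed points of the fast subsystem
#'
#' Scans the steady-state current balance of the fast subsystem (V, n, h,
#' c) -- with the slow gate M frozen as a parameter -- for sign changes on a
#' voltage grid and refines each root by bisection.
#'
#' @param M Frozen slow-gate value.
#' @param I Injected current (uA/cm^2).
#' @param params A [purkinje_params()].
#' @param backend `"reference"` or `"cordic"` (quantized rate laws).
#' @param config A [cordic_model_config()].
#' @param V_window Scan window (mV).
#' @param V_step Scan step (mV).
#' @param tol Bisection residual tolerance (reference backend; the
#'   quantized residual is a step function, so bisection there stops at
#'   voltage resolution 1e-6).
#' @param stability Also classify each fixed point via the eigenvalues of
#'   the fast-subsystem Jacobian (reference backend only).
#' @param cluster_tol Roots closer than this (mV) are merged into one.
#'   The quantized residual of the CORDIC backend wobbles by a couple of
#'   LSB around zero along shallow branches, fragmenting a single root
#'   into a tight cluster of sign changes; the default merges those while
#'   keeping genuinely distinct equilibria apart.  0 disables merging
#'   (reference default).
#' @return Data frame with columns `V`, `M`, `residual` and `stability`
#'   (`"attracting"`, `"repelling"`, `"saddle"` or `NA`); zero rows when no
#'   root lies in the window.
#' @export
fast_fixed_points <- function(M, I, params = purkinje_params(),
                              backend = c("reference", "cordic"),
                              config = cordic_model_config(),
                              V_window = c(-100, 40), V_step = 0.01,
                              tol = 1e-8, stability = FALSE,
                              cluster_tol = if (match.arg(backend) == "cordic") 0.5 else 0) {
  backend <- match.arg(backend)
  Vg <- seq(V_window[1], V_window[2], by = V_step)
  rg <- fast_residual(Vg, M, I, params, backend, config)
  sgn <- sign(rg)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0 | sgn[-length(sgn)] == 0)
  roots <- vapply(flips, function(k) {
    lo <- Vg[k]; hi <- Vg[k + 1]
    flo <- rg[k]
    mid <- (lo + hi) / 2
    for (it in 1:80) {
      mid <- (lo + hi) / 2
      fm <- fast_residual(mid, M, I, params, backend, config)
      if (backend == "reference") {
        if (abs(fm) < tol || mid == lo || mid == hi) return(mid)
      } else if (hi - lo < 1e-6) return(mid)
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    mid
  }, numeric(1))
  if (cluster_tol > 0 && length(roots) > 1) {
    grp <- cumsum(c(1, diff(roots) > cluster_tol))
    roots <- vapply(split(roots, grp), median, numeric(1))
    names(roots) <- NULL
  }
  out <- data.frame(V = roots, M = rep(M, length(roots)),
                    residual = if (length(roots))
                      fast_residual(roots, M, I, params, backend, config)
                    else numeric(0),
                    stability = rep(NA_character_, length(roots)))
  if (stability && backend == "reference" && nrow(out))
    out$stability <- vapply(out$V, function(v)
      fixed_point_stability(v, M, I, params), character(1))
  out
}

# time derivatives of the fast subsystem at (V, n, h, c), M frozen
fast_rhs <- function(x, M, I, params) {
  p <- unclass(params)
  V <- x[1]; n <- x[2]; h <- x[3]; cc <- x[4]
  m <- evaluate_rate("m_inf", V)
  Iion <- p[["g_K"]] * n^4 * (V - p[["E_K"]]) +
    p[["g_Na"]] * m^3 * h * (V - p[["E_Na"]]) +
    p[["g_Ca"]] * cc^2 * (V - p[["E_Ca"]]) +
    p[["g_M"]] * M * (V - p[["E_M"]]) +
    p[["g_L"]] * (V - p[["E_L"]])
  c(-(Iion + I) / p[["C"]],
    (evaluate_rate("n_inf", V) - n) / evaluate_rate("tau_n", V),
    (evaluate_rate("h_inf", V) - h) / evaluate_rate("tau_h", V),
    evaluate_rate("alpha_c", V) * (1 - cc) - evaluate_rate("beta_c", V) * cc)
}

#' Stability of a fast-subsystem fixed point
#'
#' Eigenvalues of the finite-difference Jacobian of the four-dimensional
#' fast subsystem at `(V*, n_inf, h_inf, c_inf)`: attracting if every real
#' part is negative, repelling if every real part is positive, saddle
#' otherwise.
#'
#' @param V_star Fixed-point voltage (mV).
#' @param M Frozen slow-gate value.
#' @param I Injected current.
#' @param params A [purkinje_params()].
#' @param jac_step Finite-difference step.
#' @return `"attracting"`, `"repelling"` or `"saddle"`.
#' @export
fixed_point_stability <- function(V_star, M, I, params = purkinje_params(),
                                  jac_step = 1e-6) {
  ac <- evaluate_rate("alpha_c", V_star); bc <- evaluate_rate("beta_c", V_star)
  x0 <- c(V_star, evaluate_rate("n_inf", V_star),
          evaluate_rate("h_inf", V_star), ac / (ac + bc))
  J <- matrix(0, 4, 4)
  f0 <- fast_rhs(x0, M, I, params)
  for (j in 1:4) {
    xp <- x0; xp[j] <- xp[j] + jac_step
    J[, j] <- (fast_rhs(xp, M, I, params) - f0) / jac_step
  }
  ev <- Re(eigen(J, only.values = TRUE)$values)
  if (all(ev < 0)) "attracting" else if (all(ev > 0)) "repelling" else "saddle"
}

#' Attracting orbit of the clamped fast subsystem
#'
#' Clamps the slow gate M, integrates the fast subsystem past a transient
#' and reports the voltage extremes of the attractor.  A peak-to-peak
#' amplitude below `amp_tol` is classified as a fixed point.
#'
#' @param M Frozen slow-gate value.
#' @param I Injected current.
#' @param params,backend,config Model parameterization.
#' @param duration,discard Simulated and discarded spans (ms).
#' @param V0 Initial potential.  The default starts on the depolarized
#'   side: in the bistable M window the attracting orbit reached from the
#'   active phase is the spiking limit cycle, matching how the full
#'   system's burst enters it.
#' @param amp_tol Amplitude threshold separating fixed points from limit
#'   cycles (mV).
#' @return List with `type` (`"limit_cycle"` or `"fixed_point"`), `V_min`,
#'   `V_max`.
#' @export
limit_cycle_envelope <- function(M, I, params = purkinje_params(),
                                 backend = c("reference", "cordic"),
                                 config = cordic_model_config(),
                                 duration = 600, discard = 400, V0 = -20,
                                 amp_tol = 1) {
  backend <- match.arg(backend)
  init <- steady_init(V0)
  lst <- cpp_simulate(unclass(params), I, duration, discard, unclass(init),
                      if (backend == "reference") 0L else 1L,
                      config$frac_bits, config$exp_iterations,
                      config$div_iterations, config$range_exponent,
                      config$int_bits, config$int_bits_hinf, 1L,
                      TRUE, M)
  vr <- range(lst$V)
  list(type = if (diff(vr) < amp_tol) "fixed_point" else "limit_cycle",
       V_min = vr[1], V_max = vr[2])
}

#' Bifurcation diagram of the fast subsystem
#'
#' Assembles, over a grid of the slow gate M: the fast fixed-point
#' branches, the fold locations (grid intervals where the branch count
#' changes), optionally the attracting-orbit voltage envelopes from
#' clamped simulations, and the full-system (V, M) trajectory overlay.
#'
#' @param I Injected current.
#' @param M_grid Grid of frozen M values (should cover the range visited
#'   by the full system).
#' @param params,backend,config Model parameterization.
#' @param envelopes Compute clamped-orbit envelopes on a thinned grid.
#' @param envelope_every Envelope grid thinning factor.
#' @param trajectory_duration Span of the overlay simulation (ms).
#' @param stability Classify branch stability (reference backend).
#' @return List of class `"pc_bifurcation"` with elements `fixed_points`
#'   (data frame), `folds` (M midpoints of branch-count changes),
#'   `envelopes`, and `trajectory` (t, V, M).
#' @export
bifurcation_diagram <- function(I, M_grid = seq(0.25, 0.65, by = 0.005),
                                params = purkinje_params(),
                                backend = c("reference", "cordic"),
                                config = cordic_model_config(),
                                envelopes = FALSE, envelope_every = 8,
                                trajectory_duration = 1500,
                                stability = FALSE) {
  backend <- match.arg(backend)
  fps <- lapply(M_grid, fast_fixed_points, I = I, params = params,
                backend = backend, config = config, stability = stability)
  counts <- vapply(fps, nrow, integer(1))
  fold_idx <- which(diff(counts) != 0)
  folds <- (M_grid[fold_idx] + M_grid[fold_idx + 1]) / 2
  env <- NULL
  if (envelopes) {
    Me <- M_grid[seq(1, length(M_grid), by = envelope_every)]
    env <- do.call(rbind, lapply(Me, function(m) {
      e <- limit_cycle_envelope(m, I, params, backend, config)
      data.frame(M = m, type = e$type, V_min = e$V_min, V_max = e$V_max)
    }))
  }
  tr <- simulate_purkinje(I, trajectory_duration, params,
                          transient_discard = 200, backend = backend,
                          config = config)
  structure(list(I = I, backend = backend,
                 fixed_points = do.call(rbind, fps),
                 branch_counts = data.frame(M = M_grid, count = counts),
                 folds = folds, envelopes = env,
                 trajectory = data.frame(t = tr$t, V = tr$V, M = tr$M)),
            class = "pc_bifurcation")
}

#' @export
print.pc_bifurcation <- function(x, ...) {
  cat(sprintf("Fast-slow bifurcation diagram (%s backend), I = %g\n",
              x$backend, x$I))
  cat(sprintf("  %d fixed points on %d grid points; folds at M = %s\n",
              nrow(x$fixed_points), nrow(x$branch_counts),
              paste(signif(x$folds, 4), collapse = ", ")))
  invisible(x)
}
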