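#' Membrane parameters of the Purkinje cell model
#'
#' Maximal conductances, reversal potentials, membrane capacitance and Euler
#' step of the five-channel (K, Na, Ca, M, leak) Purkinje model.  Defaults
#' are the published conductance table of the model; the capacitance is the
#' conventional 1 uF/cm^2 for this model family.
#'
#' @param g_K,g_Na,g_Ca,g_M,g_L Maximal conductances (mS/cm^2).
#' @param E_K,E_Na,E_Ca,E_M,E_L Reversal potentials (mV).
#' @param C Membrane capacitance (uF/cm^2).
#' @param dt Euler time step (ms).
#' @return A named numeric vector of class `"purkinje_params"`.
#' @examples
#' p <- purkinje_params()
#' p["g_K"]
#' @export
purkinje_params <- function(g_K = 10, E_K = -95, g_Na = 125, E_Na = 50,
                            g_Ca = 1, E_Ca = 125, g_M = 0.75, E_M = -95,
                            g_L = 2, E_L = -70, C = 1, dt = 0.004) {
  g <- c(g_K = g_K, g_Na = g_Na, g_Ca = g_Ca, g_M = g_M, g_L = g_L)
  if (any(g < 0)) stop("conductances must be non-negative")
  if (dt <= 0) stop("dt must be positive")
  if (C <= 0) stop("C must be positive")
  p <- c(g_K = g_K, E_K = E_K, g_Na = g_Na, E_Na = E_Na, g_Ca = g_Ca,
         E_Ca = E_Ca, g_M = g_M, E_M = E_M, g_L = g_L, E_L = E_L,
         C = C, dt = dt)
  class(p) <- "purkinje_params"
  p
}

#' @export
print.purkinje_params <- function(x, ...) {
  cat("Purkinje membrane parameters (mS/cm^2, mV):\n")
  print(unclass(x))
  invisible(x)
}

#' Neuron state
#'
#' Membrane potential plus the four dynamic gating variables.  The sodium
#' activation m is instantaneous (m_inf only) and is not part of the state.
#'
#' @param V Membrane potential (mV).
#' @param n,h,c,M Gating variables (dimensionless, in `[0, 1]` along any
#'   trajectory started from [steady_init()]).
#' @return A named numeric vector of class `"neuron_state"`.
#' @export
neuron_state <- function(V, n, h, c, M) {
  s <- c(V = V, n = n, h = h, c = c, M = M)
  if (!all(is.finite(s))) stop("state must be finite")
  class(s) <- "neuron_state"
  s
}

#' Steady-state initialization
#'
#' Gates set to their steady-state values at a holding potential: `n_inf`,
#' `h_inf`, `alpha_c/(alpha_c+beta_c)` and `alpha_M/(alpha_M+beta_M)`.
#'
#' @param V0 Holding potential (mV).
#' @return A [neuron_state()].
#' @examples
#' steady_init(-65)
#' @export
steady_init <- function(V0 = -65) {
  if (!is.finite(V0)) stop("V0 must be finite")
  ac <- evaluate_rate("alpha_c", V0)
  bc <- evaluate_rate("beta_c", V0)
  aM <- evaluate_rate("alpha_M", V0)
  bM <- evaluate_rate("beta_M", V0)
  neuron_state(V = V0,
               n = evaluate_rate("n_inf", V0),
               h = evaluate_rate("h_inf", V0),
               c = ac / (ac + bc),
               M = aM / (aM + bM))
}
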