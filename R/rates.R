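#' The nine voltage-dependent rate functions
#'
#' Closed forms of the model's nonlinear functions: steady states and time
#' constants for n and h, the instantaneous sodium activation m_inf, and the
#' alpha/beta rates of the calcium gate c and the slow M gate.  Units:
#' dimensionless for `x_inf`/`m_inf`, ms for time constants, 1/ms for
#' alpha/beta.
#'
#' `tau_n` has two exponential branches meeting at V = -10 mV, where both
#' evaluate to 4.625 ms (the `V <= -10` branch is inclusive).  `beta_c` has
#' a removable singularity at V = -8.9 mV; within `|V + 8.9| < 1e-6` the
#' limit 0.1 is returned.
#'
#' @param kind One of `rate_kinds()`.
#' @param V Membrane potential (mV), vectorized.
#' @return Numeric vector of rate values.
#' @examples
#' evaluate_rate("n_inf", -29.5)  # sigmoid midpoint: 0.5
#' evaluate_rate("tau_n", -10)    # branch-continuity point: 4.625
#' evaluate_rate("beta_c", -8.9)  # removable singularity: 0.1
#' @export
evaluate_rate <- function(kind, V) {
  kind <- match.arg(kind, rate_kinds())
  if (!all(is.finite(V))) stop("V must be finite")
  switch(kind,
    n_inf   = 1 / (1 + exp(-(V + 29.5) / 10)),
    tau_n   = ifelse(V <= -10,
                     0.25 + 4.375 * exp((V + 10) / 10),
                     0.25 + 4.375 * exp(-(V + 10) / 10)),
    h_inf   = 1 / (1 + exp((V + 59.4) / 10.7)),
    tau_h   = 0.15 + 1.15 / (1 + exp((V + 33.5) / 15)),
    m_inf   = 1 / (1 + exp(-(V + 34.5) / 10)),
    alpha_c = 1.6 / (1 + exp(-0.072 * (V - 5))),
    beta_c  = {
      u <- V + 8.9
      ifelse(abs(u) < 1e-6, 0.1, 0.02 * u / (exp(u / 5) - 1))
    },
    alpha_M = 0.02 / (1 + exp(-(V + 20) / 5)),
    beta_M  = 0.01 * exp(-(V + 43) / 18)
  )
}

#' @rdname evaluate_rate
#' @export
rate_kinds <- function() {
  c("n_inf", "tau_n", "h_inf", "tau_h", "m_inf",
    "alpha_c", "beta_c", "alpha_M", "beta_M")
}

#' Ionic currents at a given state
#'
#' The five conductance-based currents of the model.  The sodium activation
#' uses the instantaneous `m_inf(V)^3`.
#'
#' @param state A [neuron_state()].
#' @param params A [purkinje_params()].
#' @return Named numeric vector `I_K`, `I_Na`, `I_Ca`, `I_M`, `I_L`
#'   (uA/cm^2).
#' @export
ionic_currents <- function(state, params = purkinje_params()) {
  s <- unclass(state); p <- unclass(params)
  V <- s[["V"]]
  m <- evaluate_rate("m_inf", V)
  c(I_K  = p[["g_K"]] * s[["n"]]^4 * (V - p[["E_K"]]),
    I_Na = p[["g_Na"]] * m^3 * s[["h"]] * (V - p[["E_Na"]]),
    I_Ca = p[["g_Ca"]] * s[["c"]]^2 * (V - p[["E_Ca"]]),
    I_M  = p[["g_M"]] * s[["M"]] * (V - p[["E_M"]]),
    I_L  = p[["g_L"]] * (V - p[["E_L"]]))
}
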