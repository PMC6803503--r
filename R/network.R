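#' Synaptic parameters of the two-cell network
#'
#' Reciprocal coupling of two Purkinje cells: the pre cell (driven at
#' `I = -25`, bursting) receives an excitatory synaptic drive through the
#' slow ("GABA_A"-labelled) gate, the post cell (`I = -34`, fast spiking)
#' receives an inhibitory current through the fast ("AMPA"-labelled) gate
#' scaled by `inh_scale`.  Each gate obeys
#' `dz/dt = s(V_source) (1-z)/tau1 - z/tau2` with
#' `s(V) = (1 + tanh(V/10))/2`.
#'
#' Both default synaptic currents reference `V_inh`; see the package
#' vignette for the reconstruction of this convention from the coupled
#' phenomenology (the published equation set is internally inconsistent).
#' `V_ex` is retained for completeness and for user-defined conventions.
#'
#' @param W Connection weight.
#' @param V_ex,V_inh Reversal potentials (mV).
#' @param inh_scale Scale factor on the inhibitory conductance.
#' @param tau_onto_pre Rise/decay time constants of the gate feeding the
#'   pre cell (ms; the printed GABA_A pair).
#' @param tau_onto_post Rise/decay pair of the gate feeding the post cell
#'   (the printed AMPA pair).
#' @return An object of class `"synapse_params"`.
#' @export
synapse_params <- function(W = 0.5, V_ex = 0, V_inh = -50, inh_scale = 2,
                           tau_onto_pre = c(0.5, 10),
                           tau_onto_post = c(0.2, 2)) {
  structure(list(W = W, V_ex = V_ex, V_inh = V_inh, inh_scale = inh_scale,
                 tau_onto_pre = tau_onto_pre, tau_onto_post = tau_onto_post),
            class = "synapse_params")
}

#' One Euler step of a synaptic gate
#'
#' `z' = z + (s(V) (1-z)/tau1 - z/tau2) dt` with
#' `s(V) = (1 + tanh(V/10))/2`.  With s pinned at 1 the gate equilibrates
#' at `tau2/(tau1 + tau2)`.
#'
#' @param z Gate value in `[0, 1]`.
#' @param V_source Presynaptic membrane potential (mV).
#' @param tau1,tau2 Rise and decay time constants (ms).
#' @param dt Euler step (ms).
#' @return Updated gate value.
#' @export
gate_step <- function(z, V_source, tau1, tau2, dt = 0.004) {
  s <- (1 + tanh(V_source / 10)) / 2
  z + (s * (1 - z) / tau1 - z / tau2) * dt
}

#' Synaptic currents of the coupled pair
#'
#' The two coupling terms, as they enter each cell's voltage equation
#' through the common `-(I_ion + I + I_syn) * dt/C` sum:
#' the pre cell receives `-W z_post_gate (V_pre - V_inh)` (net spike-gated
#' depolarization -- the excitatory drive), the post cell receives
#' `+inh_scale W z_pre_gate (V_post - V_inh)` (a conventional inhibitory
#' conductance).
#'
#' @param V_pre,V_post Membrane potentials (mV).
#' @param z_pre_gate Gate driven by the pre cell (feeds the post cell).
#' @param z_post_gate Gate driven by the post cell (feeds the pre cell).
#' @param syn A [synapse_params()].
#' @return Named vector `I_syn_pre`, `I_syn_post` (uA/cm^2, in the
#'   subtracted-sum convention).
#' @export
synaptic_currents <- function(V_pre, V_post, z_pre_gate, z_post_gate,
                              syn = synapse_params()) {
  c(I_syn_pre = -syn$W * z_post_gate * (V_pre - syn$V_inh),
    I_syn_post = syn$inh_scale * syn$W * z_pre_gate * (V_post - syn$V_inh))
}

#' Simulate the coupled two-cell network
#'
#' Synchronous co-simulation of two Purkinje cells with reciprocal
#' synapses, on either arithmetic backend.  With `coupled = FALSE` (or
#' `W = 0`) the run reproduces two independent single-cell simulations
#' bit-identically.
#'
#' @param I_pre,I_post Injected currents of the two cells (uA/cm^2).
#' @param duration Simulated span (ms).
#' @param coupled Enable the synapses.
#' @param params A [purkinje_params()].
#' @param syn A [synapse_params()].
#' @param backend `"reference"` or `"cordic"`.
#' @param config A [cordic_model_config()].
#' @param init Common initial [neuron_state()].
#' @param transient_discard Span dropped from the returned traces (ms).
#' @return List of class `"pc_pair"` with `pre` and `post` traces
#'   (`"pc_trace"`) and the two gate series.
#' @examples
#' \donttest{
#' pair <- simulate_pair(duration = 500, transient_discard = 200)
#' classify_mode(pair$pre)
#' }
#' @export
simulate_pair <- function(I_pre = -25, I_post = -34, duration = 2200,
                          coupled = TRUE, params = purkinje_params(),
                          syn = synapse_params(),
                          backend = c("reference", "cordic"),
                          config = cordic_model_config(),
                          init = steady_init(-65), transient_discard = 200) {
  backend <- match.arg(backend)
  if (duration <= 0) stop("duration must be positive")
  lst <- cpp_simulate_pair(unclass(params), I_pre, I_post, duration,
                           min(transient_discard, duration), unclass(init),
                           if (backend == "reference") 0L else 1L, coupled,
                           syn$W, syn$V_inh, syn$inh_scale,
                           syn$tau_onto_pre[1], syn$tau_onto_pre[2],
                           syn$tau_onto_post[1], syn$tau_onto_post[2],
                           config$frac_bits, config$exp_iterations,
                           config$div_iterations, config$range_exponent,
                           config$int_bits, config$int_bits_hinf,
                           if (config$overflow == "error") 0L else 1L)
  mk <- function(m, I) {
    tr <- data.frame(t = lst$t, V = m[, "V"], n = m[, "n"], h = m[, "h"],
                     c = m[, "c"], M = m[, "M"])
    attr(tr, "I") <- I; attr(tr, "dt") <- params[["dt"]]
    attr(tr, "backend") <- backend
    class(tr) <- c("pc_trace", "data.frame")
    tr
  }
  structure(list(pre = mk(lst$pre, I_pre), post = mk(lst$post, I_post),
                 z_pre_gate = lst$z_pre_gate, z_post_gate = lst$z_post_gate,
                 coupled = coupled, backend = backend),
            class = "pc_pair")
}

#' Summary statistics of a coupled pair
#'
#' Mode labels, spike counts and mean interburst gap for both cells.
#'
#' @param pair A `"pc_pair"` from [simulate_pair()].
#' @param gap_threshold Interburst gap threshold (ms).
#' @return Data frame with one row per cell.
#' @export
pair_summary <- function(pair, gap_threshold = 20) {
  one <- function(tr, name) {
    s <- detect_spikes(tr)
    isi <- diff(s$t)
    g <- isi[isi > gap_threshold]
    data.frame(cell = name, mode = classify_mode(tr), n_spikes = nrow(s),
               mean_interburst_gap = if (length(g)) mean(g) else NA_real_)
  }
  rbind(one(pair$pre, "pre"), one(pair$post, "post"))
}
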