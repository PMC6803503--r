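#' Detect spikes in a voltage trace
#'
#' A spike is the voltage maximum between successive upward threshold
#' crossings; crossings closer than the refractory period to the previous
#' accepted spike are merged.
#'
#' @param trace A `"pc_trace"` or data frame with columns `t` and `V`.
#' @param threshold Detection threshold (mV).
#' @param refractory Minimum spike separation (ms).
#' @return A `"spike_train"`: data frame with peak times `t` (ms) and peak
#'   amplitudes `amp` (mV); empty if the trace never crosses threshold.
#' @export
detect_spikes <- function(trace, threshold = -20, refractory = 1) {
  V <- trace$V; tt <- trace$t
  up <- which(V[-1] >= threshold & V[-length(V)] < threshold)
  out <- data.frame(t = numeric(0), amp = numeric(0))
  if (length(up)) {
    pk <- vapply(seq_along(up), function(j) {
      a <- up[j]
      b <- if (j < length(up)) up[j + 1] else length(V)
      a - 1L + which.max(V[a:b])
    }, integer(1))
    keep <- c(TRUE, diff(tt[pk]) >= refractory)
    out <- data.frame(t = tt[pk][keep], amp = V[pk][keep])
  }
  class(out) <- c("spike_train", "data.frame")
  out
}

#' Find the first synchronous spike pair of two trains
#'
#' Scans the first train in order and returns the first pair of spikes
#' whose times agree within the tolerance; this anchors all subsequent
#' interval and correlation measurements.
#'
#' @param a,b `"spike_train"`s (both non-empty).
#' @param tol Synchrony tolerance (ms).
#' @return List with indices `i` (in `a`), `j` (in `b`) and the anchor
#'   time `t_syn`.
#' @export
find_sync_spike <- function(a, b, tol = 0.1) {
  if (nrow(a) == 0 || nrow(b) == 0) stop("spike trains must be non-empty")
  for (i in seq_len(nrow(a))) {
    j <- which(abs(b$t - a$t[i]) <= tol)
    if (length(j))
      return(list(i = i, j = j[1], t_syn = a$t[i]))
  }
  stop("no synchronous spike pair within tolerance ", tol, " ms")
}

#' Pointwise absolute error, maximum absolute error and RMSE
#'
#' `AE(i) = |F_ori(i) - F_CORDIC(i)|`, `mAE = max(AE)` and
#' `RMSE = sqrt(mean((F_ori - F_CORDIC)^2))` for two paired series.
#'
#' @param f_ori,f_cordic Equal-length numeric series.
#' @return List with elements `AE`, `mAE`, `RMSE`.
#' @export
abs_error_stats <- function(f_ori, f_cordic) {
  if (length(f_ori) != length(f_cordic)) stop("series lengths differ")
  if (length(f_ori) < 1) stop("empty series")
  ae <- abs(f_ori - f_cordic)
  list(AE = ae, mAE = max(ae), RMSE = sqrt(mean((f_ori - f_cordic)^2)))
}

#' Spike-timing error between two implementations
#'
#' Starting at a synchronous spike pair, consecutive inter-spike intervals
#' are paired by order and the relative interval differences
#' `|dT_b - dT_a| / dT_a` are averaged over `n_pairs` measurement points
#' (the published protocol measures at 20 different times and averages).
#' Both the interval before and after each anchor contribute through the
#' consecutive pairing.  The result is non-negative.
#'
#' @param a,b `"spike_train"`s (a is the reference in the denominator).
#' @param n_pairs Number of interval pairs averaged.
#' @param tol Synchrony tolerance handed to [find_sync_spike()].
#' @return Mean relative interval error (dimensionless).
#' @export
err_t <- function(a, b, n_pairs = 20, tol = 0.1) {
  sync <- find_sync_spike(a, b, tol)
  np <- min(n_pairs, nrow(a) - sync$i, nrow(b) - sync$j)
  if (np < 1) stop("insufficient spikes after the synchronous pair")
  dta <- diff(a$t[sync$i + 0:np])
  dtb <- diff(b$t[sync$j + 0:np])
  mean(abs(dtb - dta) / dta)
}

#' Pearson correlation of two voltage waveforms after synchronization
#'
#' Standard Pearson correlation (mean-centred covariance over the product
#' of standard deviations) of the two series over a window following each
#' trace's own synchronous spike -- by default 6 ms, about 3-4 complete
#' spikes.
#'
#' @param trace_a,trace_b Traces with equal sampling step.
#' @param window Correlation window (ms).
#' @param threshold,tol Spike detection threshold and synchrony tolerance.
#' @return Correlation in `[-1, 1]`.
#' @export
corr_traces <- function(trace_a, trace_b, window = 6,
                        threshold = -20, tol = 0.1) {
  sa <- detect_spikes(trace_a, threshold)
  sb <- detect_spikes(trace_b, threshold)
  sync <- find_sync_spike(sa, sb, tol)
  dt <- trace_a$t[2] - trace_a$t[1]
  w <- round(window / dt)
  ia <- which.min(abs(trace_a$t - sa$t[sync$i]))
  ib <- which.min(abs(trace_b$t - sb$t[sync$j]))
  if (ia + w > nrow(trace_a) || ib + w > nrow(trace_b))
    stop("trace too short for the correlation window")
  va <- trace_a$V[ia:(ia + w)]
  vb <- trace_b$V[ib:(ib + w)]
  if (sd(va) == 0 || sd(vb) == 0) stop("zero variance in correlation window")
  cor(va, vb)
}

#' Classify the spiking mode of a trace
#'
#' Operationalizes the model's five discharge regimes:
#' * interburst gaps (inter-spike intervals above `gap_threshold`) mark the
#'   bursting family;
#' * without gaps, a peak-amplitude coefficient of variation above
#'   `cv_threshold` is amplitude modulation, otherwise fast spiking;
#' * with gaps, a continuous spiking segment longer than `segment_threshold`
#'   marks bursts interspersed with amplitude modulation;
#' * plain bursting splits into Bursting I (long quiescent gaps, mean gap
#'   at least `gap_split`) and Bursting II (shorter gaps, more durable
#'   bursts).
#'
#' @param trace A `"pc_trace"` (at least ~500 ms of post-transient data
#'   for a stable label).
#' @param threshold Spike threshold (mV).
#' @param gap_threshold Inter-spike interval that counts as a burst gap (ms).
#' @param cv_threshold Amplitude coefficient-of-variation bound.
#' @param segment_threshold Spiking-segment duration marking mixed
#'   burst/amplitude-modulation activity (ms).
#' @param gap_split Mean-gap boundary between Bursting I and II (ms).
#' @return One of `"bursting_I"`, `"bursting_II"`, `"bursting_am"`,
#'   `"amplitude_modulation"`, `"fast_spiking"`.
#' @export
classify_mode <- function(trace, threshold = -20, gap_threshold = 20,
                          cv_threshold = 0.02, segment_threshold = 300,
                          gap_split = 50) {
  s <- detect_spikes(trace, threshold)
  if (nrow(s) < 3) stop("no (or too few) spikes in trace")
  isi <- diff(s$t)
  gaps <- which(isi > gap_threshold)
  cv <- sd(s$amp) / abs(mean(s$amp))
  if (!length(gaps))
    return(if (cv >= cv_threshold) "amplitude_modulation" else "fast_spiking")
  brk <- c(0, gaps, nrow(s))
  seg_dur <- vapply(seq_len(length(brk) - 1), function(j)
    s$t[brk[j + 1]] - s$t[brk[j] + 1], numeric(1))
  if (max(seg_dur) > segment_threshold) return("bursting_am")
  if (mean(isi[gaps]) >= gap_split) "bursting_I" else "bursting_II"
}

#' Compare reference and CORDIC traces at one injected current
#'
#' Simulates both backends from the same initial condition (no transient
#' discard, so the early spikes correspond), then reports the spike-timing
#' error and the post-synchronization Pearson correlation together with
#' both mode labels.  The synchrony tolerance is wider than
#' [find_sync_spike()]'s default because the two arithmetics approach the
#' first threshold crossing with a small fixed offset (~0.1-0.2 ms).
#'
#' @param I Injected current (uA/cm^2).
#' @param duration Comparison span (ms).
#' @param params,config Model parameterization.
#' @param n_pairs Interval pairs entering [err_t()].
#' @param window Correlation window (ms).
#' @param sync_tol Synchrony tolerance (ms).
#' @param mode_duration If positive, additionally classify both backends
#'   over this longer span (with 200 ms discard).
#' @return List with `ERRt`, `Corr`, `t_syn`, and mode labels when
#'   requested.
#' @export
compare_traces <- function(I, duration = 400, params = purkinje_params(),
                           config = cordic_model_config(), n_pairs = 20,
                           window = 6, sync_tol = 0.25, mode_duration = 0) {
  ref <- simulate_purkinje(I, duration, params, transient_discard = 0)
  fx <- simulate_purkinje(I, duration, params, transient_discard = 0,
                          backend = "cordic", config = config)
  sa <- detect_spikes(ref); sb <- detect_spikes(fx)
  sync <- find_sync_spike(sa, sb, sync_tol)
  out <- list(I = I,
              ERRt = err_t(sa, sb, n_pairs, sync_tol),
              Corr = corr_traces(ref, fx, window, tol = sync_tol),
              t_syn = sync$t_syn)
  if (mode_duration > 0) {
    out$mode_reference <- classify_mode(
      simulate_purkinje(I, mode_duration, params))
    out$mode_cordic <- classify_mode(
      simulate_purkinje(I, mode_duration, params, backend = "cordic",
                        config = config))
  }
  out
}

#' Error table of the nine CORDIC rate functions
#'
#' Samples the membrane potential over one complete spike waveform of a
#' reference simulation (fast spiking by default), evaluates every rate
#' function with both arithmetics at those voltages, and reports RMSE and
#' mAE per function -- the software analogue of the hardware error table.
#'
#' @param I Injected current selecting the sampling regime.
#' @param params,config Model parameterization.
#' @param spike_index Which spike period to sample (post-transient).
#' @return Data frame with columns `kind`, `RMSE`, `mAE`, `n`.
#' @export
compare_rates <- function(I = -35, params = purkinje_params(),
                          config = cordic_model_config(), spike_index = 10) {
  tr <- simulate_purkinje(I, 2000, params)
  V <- tr$V
  up <- which(V[-1] >= -20 & V[-length(V)] < -20)
  if (length(up) < spike_index + 1) stop("not enough spikes in sampling trace")
  Vs <- V[up[spike_index]:up[spike_index + 1]]
  res <- lapply(rate_kinds(), function(k) {
    fx <- evaluate_rate_cordic(k, Vs, config, params)
    rr <- evaluate_rate(k, Vs)
    st <- abs_error_stats(rr, fx)
    data.frame(kind = k, RMSE = st$RMSE, mAE = st$mAE, n = length(Vs))
  })
  do.call(rbind, res)
}
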