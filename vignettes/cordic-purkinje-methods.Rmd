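---
title: "Methods: bit-accurate CORDIC emulation of a bursting Purkinje cell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bit-accurate CORDIC emulation of a bursting Purkinje cell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cordicpc)
```

## The model

The package emulates a five-channel conductance-based cerebellar Purkinje
cell (the Kramer reduction of the detailed multi-channel models).  The
membrane equation is

$$C \frac{dV}{dt} = -g_K n^4 (V - E_K) - g_{Na} m_\infty(V)^3 h (V - E_{Na})
 - g_{Ca} c^2 (V - E_{Ca}) - g_M M (V - E_M) - g_L (V - E_L) - I$$

with gating dynamics $dx/dt = (x_\infty - x)/\tau_x$ for $n, h$ and
$dx/dt = \alpha_x (1-x) - \beta_x x$ for $c, M$; the sodium activation $m$
is instantaneous.  Note the sign convention: the injected current $I$
enters with a minus sign, so *negative* $I$ depolarizes.  Decreasing $I$
from $-25$ to $-35$ traverses five discharge regimes: Bursting I, Bursting
II, bursts interspersed with amplitude modulation (at the critical current
$I' = -33.09485$), pure amplitude modulation and fast spiking.  The slow
potassium M-current organizes the burst cycle: it accumulates during the
active phase, eventually quenching spiking, and decays during quiescence.

All default conductances, reversal potentials and the Euler step
$\Delta t = 0.004$ ms are the published values of this model.  The membrane
capacitance is never printed with them; we use the conventional
$C = 1\,\mu F/cm^2$ of this model family (configurable).  The initial
condition is $V_0 = -65$ mV with every gate at its steady state, and 200 ms
of transient are discarded by default — except when the two arithmetic
backends are compared spike-by-spike, where both start from the identical
state with no discard.

Integration is explicit Euler with fully synchronous updates: all step
$k+1$ values are computed from step $k$ values only.  This mirrors the
buffered pipeline of the hardware realization, whose latency and
throughput are deliberately *not* modeled.

## The fixed-point CORDIC datapath

The second backend recomputes the identical model using only the
operations available to a multiplier-less, LUT-less digital datapath:

* **Q-format arithmetic.**  Numbers are integer mantissas with 15
  fractional bits; the state datapath carries 8 integer bits (values up to
  $\pm 128$) and the $h_\infty$ exponential node 14 (its intermediate
  $e^{(V+59.4)/10.7}$ reaches $\approx 8000$).  The single rounding mode
  everywhere is truncation toward $-\infty$, which is what a hardware
  right-shift does.
* **Exponentials** are hyperbolic-rotation CORDIC: iterating
  $X, Y$ with the angle base $\tanh^{-1}(2^{-i})$ gives $\cosh$ and
  $\sinh$, and $e^z = \cosh z + \sinh z$.  Because the $X$ and $Y$
  recursions differ only in operand order, their sum iterates autonomously
  as $S_{i+1} = S_i + q_i S_i 2^{-i}$ — the merged form halves the
  datapath without changing any result (`exp_core_merged()` is tested to
  agree with $X + Y$ of the unmerged rotation).  The iteration schedule is
  $i = 1 \ldots 10$ with index 4 repeated: hyperbolic CORDIC only
  converges when indices $4, 13, 40, \ldots$ are iterated twice, and the
  quoted convergence bound 1.1182 is reachable only with those repeats
  (without them the angle sum stalls near 1.056).  Arguments are
  range-extended by $\theta / \ln 2 = A + b$ with $A = \lfloor \cdot
  \rfloor$ (floor, not truncation toward zero, so $b \in [0,1)$ for
  negative arguments too); $2^A$ is a pure shift.
* **Divisions** are linear-mode vectoring CORDIC with range exponent
  $n = 2$ and 20 iterations: angle base $2^{n-i}$, $i = 0 \ldots 19$,
  quotient range $|a/b| < 8$, absolute error $\le 2^{n-\mathrm{iters}+1} =
  2^{-17}$.  All sigmoids are computed as
  $1/(1 + e^x)$ via one exponential and one division; $\beta_c$'s ratio
  divides directly, returning the removable-singularity limit $0.1$ when
  the quantized denominator is zero.  The source states both 12 and 20
  division iterations in different places; 20 governs the reported
  hardware build and is the default, 12 is available via
  `cordic_model_config(div_iterations = )`.  (Empirically the published
  function-error table is consistent with the 12-iteration setting: at 12
  iterations the sigmoid-family RMSE is $\approx 1.1 \times 10^{-3}$,
  matching the printed $\approx 1.3 \times 10^{-3}$, while at 20
  iterations our errors are roughly ten times smaller than printed.)
* **Constant multiplications** decompose the quantized constant into
  canonical signed digits $\sum (-1)^k 2^n$ and sum shifted copies of the
  operand, each right shift truncating.  The decomposition targets the
  *quantized* mantissa, so reconstruction is exact at working precision
  even for constants like $0.02$.
* **Variable products** use the functional shift multiplier: one operand
  (by convention the slower-varying one) is split into bits, each set bit
  contributes the other operand shifted by the bit position, and the
  full-width sum is truncated once into the output format.  This is
  exactly the mantissa product followed by one truncation, which is how
  the emulator computes it and how the exhaustive oracle test checks it.
  Powers use square-and-multiply ($n^4$ as two squarings, $m_\infty^3$ as
  square then multiply).

`evaluate_rate_cordic()` composes each of the nine nonlinear rate laws
from these primitives alone — no native multiply, divide, exponential or
table lookup touches a model quantity, and every result lies exactly on
the $2^{-15}$ grid (a property the tests assert).

### Integrator state width

The one place the emulator is deliberately *wider* than the nominal
15-bit-fraction datapath is the Euler accumulator of each state variable.
The slow gate's per-step increment is below $2^{-15}$ over most of the
burst cycle; with 15-bit state registers and floor rounding, positive
sub-LSB increments vanish while negative ones round down a full LSB, so M
drifts, the limit cycle collapses (spike amplitude 3 mV instead of 16 mV)
and the burst structure is destroyed.  The state accumulators therefore
hold the full precision of the $\Delta t$-product (30 fractional bits —
the multiplication by the quantized $\Delta t / C$ mantissa is exact at
that width), while *every arithmetic tap* reads the 15-bit-fraction
truncation.  This is the standard wide-accumulator idiom of hardware
integrators; the published design does not document its register widths,
and this choice is the only one we found under which the fixed-point model
reproduces the reported trace agreement.

A related sizing observation: the $h_\infty$ exponential node exceeds its
nominal 14-bit range ($2^{13} = 8192$) during spike-peak overshoots (the
first post-onset spike reaches $V \approx 40$, where the node is
$\approx 16000$).  The node is monotone and feeds a reciprocal, so the
emulator saturates it at the declared width — the effect on $h_\infty$ is
below one LSB — and counts the saturations in the arithmetic report.

## Error metrics

* **AE / mAE / RMSE** compare each rate law between arithmetics over the
  voltage samples of one complete reference spike waveform
  (`compare_rates()`, fast-spiking regime by default; the sampling regime
  is a parameter because the published table does not state it).
* **ERRt**, the spike-timing error, pairs consecutive inter-spike
  intervals starting at a synchronous spike pair and averages the
  relative differences over 20 measurement points.  It is reported
  non-negative and is asymmetric in which model supplies the denominator
  (the reference does).
* **Corr** is the standard Pearson correlation of the two voltage
  waveforms over 6 ms (3–4 spikes) following each trace's own synchronous
  spike.  (The printed formula omits the square root on the standard
  deviations; values near 0.99 are only consistent with standard Pearson,
  which is what we implement.)
* **Synchronization**: `find_sync_spike()` takes the first pair of spikes
  agreeing within 0.1 ms.  The comparison harness `compare_traces()` uses
  a wider 0.25 ms tolerance: starting from the identical initial state,
  the two arithmetics approach the first threshold crossing with a fixed
  offset of 0.1–0.2 ms (largest in Bursting I, where the depolarization
  ramp is slowest), and the first corresponding spike pair — not a
  coincidental later alignment — is the right anchor.

With the default widths, ERRt is $\approx 2 \times 10^{-3}$ and Corr
$\ge 0.997$ in all five regimes, against printed values of
$(0.5\text{–}4) \times 10^{-3}$ and $0.98$–$0.998$.  Roughly a quarter of
the residual interval error is the $\Delta t$ quantization itself
($131/2^{15} = 0.0039978$ effective vs 0.004 nominal, a $5.5 \times
10^{-4}$ relative clock-rate offset); the rest is accumulated truncation
bias in the rate laws.

One published figure is not reproducible under the documented rounding
rule: the $\alpha_M$ RMSE of $1.42 \times 10^{-5}$ equals the bare
output-quantization floor $\mathrm{LSB}/\sqrt{3} = 1.8 \times 10^{-5}$ (to
within sampling), i.e. a datapath whose output is truncated exactly once.
Our $\alpha_M$ path — sigmoid division followed by a canonical-signed-digit
multiplication by $0.02$, with every right shift truncating — carries
$\approx 1.2$ LSB of additional systematic bias and lands at
$4.4 \times 10^{-5}$, a factor 3.1 from the printed value (every other
rate law is at or below its printed error).  Reaching the printed figure
would require round-to-nearest constant multipliers or a single-truncation
dataflow, either of which contradicts the truncation-everywhere
convention adopted here; we keep the convention and document the gap.

## Mode classification

`classify_mode()` operationalizes the five regimes from the spike train:
inter-spike gaps above 20 ms mark the bursting family; without gaps, a
peak-amplitude coefficient of variation of 2 % separates amplitude
modulation from fast spiking; with gaps, a continuous spiking segment
longer than 300 ms marks bursts interspersed with amplitude modulation
(measured segment durations: $\le 140$ ms for plain bursting,
$\ge 426$ ms at $I'$); plain bursting splits into Bursting I vs II at a
mean interburst gap of 50 ms (measured: 75 ms at $I = -25$, 36–46 ms at
$-28$ to $-30$).  The thresholds were chosen once to separate the regimes
with wide margins and are all configurable.  The CORDIC backend reproduces
all five regimes with its critical region shifted from
$-33.095 \ldots -33.2$ down to $-33.29 \ldots -33.40$, consistent with the
published observation that the modified model shows the same activities at
slightly different currents.

## Fast–slow decomposition

Freezing the slow gate M turns the fast subsystem $(V, n, h, c)$ into a
one-parameter family.  `fast_fixed_points()` scans the steady-state
current balance on a 0.01 mV grid over $[-100, 40]$ mV and bisects each
sign change (to residual $10^{-8}$ for the smooth reference laws; to
voltage resolution $10^{-6}$ for the quantized laws, whose residual is a
step function).  Because the quantized residual wobbles by a couple of LSB
around zero along shallow branches, a single root can fragment into a
tight cluster of sign changes; roots closer than 0.5 mV are therefore
merged for the CORDIC backend.  Stability comes from the eigenvalues of a
finite-difference Jacobian (step $10^{-6}$) of the 4-D fast subsystem.
Folds are detected as changes in branch count between adjacent M grid
points — which is also the internal consistency oracle used in tests.
Attracting limit cycles are characterized by clamped-M simulation from a
depolarized start ($V_0 = -20$: in the bistable M window this selects the
spiking orbit, matching how the full system's burst enters the active
phase); repelling cycle branches would require numerical continuation and
are out of scope.

At $I'$ both backends find a single fold of fixed points at
$M \approx 0.3375$, inside the M interval $[0.316, 0.535]$ visited by the
full system's burst — the geometry that produces bursts interspersed with
amplitude modulation.

## The two-cell network

Two cells are coupled reciprocally with first-order synaptic gates
$dz/dt = s(V_{src})(1-z)/\tau_1 - z/\tau_2$, $s(V) = (1+\tanh(V/10))/2 =
1/(1+e^{-V/5})$ (the latter form is what the fixed-point datapath
computes).  The pre cell is driven at $I = -25$ (bursting), the post cell
at $-34$ (fast spiking); $W = 0.5$; the gate feeding the pre cell uses the
printed GABA$_A$ pair $(\tau_1, \tau_2) = (0.5, 10)$ ms, the gate feeding
the post cell the printed AMPA pair $(0.2, 2)$ ms.

The printed synaptic equation set is internally inconsistent (an illegible
prefactor, subscripts that mix source and target, and an "excitatory
current received through GABA$_A$ receptors"), so the implemented
convention was reconstructed from the stated phenomenology, which is
unambiguous: coupling must leave the pre cell bursting with a *longer*
interburst period and switch the post cell from fast spiking to bursting.
An exhaustive scan of the 256 sign/reversal/time-constant/scale
assignments consistent with the printed fragments shows this phenomenology
pins the structure down to essentially one choice (the package default):

* into the pre cell: $-W z_{post}(V_{pre} - V_{inh})$ — with the model's
  inverted stimulus convention this is a spike-gated depolarizing drive;
  the extra depolarization during bursts builds more M-current per burst,
  which is exactly what lengthens the interburst gap (75 ms uncoupled
  $\to$ 122 ms coupled, reference backend);
* into the post cell: $+2 W z_{pre}(V_{post} - V_{inh})$ — a conventional
  inhibitory conductance with the printed factor 2, gated by the bursting
  pre cell, which imposes the burst rhythm on the post cell.

Variants using $(V_{pre} - V_{ex})$ with $V_{ex} = 0$, in any sign, either
silence the pre cell ($\approx 22\,\mu A/cm^2$ of tonic drive) or push it
past the bursting regime entirely; $V_{ex}$ remains available in
`synapse_params()` for user-defined conventions.  With $W = 0$ the coupled
run is bit-identical to the uncoupled one, and the CORDIC backend
reproduces the same coupled phenomenology as the reference.

## Determinism, degenerate inputs, problem sizes

There is no randomness anywhere: simulations, comparisons and CLI
artifacts are byte-identical across reruns, which the tests assert via
checksums.  Degenerate inputs are handled explicitly: zero-duration
simulations return the initial state; flat traces yield empty spike
trains; `beta_c`'s singularity and zero quantized denominators return the
analytic limit; datapath overflow stops with the step index under the
default policy (the `h_inf` node saturation described above is the single
documented exception).

Default analysis spans were chosen as the shortest that make every
quantity stable: 2200 ms (200 discarded) for mode classification — the
longest mixed segment at $I'$ is $\approx 1300$ ms, so shorter spans
misclassify the critical regime — and 400 ms, no discard, for
backend-comparison metrics, which only need ~21 paired intervals after the
first synchronous spike plus a 6 ms correlation window.  The bifurcation
grid uses $M \in [0.30, 0.60]$ in steps of 0.005, covering the burst's
visited range with margin.

## Known limitations

* The emulator validates arithmetic, not timing: pipeline latency,
  throughput and resource counts of a hardware realization are out of
  scope.
* Repelling limit-cycle branches of the fast subsystem are not computed
  (no continuation); the diagram's skeleton is fixed points, folds and
  attracting orbits.
* The published $\alpha_M$ RMSE is unreachable under truncation-everywhere
  rounding (see above); and function-level errors at the default 20
  division iterations are generally *smaller* than the printed table,
  which appears to reflect the 12-iteration setting.
* The synaptic convention, while uniquely selected by the published
  phenomenology among the printed fragments, remains a reconstruction.
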