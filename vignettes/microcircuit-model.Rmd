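---
title: "A heterogeneous layer 2/3 microcircuit model and its processing capacity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A heterogeneous layer 2/3 microcircuit model and its processing capacity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetmicro)
```

## The model

`hetmicro` implements a point-neuron model of a layer 2/3 cortical
microcircuit at the scale of an anatomical column: N = 2500 neurons, 80%
excitatory pyramidal cells (E) and 20% GABAergic interneurons split
35%/65% into fast-spiking (I1) and non-fast-spiking (I2) classes. All
neurons follow an adaptive leaky integrate-and-fire scheme,

$$C_m \dot V = -g_{leak}(V - E_{leak}) - I_{adapt} - \textstyle\sum I^{syn} + I_{inj},
\qquad
\tau_w \dot I_{adapt} = -I_{adapt} + a\,(V - E_{leak}),$$

with a spike-triggered increment $I_{adapt} \mathrel{+}= b$ at threshold
crossings, reset to `V_reset`, and an absolute refractory period. The
adaptation couplings are class-specific: E = (4 nS, 30 pA), I1 = (0, 0),
I2 = (2 nS, 10 pA), so fast-spiking interneurons carry no intrinsic
adaptation.

Synapses are conductance-based with four receptor types per postsynaptic
class. An excitatory synapse activates AMPA and NMDA receptors of the
target class, an inhibitory one GABA~A~ and GABA~B~. The single-spike
conductance transient is

$$g(t) = \bar g\, n(V)\,
  [1 - e^{-t/\tau_{rise}}]\,
  [r\, e^{-t/\tau_f} + (1-r)\, e^{-t/\tau_s}]\,\Theta(t),$$

with the voltage-gating function $n(V)$ equal to 1 except at NMDA
receptors, where it models the magnesium block,
$n(V) = (1 + ([\mathrm{Mg}^{2+}]/3.57)\,e^{-0.062V})^{-1}$ at a fixed
1 mM magnesium concentration. Each connection carries a dimensionless
weight multiplying the receptor conductances and a conduction delay
restricted to multiples of the 0.1 ms simulation grid.

Three sources of heterogeneity can be toggled independently when building
a circuit (`build_microcircuit(condition =)`):

* **Neuronal (`Neu`)** — single-cell parameters drawn per neuron from
  class-specific normal/lognormal distributions instead of the
  representative values.
* **Synaptic (`Syn`)** — weights and delays drawn from lognormal
  distributions whose means equal the homogeneous values (delays
  left-truncated at 0.1 ms and snapped to the grid).
* **Structural (`Str`)** — connection blocks with skewness parameters
  draw their pre-/postsynaptic indices from truncated exponential
  distributions, producing broad degree distributions at exactly the
  expected edge count; when structural *and* synaptic heterogeneity are
  both active, per-neuron lognormal factors
  $\zeta \sim \mathrm{logN}(-c^2/2,\, c)$ additionally rescale the
  weights, inducing correlations among weights sharing a pre- or
  postsynaptic neuron while preserving the mean (E[$\zeta$] = 1).

`Hom` disables all three; `Het` enables all three. Component generators
consume independent sub-seeds, so conditions built from one master seed
share every component their flags leave untouched — this is what makes
condition comparisons paired rather than merely distributional.

## Inputs and states

The circuit is driven by two inputs. *Background*: every neuron receives
an independent Poisson stream at rate $K_{in}\,\nu_{in}$ (default
$K_{in} = 1000$) through an excitatory synapse with its class's mean
E-originating weight; this collapses the $K_{in}$ identical sources into
one count process, which is statistically exact. The circuit driven by
background alone is the *quiet* state. *Signal*: a piecewise-constant
current $\rho_u\,u[n]$, $u[n] \sim U[0,1]$ i.i.d. held for $\Delta t$ ms,
injected into a random 25% of the E population — the *active* state used
for all processing-capacity measurements.

## Numerical scheme

Integration uses a fixed 0.1 ms grid. Receptor conductances are exact:
each receptor is a bank of four exponentially decaying state variables
(the expansion of the rise-times-decay product), decayed analytically
each step and incremented at spike arrivals, so superposition of
single-spike waveforms holds to machine precision on the grid. Within a
step the conductances and the NMDA gating factor (evaluated at the
step's initial voltage) are held fixed, making the membrane/adaptation
pair a linear 2-D system advanced with a classical RK4 step. Spikes are
detected at grid points; refractoriness clamps the membrane at
`V_reset` for the ceiling of $t_{ref}/0.1\,\mathrm{ms}$ steps. A
convergence test (halving the step) guards this choice; spike counts at
0.05 ms agree with 0.1 ms at the few-percent level expected from the
stochastic background.

Two conventions deserve emphasis because the parameter tables do not fix
them:

* **No peak renormalization.** $\bar g$ scales the raw waveform above,
  whose realized peak is below $\bar g$ because the rise gate has not
  saturated when decay begins. We verified that this convention — not a
  renormalization to peak $\bar g$ — reproduces the reference PSP
  amplitudes (e.g. 0.83 mV vs the quoted 0.82 mV for the unit-weight
  excitatory PSP on E; renormalizing gives 1.28 mV).
* **$\tau_w$ = 90 ms.** The adaptation time constant is not part of the
  published parameter set. It is, however, pinned by the published PSP
  triple for the E class (amplitude 0.82 mV, rise 3.16 ms, decay
  17.8 ms): with $a = 4$ nS the fitted PSP decay is a monotone function
  of $\tau_w$ (144 ms ⇒ 20.2 ms, 90 ms ⇒ 17.8 ms). The default is
  therefore 90 ms, exposed as `tau_w` everywhere.

Two further interpretive choices: excitatory PSP benchmarks are recorded
from rest and inhibitory ones at a −55 mV holding potential (maintained
by a constant bias current) — the combination under which the published
PSP table is internally consistent; and heterogeneous membrane sampling
draws `C_m` and `g_leak` (the model's native parameters, both with
published distributions) and derives `tau_m = C_m/g_leak`, since the four
published membrane rows are mutually redundant and not jointly
consistent. The alternative (`C_m`, `tau_m`) convention is available via
`sample_population(primary = "Cm_taum")` and leaves the population
dynamics essentially unchanged.

Known residual discrepancies: the inhibitory PSP amplitudes onto I1 and
I2 neurons come out at −0.30 and −0.43 mV against quoted values of −0.25
and −0.6 mV; no waveform or protocol convention we tested reconciles
both rows while preserving the five rows that do match, so we treat this
as an inconsistency of the source table and report our faithfully
simulated values. Relatedly, the quiet-state E/I current correlation
under neuronal heterogeneity stabilizes at −0.71 across seeds and
conventions, somewhat weaker than the quoted −0.8 (the homogeneous value
−0.64 is reproduced exactly).

## Activity metrics

`spike_statistics()` reports mean rate, pairwise spike-count correlation
(CC; Pearson over 500 random disjoint pairs, 2 ms bins by default —
reported with the bin size, since CC depends on it), the coefficient of
variation of inter-spike intervals (neurons with fewer than 10 ISIs are
excluded and counted), the 5th ISI percentile (burstiness) and the
entropy of the binned log-ISI density (Freedman–Diaconis bins; entropy
is bin-width sensitive, so the rule is fixed). `ei_balance()` summarizes
per-neuron mean excitatory/inhibitory currents and their zero-lag
correlation. `effective_time_constant()` computes
$\tau_{eff} = C_m/\langle G_{total}\rangle \le \tau_0 = C_m/g_{leak}$.

`intrinsic_timescale()` fits
$R(\tau) = a[\exp(-\tau/\tau_{int}) + b]$ to the membrane-potential
autocorrelation over lags up to `max_lag`. The autocorrelation of a
conductance-driven neuron is multi-exponential (receptor timescales span
0.7–600 ms), so the fitted constant grows with the window; we fix the
population default at `max_lag` = 1000 ms — the largest window a 10 s
recording supports at the recommended ten-samples-per-lag margin — and
evaluate the circuit-level summary on the E population, whose membrane
potentials are the state variables of all processing analyses. Traces
whose autocorrelation already falls below $1/e$ at the first lag get
their timescale from that value directly (they are unresolved by the
sampling grid). On Ornstein–Uhlenbeck traces with known correlation
times 10–200 ms the fit recovers the truth within 10% from 100 s of
data at windows of five correlation times.

The fI-curve summary discards an onset `settle` window (default 500 ms):
with slow adaptation, a current step from rest transiently overshoots
the adapted fixed point and can fire a few onset spikes below the
stationary rheobase $(g_{leak} + a)(V_{thresh} - E_{leak})$; sustained
firing, which is what the rheobase ordering between classes refers to,
begins at the stationary value.

## Processing capacity

For capacity measurements the state matrix X collects every E neuron's
membrane potential at the last grid point of each input step
(`harvest_states()`, initial states $V_0 \sim U[E_{leak}, V_{thresh}]$,
100 washout steps discarded). The capacity to reconstruct a target
$z[n]$ is the variance fraction captured by an ordinary least-squares
readout on the mean-centered states,
$C[X, z] = 1 - \|z - \hat z\|^2/\|z\|^2 \in [0, 1]$, computed through a
QR decomposition shared across all targets on the same window.

Targets are products of Legendre polynomials of the delayed input,
$z[n] = \prod_k P_{d_k}(2u[n-k] - 1)$, normalized by $\sqrt{2d+1}$. The
input is remapped from $[0,1]$ to $[-1,1]$ before evaluation — required
for the family to be orthonormal under the uniform input measure, which
is what makes individual capacities measure independent properties.
Scores below $2\,N_{state}/T$ are zeroed before aggregation to control
finite-sample inflation (the expected capacity of pure noise is
$N_{state}/T$; we verify this bias empirically). The memory curve is the
degree-1 family $C(k)$, $k = 0..k_{max}$, and $C_M = \sum_k C(k)$; total
capacity sums thresholded scores over total degrees up to `d_max` with
at most three simultaneous factors and per-degree enumeration budgets —
deliberately incomplete at high degree, so $C_T$ is a lower bound.
`optimal_resolution()` scans the input step $\Delta t$ for the smallest
value at which $C_{d=1,k=0} \ge 0.99$.

## Problem sizes and what the tests show

The test-suite and acceptance computations use these scales, chosen as
the package's reference desk-scale conditions:

* Single-neuron benchmarks (PSPs, fI curves): exact scales, seconds.
* Quiet-state population statistics: the full N = 2500 circuit, 10 s of
  activity, background at 10 spikes/s, three seeds. These reproduce the
  reference values directly (fraction of active E neurons, E/I current
  correlation, E-population intrinsic timescale).
* Capacity: reduced circuits (N = 250, preserving the population
  fractions and all densities) with T = 5000 input steps at
  $\Delta t$ = 20 ms, $\rho_u$ = 300 pA, $\nu_{in}$ = 5 spikes/s, chosen
  once as a surrogate active state (the published per-condition tuning
  targets full-scale operating points and has no admissible point at
  N = 250). At this scale the reproducible condition-level result is
  the ordering $C_M(\mathrm{Hom}) < C_M(\mathrm{Het}) <
  C_M(\mathrm{Str})$; the full-scale capacity values (e.g.
  $C_M \approx 2.67$ for the homogeneous circuit) and the advantage of
  neuronal heterogeneity require the full N = 2500, T = $10^5$ runs,
  which the same code supports but which take hours.

The synthetic background emulates stationary, unstructured cortical
bombardment; passing tests therefore say nothing about responses to
spatiotemporally structured (naturalistic) input, about plasticity (the
model has none), or about spatial connectivity — all outside the model's
scope.

## A worked example

```{r, eval = FALSE}
library(hetmicro)

mc <- build_microcircuit(N = 2500, condition = "Hom", seed = 1)
res <- simulate_circuit(mc, stimulus_program(nu_in = 10),
                        duration = 10000, seed = 2,
                        record = c("V", "currents"))

# excitation/inhibition balance on the E population
bal <- ei_balance(res)
bal$CC

# intrinsic timescale of E membrane potentials
pt <- population_timescale(res, ids = seq_len(mc$sizes[["E"]]))
pt$mean
```
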