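---
title: "A hierarchical neural-network model of vagal nerve stimulation and heart-rate control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hierarchical neural-network model of vagal nerve stimulation and heart-rate control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(vnsnet)
```

## The problem

Vagal nerve stimulation (VNS) delivers intermittent electrical current to the
cervical vagosympathetic trunk. The trunk is a bundle: afferent axons,
sympathetic efferents, parasympathetic efferents that synapse *directly* onto
cardiac motor neurons, and parasympathetic efferents that synapse *indirectly*
through local circuit neurons of the intrinsic cardiac and intrathoracic
ganglia. A cuff electrode cannot recruit these components separately, which is
why the heart-rate response to graded VNS is famously non-monotone: nothing at
low current, tachycardia at moderate current, bradycardia at high current.

`vnsnet` implements a simulator in which the components *can* be activated
separately. Heart rate is controlled by a three-level hierarchical network of
neurons (cardiac, intrathoracic, central), and VNS is modelled as two
independent mechanisms — an *indirect* one acting on the sensitivities of
network neurons, and a *direct* one acting on the gain of the direct
parasympathetic motor pathway. The package regenerates the four canonical
stimulation regimes (baseline, subthreshold, sympathetic threshold,
parasympathetic threshold) and exposes the full network activity map that no
in-vivo preparation can record.

## Model structure

### The neuron population

The network holds `3 * N` neurons divided equally among three levels
(1 = cardiac, 2 = intrathoracic, 3 = central). In the canonical configuration
`N = 600`; the 600 cardiac-level neurons comprise 500 sympathetic neurons and
100 indirect-parasympathetic neurons, and levels 2–3 are sympathetic. Each
neuron carries a scaled state of activity in `[0, 1]` (1 = maximal discharge,
0 = silent) and belongs to one response class:

* **heart-rate neurons** respond only to (delayed) heart rate and to their
  neighbours;
* **blood-demand neurons** respond only to the prevailing demand for blood
  flow and to their neighbours.

Heart-rate neurons sit mainly low in the hierarchy and blood-demand neurons
mainly at the central level; the default fractions of heart-rate neurons per
level are (0.8, 0.5, 0.2). "Mainly" is all the biology pins down, so the
fractions are configuration values, and which particular indices carry each
class is drawn from the run seed.

### Per-interval neuron dynamics

Time advances in discrete intervals `k` (default 1 s each). Writing `A_i` for
the activity of neuron `i`, `M` for the mean activity over the entire network,
`H_d` for the scaled heart rate delayed by `tau_delay` intervals and `D` for
demand, one synchronous update is

```
sympathetic     heart-rate  neuron:  dA = -beta_H (H_d - M)
parasympathetic heart-rate  neuron:  dA = +beta_H (H_d - M)
sympathetic     blood-demand neuron: dA = +beta_D (D - M)
parasympathetic blood-demand neuron: dA = -beta_D (D - M)
networking (every neuron):           dA = sum_J w_iJ (A_J - A_i)
```

followed by clipping to `[0, 1]`. All terms are evaluated on interval-`k`
values (a synchronous update: the equations are indexed on a single interval,
so no within-interval ordering is imposed). The branch signs make sympathetic
and parasympathetic responses to the same input error opposed. For the
heart-rate class this closes a delayed negative-feedback loop — rate above the
network-mean reference withdraws sympathetic and recruits parasympathetic
activity — and that delayed loop, perturbed by demand noise, is the source of
the baseline heart-rate oscillation. For the blood-demand class, demand above
the reference recruits the sympathetic branch.

This sign orientation is a substantive design choice. We evaluated every
branch-sign assignment of the `(input - M)` increments in simulation: the
orientation above is the only one that simultaneously (i) keeps the closed
loop stable (the mirrored heart-rate orientation is positive feedback and
rails heart rate to a bound), and (ii) lets the two stimulation mechanisms
produce the tachycardia/bradycardia phenomenology described below.

### Networking topology

The biology states that neurons interact within their own level and with
adjacent levels, but no wiring diagram exists. We use sparse local coupling:
each neuron links to its `m = 2` nearest same-branch indices within its level
(circular index distance) and its `m = 2` nearest aligned indices in each
adjacent level, with uniform weight `w0 = 0.05`. Networking is within-branch
because the sympathetic and parasympathetic networking sums are written over
their own populations. Both `m` and `w0` are configuration values; sparse
local coupling reproduces the "networking" construct without inventing an
arbitrary dense matrix.

### Efferent drives and the move

Three first-order pathways convert network state into a heart-rate increment:

* sympathetic drive `S` relaxes toward `g_s (mean cardiac sympathetic
  activity - ref_s)` with time constant `tau_s`;
* indirect parasympathetic drive `P_ind` relaxes toward `g_p (mean cardiac
  parasympathetic activity - ref_p)` with `tau_p`;
* direct parasympathetic drive `P_dir` bypasses the network and relaxes
  toward `g_r (beta_H_direct * H + beta_D_direct * D - ref_r)` with `tau_r`.

Each relaxation uses the exact exponential step (factor `exp(-1/tau)`), which
is unconditionally stable and matches the closed form the tests pin. The
per-interval heart-rate *move* is

```
dH_k = a_s S - a_p P_ind - a_r P_dir
```

so the sympathetic contribution raises rate and both parasympathetic
contributions lower it. Within each interval, the scaled heart rate `H`
relaxes continuously toward `H_k + dH_k` as a first-order linear system with
time constant `tau_H`, sampled on a uniform grid (default 20 samples per
interval) and clipped to `[0, 1]`; the interval-end value seeds the next
interval and the delayed-feedback history. Drives themselves are not clipped
— only activities and `H` are range-limited quantities.

## Parameters and defaults

| parameter | default | units | role |
|---|---|---|---|
| `g_s, g_p, g_r` | 1 | — | pathway gains |
| `tau_s, tau_p, tau_r` | 5 | intervals | drive time constants |
| `ref_s, ref_p, ref_r` | 0 | — | drive reference levels |
| `a_s, a_p, a_r` | 0.1 | — | move coefficients |
| `beta_H_direct, beta_D_direct` | 0.5 | — | direct-pathway sensitivities |
| `tau_H` | 0.5 | s | within-interval heart-rate time constant |
| `tau_delay` | 3 | intervals | heart-rate feedback delay |
| `interval_duration` | 1 | s | seconds per interval |
| `beta_H, beta_D` (network) | 0.015 | — | neuron sensitivities |
| `w0`, `m` | 0.05, 2 | — | networking weight / neighbours |

Notes on the non-obvious choices:

* **Reference levels are 0**, so each drive is non-negative whenever its
  forcing input is (activities and rates live in `[0, 1]`). This keeps the
  move decomposition interpretable: every drive pulls in its own fixed
  direction, and stimulation of `a_r` is guaranteed bradycardic.
* **`beta_H = beta_D = 0.015`.** The sensitivities set the gain of the
  delayed feedback loop and hence the baseline oscillation amplitude. The
  governing requirement is an oscillation that is visible but non-saturating.
  At 0.1 the loop produces large relaxation oscillations that repeatedly rail
  `H` at 0 with strongly seed-dependent amplitude; at 0.015 the oscillation
  is uniform across seeds (post-warm-up standard deviation of `H` about
  0.02, mean near 0.2 — the lower third of the scaled range) and never
  saturates. This value was fixed once, during model calibration, together
  with `tau_delay = 3`.
* **`beta_H_direct = beta_D_direct = 0.5`** put the direct drive's baseline
  fixed point at a positive but modest value (about `0.5 H + 0.5 D ~ 0.2`),
  so the direct pathway exerts tone at rest and direct stimulation has a
  proportional effect.

## Vagal nerve stimulation

Stimulation follows the experimental duty cycle: each cycle is 14 s ON
followed by 108 s OFF (122 s per cycle), five cycles by default, after a
200-interval unstimulated warm-up that is excluded from response statistics.
Pulse-level electrical detail (pulse width, frequency, mA) is out of scope:
stimulation is a phase-level state, and intensities are model units.

While ON, two mechanisms apply simultaneously and non-accumulatingly (OFF
intervals restore baseline values exactly):

* **indirect** — every heart-rate neuron's `beta_H` decreases by
  `delta_H_sens` (floored at 0) and every blood-demand neuron's `beta_D`
  increases by `delta_D_sens`, in both branches. The first is afferent
  withdrawal: it removes the restraint that delayed heart rate exerts on the
  sympathetic population and the excitation it provides to the
  parasympathetic one. The second raises central drive: blood-demand neurons
  concentrate at the central level, so their amplified response propagates
  down the sympathetic hierarchy through networking.
* **direct** — the move coefficient `a_r` increases by `direct_increment`,
  scaling up the bradycardic pull of the direct parasympathetic pathway.

Shifts are additive (a single intensity knob comparable across neurons), and
no mapping from milliamperes to model units is attempted.

### Scenario presets and their calibration

The biology specifies relative, not absolute, intensities: subthreshold is
"minimal indirect, direct off", the sympathetic threshold is "stronger
indirect, direct off", and the parasympathetic threshold keeps those indirect
intensities and turns the direct mechanism on. The package freezes one point
per regime:

| preset | `delta_H_sens` | `delta_D_sens` | `direct_increment` |
|---|---|---|---|
| baseline | 0 | 0 | 0 |
| subthreshold | 0.002 | 0.005 | 0 |
| sympathetic_threshold | 0.015 | 0.08 | 0 |
| parasympathetic_threshold | 0.015 | 0.08 | 0.3 |

These values were calibrated once, by a sweep over 16 seeds at the default
network, so that the regime ordering holds in every seed — subthreshold
stays inside the 0.02 classification margin while measurably perturbing the
network, the sympathetic threshold clears the margin upward, and the
parasympathetic threshold clears it downward — and were not revisited
afterwards. They are ordinary configuration values: `scenario_preset()`
exposes them and the `sweep` CLI subcommand explores the intensity plane.

### Response classification

`classify_response()` compares mean scaled heart rate during ON and OFF
phases over the post-warm-up intervals: `delta > margin` is tachycardia,
`delta < -margin` bradycardia, otherwise none. The default margin of 0.02
scaled units was chosen during calibration to exceed the ON/OFF mean
differences that baseline oscillation alone produces under the default run
geometry, so a classified response is stimulation-locked rather than
oscillation aliasing.

## Synthetic inputs

Demand is the regime's only exogenous signal:
`D_k = clip(base_level + eps_k, 0, 1)` with i.i.d. Gaussian noise,
`base_level = 0.2`, `noise_sd = 0.02` — constant low demand with low-level
noise, the regime in which the characteristic noisy baseline oscillation
appears. The demand trace is the single stochastic input: neuron updates and
drives are deterministic given the seed, which makes every scenario contrast
an exact ablation (two runs with the same seed share the network and the
demand realisation).

What the generator does *not* emulate: physiological demand waveforms
(exercise, posture, baroreflex challenges), beat-to-beat variability (`H` is
a scaled rate, not an RR-interval surrogate), afferent transduction beyond
the delayed-rate input, pharmacology, and any electrode physics. Passing
tests therefore demonstrate the internal consistency and the qualitative
stimulation phenomenology of the model — not quantitative agreement with any
recorded animal.

## A worked run

```{r regimes}
suite <- run_suite(seed = 1, n_per_level = 60)
for (nm in c("baseline", "subthreshold", "sympathetic_threshold",
             "parasympathetic_threshold"))
  print(suite[[nm]])
```

```{r plots, fig.height = 3.2}
plot(suite$sympathetic_threshold)
plot(suite$parasympathetic_threshold)
```

The subthreshold dissociation — the scientifically loaded observation — is
that heart rate is indistinguishable from baseline while the network is not:

```{r dissociation}
abs(hr_on_off_delta(suite$subthreshold))          # inside the 0.02 margin
mean(abs(suite$diff_map))                         # network moved anyway
```

```{r map, fig.height = 4}
plot_activity_map(suite$diff_map, zlim = c(-0.2, 0.2),
                  main = "subthreshold - baseline activity difference")
```

## Numerical choices

* **Exact exponential integration** for every first-order system (drives and
  within-interval heart rate): unconditionally stable, and the interval-end
  rate is independent of the sampling density to machine precision.
* **Clipping, not sigmoidal saturation**, enforces the `[0, 1]` activity and
  rate ranges: the model states the scale, not a saturation mechanism.
* **Whole-interval delay** with cold-start padding by the initial rate; no
  sub-interval interpolation, because the network equations are
  interval-indexed.
* **Synchronous updates** with deterministic neighbour selection
  (ties broken toward the smaller index), so runs are bit-reproducible.
* **Warm-up of 200 intervals** excluded from classification, removing the
  transient from the uniform initial activity (0.5) and initial rate (0.2).
* Degenerate inputs are rejected at construction time with the offending
  field named (`vns_parameters()`, `vns_protocol()`, the network builder).

## Problem sizes

The test suite exercises the full 1800-neuron configuration for the regime
and dissociation checks (five seeds, 810 intervals each, a few seconds per
run) and reduced networks of 12–180 neurons for oracle and behavioural
checks. `scripts/acceptance.R` re-runs the full-size suite from scratch and
writes the headline numbers as JSON.

## Known limitations

* The wiring is a stylised nearest-neighbour lattice; no attempt is made to
  infer realistic ganglionic connectivity, and whether within-level and
  cross-level weights should differ is unknown (they are equal by default).
* Scaled heart rate is not mapped to beats per minute: the affine constants
  (base and maximum rate) are preparation-specific and are not modelled, so
  all exports stay in scaled units.
* Stimulated-regime intensities are calibrated points, not measurements;
  only the ordering and the qualitative phenomenology carry meaning.
* The parasympathetic network population exists only at the cardiac level in
  the canonical configuration; exploring parasympathetic populations at
  higher levels is possible through `neuron_population()` but uncalibrated.
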