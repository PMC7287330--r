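---
title: "Emulation, history matching and sensitivity analysis of a 0D left ventricle"
author: "emuwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emulation, history matching and sensitivity analysis of a 0D left ventricle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emuwave)
```

## The problem

Multi-scale models of heart contraction map a handful of cell-, tissue- and
haemodynamics-level parameters to organ-scale readouts such as ejection
fraction and peak ventricular pressure. Fitting such models to measurements,
or asking which parameters drive which readouts, requires far more model
evaluations than a simulator costing hours per run permits. The standard
machine-learning remedy is a probabilistic surrogate: per-output Gaussian
process emulators (GPEs) trained on a designed set of simulations, then used
in place of the simulator for Bayesian history matching (HM) and for
variance-based global sensitivity analysis (GSA).

`emuwave` implements that full loop as reusable, tested components, together
with a fast 0D left-ventricle simulator that plays the role of the expensive
multi-scale model at desk scale. Every stage — designs, simulation, feature
extraction, emulation, HM, GSA — is exercisable end to end in minutes.

## The 0D heart simulator

The simulator is a time-varying-elastance left ventricle coupled to a
three-element Windkessel. It is deliberately simple: its purpose is to
provide a realistic *shape* of problem — an 8-parameter to 12-feature
nonlinear map with interactions, heteroscedastic output scales and a
physiologically structured failure region — not to reproduce any particular
3D mechanics model.

State variables per beat (units kPa, µL, ms):

* activation $A$: Hill-type calcium binding,
  $\dot A = k_\mathrm{on}\,\mathrm{Ca}(t)^2 (1-A) - k_\mathrm{off} A$ with
  $k_\mathrm{on} = k_\mathrm{off}/ca_{50}^2$ (Hill coefficient fixed at 2);
* cross-bridge tension fraction $X$: first-order lag
  $\dot X = k_\mathrm{xb}(A - X)$;
* cavity volume $V$ and Windkessel pressure $P_\mathrm{wk}$.

Cavity pressure combines an exponential passive law and a volume-scaled
active term,
$$P(V, X) = c_1\left(e^{\beta (V-V_0)/V_0} - 1\right)
  + \alpha\, T_\mathrm{ref}\, X\, \frac{V}{V_0}.$$
Filling is driven by the constant preload $p$ through a mitral resistance;
when $P$ exceeds the Windkessel pressure the aortic valve opens and ejection
follows $q = (P - P_\mathrm{wk})/z$, with
$\dot P_\mathrm{wk} = (q - (P_\mathrm{wk} - ap)/R_p)/C$, so the distal
pressure relaxes to the aortic-pressure parameter $ap$ in diastole. Valve
events are detected by sign change with linear interpolation of the event
time. Integration is classical RK4 at a fixed step (0.05 ms, adjusted to
divide the cycle); four beats are run at 6 Hz and only the fourth beat is
analysed, the first three being wash-in.

The fixed calcium drive is a skewed pulse
$\mathrm{Ca}(t) = \mathrm{Ca}_\mathrm{dia} + \Delta\mathrm{Ca}\,(t/\tau)
 e^{1 - t/\tau}$, peaking exactly at $t = \tau$.

A simulation can fail in a structured way: if contraction is insufficient to
reach the aortic pressure the aortic valve never opens in the final beat and
the run is flagged `no_ejection`; integrator degeneracies are flagged
`numerical_failure`. Failures are data (they remain in the batch table with
`NA` features), mirroring how expensive simulators lose a fraction of their
design points.

### Parameters and default box

The eight inputs and their shipped ranges:

| name | meaning | units | range |
|------|---------|-------|-------|
| p    | end-diastolic (preload) pressure | kPa | 0.5–2.5 |
| ap   | aortic pressure | kPa | 8–16 |
| z    | aortic characteristic impedance | mmHg·s·ml⁻¹ | 0.5–5 |
| c1   | passive tissue stiffness | kPa | 1–5 |
| ca50 | calcium sensitivity | µM | 0.4–1.2 |
| kxb  | cross-bridge binding rate | ms⁻¹ | 0.02–0.10 |
| koff | Ca–TnC unbinding rate | ms⁻¹ | 0.03–0.25 |
| Tref | maximal cellular force | kPa | 60–200 |

The ranges are configuration, not measurements: they were chosen once from
rat physiology (end-diastolic pressures of a few mmHg to ~19 mmHg, systolic
pressures of 60–120 mmHg, relaxation and cross-bridge time constants of
4–50 ms) so that the box contains a broad mid region of healthy-looking
beats and corners that genuinely fail. Impedance is quoted in the
conventional mmHg·s·ml⁻¹ and converted internally
(1 mmHg = 0.133322 kPa; the s→ms and ml→µL rescalings cancel), with the
conversion centralised in `mmHgSecPerMl2kPaMsPerUl()`.

The protocol constants (`simProtocol()`) were calibrated once so that the
mid-range point ejects with an ejection fraction between 50 and 80 % and a
peak pressure above $ap$: $V_0 = 250$ µL, $\beta = 1.8$, $\alpha = 0.65$,
$R_p = 3$ kPa·ms·µL⁻¹, $C = 30$ µL·kPa⁻¹, calcium pulse
$0.05 + 1.25\,(t/18)e^{1-t/18}$ µM. The diastolic calcium level is kept low
enough that residual cross-bridge tension is small against the preload;
this keeps end-diastolic volume above $V_0$ and makes the stiffness
response physiological (stiffer wall, smaller EDV). Under these defaults
roughly 95 % of a full-box Latin hypercube simulates successfully, with
no-ejection failures concentrated at low `Tref`, high `ca50` and high `ap`.

### What the generator does and does not emulate

It reproduces the *structure* of the application — nonlinearity,
parameter interactions, failure region, outputs on very different scales —
but none of the spatial mechanics (fibre architecture, regional strain,
constitutive anisotropy). Passing tests therefore demonstrate that the
statistical machinery works on a map of this shape; they say nothing about
the fidelity of any particular 3D model.

## Feature extraction

Twelve features are read from the final-beat traces, in a fixed canonical
order (`featureNames()`): EDV, ESV, EF, IVCT, ET, IVRT, Tdiast, PeakP,
Tpeak, ESP, maxdP, mindP. Volumes are interpolated at the valve events (EDV
at mitral closure, ESV at aortic closure, which also defines end-systole
for ESP); phase durations are event-time differences; diastolic time is the
complement of the three systolic phases within the cycle, a declared
convention since "diastolic time" has no unique operational definition.
Pressure-derivative extrema use centred differences on the uniform grid
(one-sided at the ends), and the time origin for `Tpeak` is the final
beat's stimulus onset. Ties in the pressure maximum take the first
maximiser.

## Gaussian process emulation

Each feature gets its own emulator (twelve in total; the matched subset of
seven is used for HM). The model is universal kriging fitted in two steps:

1. a polynomial mean (degree 1–3, intercept, all monomials including cross
   terms) fitted by ordinary least squares (ridge fallback on rank
   deficiency);
2. a zero-mean anisotropic GP (squared exponential, Matérn 3/2 or Matérn
   5/2) fitted to the residuals by maximising the log marginal likelihood.

Inputs are mapped to the unit cube and outputs standardised before fitting,
so lengthscales are comparable across dimensions; predictions are
back-transformed. Prediction treats the mean coefficients as fixed
(their uncertainty is not propagated), the standard two-step convention;
the joint-fit alternative is out of scope.

Hyperparameters are optimised by L-BFGS-B on log parameters with analytic
gradients (implemented in compiled code for speed), with multi-restart
initialisation log-uniform in $\ell \in [0.05, 5]$,
$\sigma_f^2 \in [0.1, 10]\cdot\mathrm{var}(r)$ and
$\sigma_n^2 \in [10^{-6}, 0.1]\cdot\mathrm{var}(r)$. Non-positive-definite
covariances climb a jitter ladder ($10^{-10}$ to $10^{-6}$ of the mean
diagonal) before failing. A constant output degenerates to a mean-only
emulator with a warning.

Model selection uses seeded, shuffled 5-fold cross-validation over the
3 × 3 degree/kernel grid, maximising mean held-out $R^2$; ties prefer the
lower degree, then Matérn 5/2 over Matérn 3/2 over the squared
exponential. Inside history-matching waves the spec is fixed
(degree 2 + Matérn 5/2 by default) and refits are warm-started from the
previous wave's hyperparameters with a single restart — between waves the
optimum moves little and the warm fit converges in a few iterations.

## History matching

Targets are per-feature observed means $z_i$ and standard deviations
$\sigma_{\mathrm{obs},i}$ for a matched subset (default: EDV, ESV, ET,
IVRT, PeakP, maxdP, mindP; EF is never matched because it is derived from
EDV and ESV). The implausibility of a point is
$$I(x) = \max_i \frac{|z_i - m_i(x)|}
 {\sqrt{v_i(x) + \sigma_{\mathrm{obs},i}^2}},$$
the maximum over matched features of the standardised emulator–target
discrepancy; no model-discrepancy term is included. The max form is the
conservative standard choice for univariate emulators.

Waves proceed as usual: wave 1 trains on an initial Latin hypercube of
simulations and tests a large LHD cloud; each later wave draws points
uniformly without replacement from the surviving (NROY) cloud, simulates
them (failures are dropped from training but counted in the budget),
retrains, rebuilds a testing set from the remaining NROY points plus new
points generated inside the region by cloud augmentation (Gaussian jitter,
SD 5 % of each range, clipped to the box, filtered by the previous wave's
implausibility; uniform rejection sampling is the fallback), and rescores
at the next cutoff. The cutoff schedule starts at 5.0 (or 5.5) and drops
by 0.5 per wave to a floor of 3.0. The run stops when the non-implausible
fraction falls below a configured threshold, when NROY empties (an error
advising a larger starting cutoff), or at the wave cap.

Two fractions are logged per wave: the fraction of that wave's testing set
that survives, and the cumulative NROY volume fraction relative to the
initial box (the product of per-wave fractions). The per-wave fraction
necessarily jumps after wave 1 — later testing sets are drawn inside the
previous NROY, so most of their points are nearly plausible — while the
cumulative volume fraction is the quantity that tracks how much of the
original space remains and decreases whenever a wave genuinely rules
points out.

Desk-scale defaults (`hmConfig()`): 20,000 initial test points, 256 initial
training simulations, 128 simulations and 5,000 new test points per wave,
cutoff 5.0 → 3.0, at most 5 waves. A full-scale configuration
(400,000 initial tests, 256 simulations and 50,000 test points per wave,
start 5.5) is shipped for budget accounting (`hmBudget()`), which
reproduces protocol totals exactly without touching the simulator.

### What the final NROY does and does not guarantee

With targets built from a known ground-truth point plus observation noise,
desk-scale HM retains the truth in the final NROY in essentially all seeded
repetitions, and the emulators at the final wave are accurate (their
predictive SD is a few per cent of the observation SD, and their claimed
SDs match their actual errors). One property should *not* be expected,
and the package's own validation makes this visible: re-simulated points
from the final NROY do not concentrate within ±2 SD of the targets. At
cutoff 3.0 the NROY is, up to emulator error, the preimage of the
±3σ feature box, and a uniform sample of it puts each feature inside ±2σ
only about two-thirds of the time (we observe ~0.74 pooled across the
seven matched features, and ~0.1 for all seven simultaneously). Tightening
this would require a cutoff near 2, i.e. a different acceptance criterion,
not better emulators. The bundled validation reports these fractions
rather than asserting an unattainable concentration.

## Sobol sensitivity analysis

GSA runs on the emulator predictive mean (emulator uncertainty is
ignored — the simple point-wise approximation; an uncertainty-aware
estimator is out of scope). Designs are Saltelli blocks
$A, AB_1 \dots AB_D, BA_1 \dots BA_D, B$ built from a base-2 Sobol
low-discrepancy sequence (Joe–Kuo direction numbers, dimensions up to 21,
implemented in compiled code because no installed R package provides one);
a seeded digital shift randomises the sequence without destroying its
balance. Base sizes are restricted to powers of two and never silently
rounded. The estimators are the standard ones: Saltelli-2010 for
first-order, Jansen for total effects, and the closed pairwise formula for
second order. Estimates are reported raw — small negatives are sampling
noise — and clipped only in the stacked display aggregation
(`aggregateContributions()`), which attributes to each parameter its
first-order share plus half of each pairwise interaction. The
higher-order remainder is computed as
$\sum_i S_{T_i} - \sum_i S_{1_i} - 2\sum_{i<j} S_{2_{ij}}$: each pairwise
index enters two total effects, so this combination vanishes exactly for
functions with no interactions beyond pairs (it is zero for the Ishigami
function, which has only a single pairwise term).

Closed-form benchmarks (`ishigami()`, `sobolG()`, with analytic indices in
`ishigamiIndices()` and `sobolGIndices()`) anchor the estimators: at a base
size of $2^{15}$ the estimates agree with the analytic values to better
than 0.01; accuracy degrades as expected at smaller bases.
Defaults are $2^{14}$ for benchmarks and $2^{10}$ for quick runs.

## Numerical and design choices

* All design mathematics happens on the unit hypercube; physical units are
  applied by affine rescaling at the interface.
* One master seed per run; every stage derives its own sub-stream
  deterministically, so stages are independently reproducible and reruns
  are byte-identical.
* "Uniform sampling from the NROY region" means a uniform draw without
  replacement from the retained cloud — the region has no closed form.
* Duplicate detection after cloud jitter uses exact equality; jitter makes
  collisions measure-zero.
* Problem sizes in the shipped tests (desk-scale HM with twenty seeded
  recovery repetitions, 300-simulation cross-validation, $2^{15}$-point
  Sobol benchmarks) were chosen as the smallest sizes at which the checks
  are statistically meaningful while a full run remains an
  interactive-session affair.

## Limitations

* The 0D simulator is a stand-in: no spatial mechanics, no regional
  heterogeneity, no pericardium, a fixed Hill coefficient, and a failure
  rate that emerges from valve mechanics rather than FEM non-convergence.
* Emulators are univariate; output correlations are not modelled and the
  implausibility is the max over features, not a multivariate distance.
* HM yields bounds, not posteriors; an MCMC stage inside the final NROY is
  deliberately out of scope.
* GSA ignores emulator variance; with the emulator quality reached here the
  effect is small, but it is unquantified.
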