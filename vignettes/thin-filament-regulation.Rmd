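---
title: "Modelling cooperative thin-filament regulation and analysing contractility assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cooperative thin-filament regulation and analysing contractility assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarcoreg)
```

## The regulatory-unit model

A thin filament is treated as a linear chain of regulatory units, each an
actin~7~–tropomyosin–troponin span. Every unit occupies one of three
states reflecting the azimuthal tropomyosin position:

* **B** (blocked): myosin binding forbidden;
* **C** (closed): weak myosin binding permitted;
* **M** (open/bound): a cycling crossbridge holds tropomyosin open.

Transitions form the linear scheme B &harr; C &harr; M with per-unit
rates

| rate | transition | meaning | default |
|------|------------|---------|---------|
| `a`  | B &rarr; C | tropomyosin shift off the blocked position | Ca- and MyBP-C-dependent, see below |
| `b`  | C &rarr; B | reverse shift (`k_off`) | 100 s^-1^ |
| `f`  | C &rarr; M | apparent crossbridge attachment (`f_app`) | 10 s^-1^ |
| `g`  | M &rarr; C | apparent crossbridge detachment (`g_app`) | 10 s^-1^ |

The forward shift combines two activation pathways,

$$a = k_{on,max}\,\frac{[Ca^{2+}]^{n}}{[Ca^{2+}]^{n} + Ca_{50}^{n}}
      \;+\; \theta\, k_{act},$$

where the first term is the calcium pathway — troponin occupancy treated
as an *instantaneous* Hill equilibrium (`ca50_tn`, default 5 µM;
`n_tn = 1`), justified because calcium exchange on troponin is fast
relative to the tropomyosin shift — and the second is the MyBP-C pathway:
an N-terminal fragment bound with occupancy
$\theta = [frag]/([frag]+K_d)$ shifts tropomyosin even with empty
troponin, so activation survives at pCa 9. This is deliberately additive
and calcium-independent.

Cooperativity enters only through nearest neighbours: a unit whose
neighbour is active (C or M) has its forward rate multiplied and its
reverse rate divided by `gamma` per active neighbour (default
`gamma = 2`, free chain ends, `n_units = 26`, one strand of a thin
filament). The chain is simulated by fixed-timestep kinetic Monte Carlo
(default `dt = 1e-4` s): each step, every unit leaves its state with
probability rate × dt, with neighbour factors evaluated synchronously on
the previous step's configuration. A stability guard refuses any run in
which the worst-case exit probability exceeds 0.1 per step and reports
the required `dt`. Each run consumes exactly one seeded random stream;
identical parameters and seed give bit-identical trajectories, and every
returned trace carries seed and `dt` in its metadata.

The force proxy is the fraction of units in M. None of the protocols in
this package are loaded, so no force-dependent rate or strain-dependent
detachment is modelled; lattice mechanics and length-dependent
activation are likewise out of scope.

### Analytic oracle

At `gamma = 1` units are independent, and the stationary distribution of
one unit follows from flux balance on the linear chain:
$\pi_C = \pi_B\,a/b$, $\pi_M = \pi_B\,af/(bg)$, normalised.
`steady_state_single_unit()` implements this closed form (including the
absorbing limits `b = 0`, `g = 0`) and the test suite requires the
simulator's time averages to match it within Monte-Carlo error. In the
two-state limit (B negligible, reached at saturating calcium with
`a >> b`), tension redevelopment after detaching all crossbridges relaxes
at `f_app + g_app`; the exact slow eigenvalue of the three-state system
at the parameters used in the tests (a = 1000, b = 1, f = 5, g = 2 s^-1^)
is 6.995 s^-1^, within 0.1% of that limit.

### MyBP-C isoform parameter sets

`isoform_defaults()` returns declared fixtures chosen once so that the
qualitative isoform behaviour holds and then frozen:

| isoform | `k_act` (s^-1^) | `drag` | `kd_frag` (M) |
|---------------|------|-------|-------|
| cardiac       | 15   | 0.516 | 5e-8  |
| slow-skeletal | 10   | 0.10  | 5e-8  |
| fast-skeletal | 2    | 0.50  | 1e-7  |
| none          | 0    | 0     | —     |

Activation capacity orders cardiac > slow > fast; velocity inhibition
orders cardiac ≈ fast ≫ slow. The cardiac `drag`/`kd_frag` pair encodes a
43% velocity inhibition at a 0.25 µM dose
(`theta = 0.25/(0.25+0.05) = 0.833`; `0.516 × 0.833 = 0.43`), the
reference high-calcium cardiac-fragment effect. The drag multiplies
sliding velocity only (motility and twitch contexts), never the isometric
force proxy, because maximal calcium-activated force is insensitive to
the fragments.

### Cooperative lock-in and the twitch protocol

With coupling `gamma` and reverse rate `k_off`, an interior unit flanked
by two active neighbours has its effective C&rarr;B equilibrium scaled by
`gamma^4`. The active phase of the chain therefore becomes
self-sustaining once the calcium-independent drive exceeds roughly
`k_off / gamma^4` (≈ 6 s^-1^ at the defaults). This is a real property of
cooperative chains — strong constitutive activators hold the filament on
at diastolic calcium — and it dictates the twitch protocol: simulated
unloaded twitches use a sub-critical fragment dose (0.02 µM,
`theta ≈ 0.29`) so that every isoform relaxes within a beat, and a 0.5–1 s
diastolic lead-in so the baseline sarcomere length and occupancy are
pre-equilibrated before the stimulus. At the 0.25 µM motility dose the
cardiac fragment does cross the threshold; that manifests as strong
constitutive activation in the low-calcium motility and steady-state
protocols, which is the intended behaviour there.

### Protocols

* **Force–pCa** (`force_pca_curve`): one run per pCa, first half
  discarded as burn-in, M-fraction averaged over the second half.
  `dt = "auto"` picks the largest stable step per pCa; `n_reps` averages
  replicate runs (used for steep, high-`gamma` curves where a single run
  near the transition is bimodal).
* **k_tr** (`simulate_ktr`): run to steady state, instantaneously move
  every M unit to C at the release (tropomyosin states untouched),
  follow redevelopment; the returned trace puts the release at `t = 0`.
* **Twitch** (`simulate_twitch`, `average_twitches`): a
  difference-of-exponentials calcium transient (`ca_transient`; default
  diastolic pCa 7, peak pCa 5.8, rise 30 ms, decay 150 ms, amplitude
  normalised so the maximum hits the peak calcium exactly) drives the
  chain; unloaded sarcomere length integrates
  $dSL/dt = -v_{max}(1 - drag\,\theta)\,\pi_M + k_{restore}(SL_{rest} - SL)$
  by forward Euler on the simulation grid (`sl_rest = 1.8` µm,
  `v_max = 4` µm/s, `k_restore = 12` s^-1^ — an unloaded shortening of a
  few percent of resting length with relaxation in the 0.2–0.5 s range).
  Because a single 26-unit chain is a noisy force sensor, relaxation
  metrics are extracted from 10-beat averages (`average_twitches`),
  mirroring the experimental practice of averaging ten paced
  contractions.

## Analysis conventions

* **Hill fits** (`fit_hill`, `dose_response`): 4-parameter logistic in
  pCa with base-10 exponent, floor and ceiling free (reduces to the
  2-parameter form at floor 0, ceiling 1). Five deterministic
  Levenberg–Marquardt starts over an `n_H` grid {0.5, 1, 2, 4, 8} with
  the half-maximum crossing as the pCa50 start; best fit by lowest RSS,
  ties by lowest `n_H`. Box bounds keep the floor within the data span,
  `n_H ≤ 50` and pCa50 within the grid ± 2, so grids without a low-calcium
  plateau cannot send the optimiser to an unidentifiable corner.
  Constant responses and collapsed spans (`ceiling ≈ floor`) are errors,
  not numbers.
* **k_tr** (`fit_ktr`): single exponential
  `offset + amplitude (1 - exp(-rate t))` starting two samples after the
  release to skip the restretch artifact; five rate starts bracket the
  63%-recovery estimate.
* **ATPase** (`atpase_rate`): injection steps measured as the difference
  of 1-s medians around each injection (robust, no free parameters);
  calibration factor is the mean step per mole (steps must be negative —
  NADH is consumed); the rate is the negated baseline slope over the
  calibration factor. A 50 nl injection of 10 mM ADP is 5 × 10^-10^ mol.
* **Relaxation tau** (`fit_relaxation_tau`): the "logarithmic fit" is a
  linear regression of `log(sl_rest - SL)` against time from peak
  shortening, `tau = -1/slope`. The fitted segment stops at the first
  sample whose deflection reaches the noise floor (default: 5% of the
  peak deflection or 3 × the pre-stimulus noise SD, whichever is larger)
  so the flat noise tail cannot bias the slope; a direct nonlinear
  exponential fit is available as a cross-check and agrees within 5% on
  clean data. Fits whose usable segment spans less than one tau are
  flagged `low_confidence` rather than rejected.
* **Time to % baseline** (`twitch_metrics`): percentages measure
  *recovery of the deflection* — "90% baseline" means the sarcomere has
  recovered 90% of its peak deflection toward resting length — linearly
  interpolated between samples and measured from the peak. Levels never
  reached within the beat are `NA`, never extrapolated. The baseline is
  the median of the 100 ms before the stimulus (robust to drift without
  a detrending model).
* **Motility** (`classify_mobile`, `motility_statistic`): a filament is
  mobile when its mean frame-to-frame velocity is at least 0.3 µm/s
  *and* its net-to-path displacement ratio is at least 0.5. The second
  condition is what actually separates localisation jitter from
  processive sliding: stationary tracks with 95 nm/frame localisation
  noise have apparent velocities near 0.34 µm/s at 2 frame/s but
  straightness far below 0.5. Velocity is averaged over mobile filaments
  only, so the velocity × fraction product does not penalise immobility
  twice. SEM is computed across per-movie products when movie labels are
  present (triplicate experiments), otherwise from the per-filament
  spread.

## The EGTA calculator

`free_calcium()` solves the 1:1 Ca:EGTA equilibrium
`free + E_t free/(free + K_d) = Ca_t` by bracketed bisection on
`[0, Ca_t]`, refined to 10^-12^ M absolute and 10^-12^ relative so that
nanomolar and micromolar roots are equally exact; the closed-form
quadratic root serves as the independent test oracle, and bisection keeps
the solver extensible to multi-ligand variants. The apparent dissociation
constant defaults to 5 × 10^-8^ M at the working pH/ionic strength, chosen
so the standard equimolar 20/20 mM activating solution labels as
pCa 4.50. Zero free calcium maps to a pCa cap of 12.0 so relaxed
solutions stay finite in plots and fits. Mg^2+^/ATP competition,
temperature/pH corrections and multi-species speciation are deliberately
out of scope: the calculator provides reproducible pCa labels, not a
speciation model.

## Synthetic data: what it emulates, what it does not

Every generator takes a mandatory seed, embeds its generating parameters
as a `ground_truth` attribute, and regenerates bit-identically from
(parameters, seed).

* `gen_force_pca`: logistic curve + i.i.d. Gaussian noise, clipped at 0,
  on the standard titration grid (pCa 4.50–6.00 plus relaxed 10.00).
* `gen_tracks`: mobile probability is a calcium logistic
  (half-activation pCa 6.25, steepness 2, ceiling 0.9, spontaneous floor
  0.02) raised by fragment occupancy in proportion to the isoform's
  activation capacity; mobile filaments move ballistically at
  `v0 (1 - drag θ)` (v0 = 5 µm/s, 10% per-filament speed CV) in a random
  fixed direction; all positions get 95 nm/frame Gaussian localisation
  jitter; 41 frames at 10 Hz, analysed at 2 Hz, three movies per
  condition.
* `gen_ktr_trace`, `gen_nadh_trace`, `gen_twitch`: model curves plus
  declared Gaussian noise; the twitch rises along a half-cosine and
  recovers as a single exponential so the analysers' round trips have
  closed forms.

Noise is Gaussian everywhere and tracks are ballistic; real assays have
heavy-tailed localisation errors, filament crossing/linking failures,
photobleaching, drift, and mechanochemical coupling that none of these
generators attempt. Passing recovery tests therefore demonstrates that
the analysers are unbiased under the declared noise model at the declared
sizes — not that they are robust to every artifact of real recordings.

## Problem sizes and runtime choices

The test and acceptance workloads are sized for quick, deterministic
verification: oracle-equivalence uses 8 replicate 20 s runs of the
26-unit chain at five pCa levels; the k_tr limit uses 2000 independent
units with three averaged runs; Hill-recovery uses 200 replicates at
noise SD 0.02; motility recovery uses 300 filaments per condition and
three replicate generations; twitch orderings use 10-beat averages over
five seeds. These sizes put Monte-Carlo error comfortably below the
tolerances being checked while keeping the whole suite at around a
minute of compute.

## Known limitations

* The chain omits strain-dependent crossbridge kinetics and
  length-dependent activation; only unloaded, force-free protocols are
  meaningful.
* Fragment binding is assumed persistent during activation; no
  association/dissociation kinetics are modelled.
* Near the cooperative transition at high `gamma`, single runs are
  bimodal and time averages converge slowly; use `n_reps` and expect
  fitted `n_H` to be grid-limited.
* The 4-parameter Hill fit cannot separate floor from span when the
  sampled grid misses a plateau; the fitter bounds the parameters and
  errors on degenerate data rather than extrapolating.
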