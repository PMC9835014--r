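---
title: "Methods: a constrained-mixture model of bladder micturition, growth and remodeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a constrained-mixture model of bladder micturition, growth and remodeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(bladdergr)
cfg <- bladder_config()
```

This vignette documents the model, the parameterization, the numerical
scheme and the design decisions behind `bladdergr`. Units are fixed
package-wide: Pa, mm, ml, seconds for micturition, days for growth and
remodeling (G&R).

## The wall as a constrained mixture

The bladder is idealized as a thin spherical membrane of unloaded radius
$R_0$ and thickness $H_0$, with three layers (lamina propria LP, detrusor DL,
adventitia AD) whose thickness fractions $r_L$ sum to one. All constituents
deform with the tissue but each has its own natural configuration — the
essence of a constrained mixture:

* the **ground matrix** is an incompressible neo-Hookean membrane. We use
  the plane-stress equibiaxial form $\sigma_{nc} = 2k_{nc}(\lambda^2 -
  \lambda^{-4})$, in which the through-thickness pressure has been
  eliminated, so that the stress (and hence the transmural pressure)
  vanishes in the unloaded state. For $\lambda < 1$ a membrane wrinkles
  rather than supporting in-plane compression, so the stress is cut off at
  zero: the voided bladder (radius 1.7 mm, below the unloaded 3 mm) is
  floppy, not compressed.
* **collagen fibers** are wavy and join load bearing progressively. The
  recruitment stretch of a fiber population follows a triangular density on
  $[\lambda_R^{min}, \lambda_R^{mode}, \lambda_R^{max}]$; a recruited fiber
  carries a linear force-stretch response, and the ensemble Cauchy stress is
  the convolution of the two. Because the density is piecewise linear the
  convolution has a closed form (logarithmic-polynomial per branch), which
  the test suite checks against adaptive quadrature at rel. tol 1e-8. A
  zero-width distribution degenerates to a Dirac mass (all fibers recruit
  together); this branch exists mainly to give fitting routines robust
  starting points.
* **smooth muscle (SMC)** produces active stress $S(t)\,m_m\,k_{act}\,
  (\lambda_m^4+\lambda_m^2)(\lambda_m-\lambda_m^{min})(\lambda_m^{max}-
  \lambda_m)$ inside its working range, where $\lambda_m = \lambda /
  \lambda_{Rm}$ is the SMC stretch and $m_m$ the normalized mass density.
  Pushed through membrane equilibrium this yields the active pressure in
  closed form; the algebraic identity between the two routes is asserted at
  1e-12 in the tests. The printed active modulus absorbs the detrusor
  thickness fraction, so the active pressure law carries no $r_{DL}$ factor.

Membrane equilibrium closes the statics:
$p = \frac{2H_0}{R_0\lambda^3}\big(\sigma_{nc} + \sum_L r_L \sigma_{c,L} +
\sigma_{act}\big)$.

## Micturition

Voiding is triggered when the SMC stretch reaches its homeostatic value
$\lambda_{m,h}$. The nervous stimulus then ramps up as
$S(t) = 1 - 1/(1+(t/k_{m1})^4)$; flow through the urethra is linear above a
cutoff, $Q = (p - P_c)/\alpha$; the volume balance $dV/dt = Q_{in} - Q$ is
integrated with classical RK4 at a fixed step (default 10 ms, matching the
100 Hz sampling of cystometry rigs). The voided volume is carried as a
second state variable so that volume conservation holds to machine
precision. When the flow falls below $Q^S_{crit}$ the ramp-down is latched
(mirrored quartic with constant $k_{m2}$), and the stimulus ends outright at
$t_{end}$. If the wall cannot reach the cutoff at full stimulus the
simulation returns a *failed void*, the marker the G&R loop uses to enter
the leaky mode.

### Stimulus constants are calibration targets

$k_{m1}$, $k_{m2}$, $Q^S_{crit}$ and $t_{end}$ are not identifiable from
tissue data, so they are calibrated against the healthy-bladder
urodynamics, exactly as the cutoff pressure and resistance were calibrated
in the source experiments:

* `k_m1 = 3.856 s` — tuned (by `calibrate_stimulus()`, a bisection on one
  simulated cycle) so the healthy bladder voids in 12 s;
* `q_crit = 0.001 ml/s`, `k_m2 = 1 s` — a low threshold with a quick
  ramp-down lets the healthy void drain to its quasi-static endpoint,
  reproducing the 0.02 ml residual;
* `t_end = 50 s` — the obstructed steady-state void otherwise crawls along a
  few-hundred-Pa margin for ~90 s; the observed voiding times imply the
  stimulus, not the pressure balance, terminates the void. The healthy cycle
  (14 s including ramps) never feels this cap.

With these defaults one cycle gives voided volume 0.805 ml, duration
12.0 s, residual 0.021 ml and peak pressure 3.97 kPa — the quantities the
acceptance tests check.

## Growth and remodeling

Between voids the wall adapts by explicit Euler steps of three rate laws,
at a slow step `dtau = 0.005 day`:

* **collagen recruitment** remodels so the fiber stretch distribution at the
  onset of voiding relaxes toward a homeostatic (deposition) distribution.
  The pairing is crossed — the earliest-recruited fibers are the most
  stretched, so $\lambda_R^{min}$ responds to the excess of the *maximum*
  fiber stretch, and vice versa. If an Euler overshoot ever breaks the
  ordering the three values are re-sorted with a warning (never observed at
  the default step).
* **SMC recruitment** relaxes the SMC stretch at the onset of voiding toward
  $\lambda_{m,h}$.
* **SMC mass** follows $\dot m = \beta\, m\,(X_0 - X)/X_0$ with the
  functional readout $X$ selected by the growth hypothesis: voided volume
  (GF1), mean voiding flow (GF2), or SMC contractile range (GF3). In the
  leaky mode there is no functional void and $X = 0$.

### Rate constants and time units

The rate constants (3.6, 40, 5) are dimensionless in the source table. We
interpret the collagen remodeling rate and the SMC growth rate **per week**:
per-day values make the mass grow as $e^{5\tau}$ during the leaky phase
(five orders of magnitude in under three days) and destroy every observed
4-week outcome, while per-week values reproduce the ~2-week muscle
stabilization and the ~4-week collagen/voiding-time stabilization. The SMC
recruitment rate is interpreted **per day** (a relaxation time of hours):
the homeostatic-stretch trigger is only self-consistent if the muscle
working point re-centers quickly relative to the day-scale filling cycle,
and the observed equality of the recovery radius and the subsequent voiding
radius requires the recruitment stretch to track the leaky state with
negligible lag.

### The slow loop

Filling proceeds at `q_in = 0.84 ml/day` (chosen over the rounded 0.8 so the
healthy bladder voids exactly once per day; both exposed in config). Each
slow step:

1. the volume is advanced; if the passive pressure exceeds the cutoff the
   bladder leaks, and when the net flow changes sign the state is clamped to
   the quasi-static leaky balance $p_{passive}(\lambda) = \alpha Q_{in} +
   P_c$ (the relaxation to that balance takes minutes, far below `dtau`);
2. in functional mode, a void fires when $\lambda_m$ crosses
   $\lambda_{m,h}$. The void starts at the *exact* trigger volume and the
   slow-step overshoot is carried into the next fill; this makes the healthy
   configuration a machine-precision fixed point of the whole loop (asserted
   in the tests). A failed void switches the loop to leaky mode, as does
   passive leakage before the trigger (overflow incontinence);
3. in leaky mode, once the steady leak state is established, a trial
   contraction is evaluated; the leaky phase ends when the predicted void
   reaches an SMC stretch at least 0.02 below $\lambda_{m,h}$ (a named
   config constant). The margin is assessed from the voiding-trigger
   stretch so that a recovered bladder can sustain its subsequent cycles;
   the ending event itself is a full dynamic void simulated from the leak
   state. During the overfilling transient no trial is attempted: the
   trigger was crossed once, upward, and there is no re-crossing while the
   bladder is stuck above it.

After recovery the remodeling laws are driven by the trigger-state
configuration (the onset state of every subsequent cycle). Holding the
transient leak-onset state instead makes the trigger volume recede faster
than the bladder can fill — a deadlock, not a model prediction.

### A continuous growth readout

Driving the growth law with the metrics of the most recent completed void
(a sample-and-hold with a ~1 day delay) is structurally unstable at the
obstructed steady state: the void endpoint sits on the flat part of the
active length-tension curve, so the per-cycle loop gain is far above one
and the mass oscillates instead of converging. The growth drive is
therefore evaluated continuously: at every slow step a quasi-static
prediction of the void the current wall would produce (full stimulus, flow
cut at $Q^S_{crit}$, clock capped at the stimulus window) supplies the
readout $X(\tau)$, bias-corrected by the ratio of the last dynamic cycle to
its own prediction. This has the same fixed point ($X = X_0$, with the
dynamic metrics pinned to their baselines), is stable at the default step
($\beta\,\cdot$ gain $\cdot\, d\tau \ll 1$), and leaves all *recorded*
urodynamics to the dynamic simulations. Halving `dtau` moves the 4-week
endpoints by well under 1% (tested).

## Parameters

The default configuration (`bladder_config()`) is the calibrated healthy
male rat set: $R_0 = 3$ mm, $H_0 = 0.78$ mm, $k_{nc} = 1170$ Pa, layer
collagen stiffnesses $11.7/0.79/11.7$ MPa (LP/DL/AD), layer ratios
$0.30/0.60/0.10$ (the ratios are not measured; LP and AD collagen are slack
at homeostasis so they only matter far above the voiding stretch),
deposition distributions $(0.77,0.82,0.87)$, $(0.84,0.90,0.97)$,
$(0.60,0.70,0.80)$, active modulus 5770 Pa on the window $[0.25, 2.5]$ with
homeostatic stretch 1.5, sham outlet $(\alpha, P_c) = (19800, 1450)$,
obstructed outlet $(22075, 8487)$, volume fractions
elastin/collagen/SMC $= 0.01/0.29/0.70$ with elastin and collagen mass held
at baseline. Bladder mass is reported as $0.11\,\mathrm{g}\times\hat v$
with $\hat v = 0.3 + 0.7\,m_m$.

The initial void stretch is taken as the printed $\lambda_F(0) = 1.94$
rather than the radius ratio $5.9/3.0 = 1.967$; the printed value is the one
consistent with the rest of the printed set (with 1.94 the quasi-static
end-of-void state reproduces the 0.02 ml residual; with 1.967 it does not).
The SMC recruitment stretch starts at $\lambda_F(0)/\lambda_{m,h} = 1.2933$
so the muscle sits at its homeostatic stretch at the onset of voiding, and
the collagen recruitment distributions are placed so the fiber stretches at
the onset of voiding equal the deposition targets.

## Calibration pipeline

`fit_recruitment()` fits the triangular CDF (the measured quantity is the
cumulative recruited fraction) by bounded Levenberg-Marquardt under the
ordering reparameterization $(\lambda^{min}, \delta_1, \delta_2 \ge 0)$.
`fit_passive_model()` exploits that the total stress is linear in the
stiffnesses once the recruitment distributions are fixed, so it is a linear
regression on two/three basis functions; the default weighting is relative
(inverse squared stress, floored at 1% of the maximum) because the
measurement error is multiplicative and the stresses span three decades —
uniform weighting leaves the kPa-scale toe, and hence $k_{nc}$, swamped by
the MPa-scale collagen points (a uniform option is exposed).
`estimate_void_stretch()` applies the law of Laplace to the filled explant
(equivalent-sphere unloaded radius, incompressible thinning
$h_F = h_0/\lambda_F^2$) and inverts the measured stress-stretch curve by
monotone (Hyman-filtered) spline interpolation; extrapolation outside the
measured stress range is refused. `infer_deposition()` is the reciprocal
map $\lambda_{c,h} = \bar\lambda_F / \bar\lambda_R$ (order reverses);
`map_stretch()` re-anchors stretches between the biaxial and model frames by
the ratio of the two void stretches.

## The synthetic-data generator

`make_synthetic_biaxial()` emulates what a biaxial rig with multiphoton
recruitment imaging produces: an equibiaxial stress-stretch curve from the
package's own constitutive law with multiplicative Gaussian noise (default
2%, typical of load-cell and geometry errors), and per-layer recruited
fractions with binomial sampling noise (default 50 traced fibers per
observation). It emulates neither preconditioning hysteresis, nor
anisotropy, nor inter-sample biological variability, nor image-processing
errors in fiber tracing — so passing recovery tests demonstrates that the
estimators are consistent and well-conditioned under the stated noise model,
not that they are robust to everything real tissue does. All randomness is
seeded and the generator restores the caller's RNG state.

A small worked fixture (`inst/extdata/biaxial_sham_synthetic.csv`,
synthetic and labeled as such) anchors the void-stretch worked example: a
stress-stretch curve constructed from the constitutive model with early
recruitment and scaled so the mean sham explant's Laplace wall stress is
reached at biaxial stretch 1.05.

## Numerical choices, degenerate inputs, tie-breaks

* Micturition: RK4, `dt = 0.01 s`; passive pressure interpolated once per
  void on a stretch grid (monotone Fritsch-Carlson cubic); state floored at
  a nanoliter to survive pathological parameter probes.
* Slow loop: explicit Euler, `dtau = 0.005 day`; all rates times `dtau`
  stay well below stability limits.
* Trigger events are located exactly (the trigger volume is algebraic), so
  the healthy fixed point is exact, not $O(d\tau)$.
* Leaky-state root finding is bracketed (`uniroot`, tol 1e-12) with an
  explicit error when the wall cannot sustain the leak pressure, and the
  G&R loop aborts with a diagnostic if the stretch passes a configurable
  cap (default 6).
* A failed dynamic trial in leaky mode raises the hysteresis bar slightly
  (0.005 in SMC stretch) before another trial is run, so the loop does not
  re-simulate a hopeless contraction every 7 minutes of model time.
* Degenerate (zero-width) recruitment distributions take the Dirac branch
  everywhere; fitting starts are therefore always valid.

## Problem sizes

The shipped analyses use one sham cycle (~1500 RK4 steps), 28-day G&R runs
(5600 slow steps, ~30 dynamic voids) and recovery studies of 30-200
replicates; a full 28-day run takes ~20 s and the whole test suite a little
over a minute on one core.

## Known limitations

* The spherical, isotropic reduction: no fiber directions, no anatomical
  geometry, no bending or shear, no external abdominal loads.
* The two printed stretch anchors ($\lambda_F(0)$ 1.94 vs the 1.967 radius
  ratio) are mutually inconsistent at the percent level; we carry 1.94.
* With the printed parameters the passive pressure at the filled state is
  ~0.6 kPa, about twice the measured mean maximum filling pressure; the
  model inherits this from its source calibration.
* Only the hypertrophy and early compensation stages are modeled: no
  ischaemia, no decompensation, no collagen mass growth or elastogenesis,
  no electro-chemical SMC activation.
* The growth hypotheses are phenomenological set-point laws; the
  contractile-range hypothesis in particular converges slowly and its
  28-day state is not a strict steady state.
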