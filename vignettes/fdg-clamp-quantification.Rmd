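---
title: "Quantifying tissue glucose uptake from FDG-PET clamp studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tissue glucose uptake from FDG-PET clamp studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdgclamp)
```

## The measurement problem

During a hyperinsulinemic–euglycemic clamp, insulin is infused at a
fixed rate while glucose is infused at a variable rate that holds
glycemia constant; at steady state the glucose infusion rate (GIR)
indexes whole-body insulin sensitivity (the *M value*).  Injecting
[¹⁸F]FDG during the clamp adds tissue-level resolution: dynamic PET of
the thorax, abdomen and thighs and static scans of the neck and brain
yield regional time–activity curves (TACs), from which glucose uptake
rates of muscle, liver, adipose depots, myocardium, brown adipose
tissue and brain are quantified.  This package implements that full
quantification chain plus the cohort statistics used to compare a
low-risk and a high-risk group, and a synthetic-data generator that
stands in for subject-level data that cannot be redistributed.

## Models and estimators

### Irreversible two-tissue compartment model

FDG is transported into tissue (K₁, mL/mL/min), can efflux back (k₂,
1/min) and is phosphorylated and trapped (k₃, 1/min):

$$\frac{dC_1}{dt} = K_1 C_p - (k_2+k_3)\,C_1,\qquad
  \frac{dC_2}{dt} = k_3\,C_1,$$

with measurable activity
$C_T = (1-V_b)(C_1+C_2) + V_b\,C_p$ for blood volume fraction $V_b$.
`simulate_tissue_curve()` integrates this system with `deSolve::lsoda`
(rtol 1e-8, atol 1e-10 — far below measurement noise).  The trapping
influx constant is $K_i = K_1 k_3/(k_2+k_3)$.

### Patlak–Gjedde analysis and its fit start

`patlak_fit()` regresses $C_T(t)/C_p(t)$ on
$\int_0^t C_p / C_p(t)$ over frames with mid-time $\ge t^*$ (ordinary
least squares by default; frame-duration weights optionally).  The
regression becomes linear only once the exchangeable compartment has
equilibrated: the transient decays as $e^{-(k_2+k_3)t}$ *relative to the
plasma level*, and after a bolus the stored early activity makes this
transient substantially larger than the constant-infusion intuition
suggests.  Numerically, for $k_2+k_3 = 0.2$/min a fit over 10–40 min
still carries a double-digit percentage slope bias, while a fit start
of ~45 min on a 90-min acquisition is accurate to well below 1%.  The
package default `t_star = 10` min is appropriate for the tissues and
windows it is used on in the pipeline — myocardium
($k_2+k_3 \approx 0.9$/min, frames 10–40 min) and liver/muscle (frames
at 40–70 min post-injection) — but users fitting slowly equilibrating
tissues over early windows should verify convergence; the package's own
recovery checks use a late fit window for exactly this reason.

A second structural point: the Patlak slope of the *measured* curve is
$(1-V_b)\,K_i$, because only the tissue fraction of the voxel traps
tracer.  For muscle, adipose tissue and brain ($V_b \le 0.05$) this is
negligible; for myocardium and liver ROIs it is not, which is why the
synthetic generator back-solves K₁ with a $1/(1-V_b)$ factor so that
its glucose-uptake targets are honored in the measurable slope.

### Fractional uptake rate

For single-frame regions `fur()` computes
$FUR = C_T(T)/\int_0^T C_p$, which exceeds $K_i$ by
$V\,C_p(T)/\mathrm{AUC}(0,T)$.  With the default input curve this
relative excess falls monotonically with $T$ — about 19% at 30 min,
6% at 90 min for $K_i = 0.025$/min — and the same systematic applies
to the adipose FUR values produced by the pipeline at their mid-scan
frame times (~30% at 52.5 min for the slow adipose kinetics).  This is
a property of the estimator, shared with any analysis that uses FUR at
those times, not an implementation artifact; between-group contrasts
are preserved because both groups are biased alike.

### Hybrid input function

`build_hybrid_input()` uses the image-derived left-ventricle curve for
knots before the switch time (default 4.5 min) and arterialized plasma
samples from the switch onward; at the switch itself the plasma value
wins, since blood sampling is the reference measurement.  Whether the
image-derived segment should be rescaled to the plasma scale is exposed
as `calibrate` (default off — no cross-calibration is assumed; when on,
the factor matches the full image-derived curve to the first plasma
sample).  Evaluation is linear between knots with an implicit origin at
(0, 0); `auc()` integrates the polyline exactly, so
$\mathrm{AUC}(0,a)+\mathrm{AUC}(a,b)=\mathrm{AUC}(0,b)$ to rounding.
Beyond the last knot a mono-exponential tail fitted to the last three
plasma knots provides extrapolation, including $\mathrm{AUC}(0,\infty)$
for tracer clearance.

### Glucose uptake and clamp indices

`gu_from_rate()` applies
$GU = \text{rate} \times [\text{glucose}]/(LC \times \rho)$ with the
registry defaults: lumped constants 1.2 (muscle), 1.0 (liver), 1.14
(adipose) from the protocol this package models; 0.65 (brain) and 1.0
(myocardium) are *conventions only* — the modeled protocol does not fix
them — and densities (1.06, 1.05, 0.925, 1.04, 1.05 kg/L) are
literature-standard values.  All are configurable.

`m_value()` averages GIR over the steady-state window and subtracts a
glucose-space correction $(G_{end}-G_{start})\cdot v_d/\Delta t$ (with
$v_d = 0.19$ L/kg by default) and an optional urinary-glucose
correction (default 0).  The exact space- and urine-handling rules of
clamp protocols vary and the modeled study's supplementary details are
not available, so these two constants are explicit reconstructions.
`rd_from_tracer()` converts tracer plasma clearance
$(dose - urine)/\mathrm{AUC}(0,\infty)$ to a glucose disappearance rate
with a whole-body lumped constant of 1.0 (keeping R_d in glucose
equivalents), and `egp()` is the exact identity $EGP = R_d - GIR$,
negative under effective insulin suppression.  `matsuda_isi()` uses the
conventional unit conversions (×18.016 for glucose, ÷6.0 for insulin);
the pipeline feeds it the fasting sample and the mean of fasting and
2-h OGTT values.  `ifcc_to_ngsp()` is the HbA1c master equation
$\%= 0.09148\cdot\text{mmol/mol} + 2.152$.

### Cohort statistics

`compare_groups()` defaults to the pooled-variance Student t-test
(Welch optional), with `wilcox.test`'s exact rank-sum for small
tie-free samples and χ² for categorical variables.  `age_adjust()`
removes the least-squares age slope around the sample mean age
(mean-preserving and idempotent); in correlation analyses only the
uptake variable is adjusted.  `bh_fdr()` is Benjamini–Hochberg.
`voxelwise_group_map()` is a deliberate simplification of statistical
parametric mapping: per-voxel pooled t-tests, BH-FDR across voxels
(zero-variance voxels are excluded from the family), and 26-connectivity
components of the significance mask.  Random-field cluster-level
inference is out of scope, and results are not comparable to SPM
cluster statistics.

## The synthetic-data generator

`simulate_cohort()` emulates the study conditions end to end:

* **Cohort structure.**  Two groups (low-risk n = 22, high-risk
  n = 19) with independent truncated-normal variables.  Anthropometric,
  fasting, OGTT, steady-state, M value, EGP and clamp-FFA parameters
  use the published group means and SDs; per-tissue glucose-uptake
  targets are published depot uptake divided by depot mass where both
  exist, and plausible insulin-stimulated values for liver
  (20/15 µmol/kg/min, LR/HR), myocardium (450/430) and BAT (14/9),
  which the source tables do not provide.  Truncation bounds prevent
  physically impossible draws (negative masses, zero doses).
* **Input curve.**  A tri-exponential bolus model with ramp and delay
  (defaults: λ of −4, −0.25, −0.012 /min, delay 0.5 min).  Each
  subject's curve is scaled so that
  $\mathrm{AUC}(0,\infty) = dose(1-f_{urine})/CL$, with the clearance
  implied by the subject's target $R_d = EGP + M$ — so the pipeline's
  tracer-based R_d and EGP recover their targets by construction.
* **TACs.**  Per-tissue K₁ back-solved from the uptake target (with
  fixed synthetic k₂/k₃/V_b per tissue — these are *not* measured
  values), simulated on the protocol's frame schedules: thorax 4×15,
  6×20, 2×60, 2×150, 6×300 s (0–40 min), abdomen and thigh 3×300 s
  blocks, neck and brain 1×600 s statics.
* **Noise.**  Gaussian on frame means with
  $sd = scale\sqrt{value/duration}$ (default scale 0.05, ≈1.5%
  on late 5-min frames — typical ROI-level precision); plasma samples
  1% CV; clamp series get small Gaussian jitter.  Setting all scales to
  0 gives exact parameter recovery (used by the tests).
* **Clamp records.**  GIR ramps linearly to the target M over 80 min
  and stays constant, glucose is flat at the steady-state target, so
  the M estimator recovers the target exactly in the noise-free case;
  the steady-state window is 110–170 min.

What the generator does *not* emulate: scanner physics (attenuation,
scatter, dead time, isotope decay — all activities are decay-corrected
by construction), anatomy and partial-volume effects, within-subject
correlation between variables (each is drawn independently), and
non-normal tails.  Passing tests therefore demonstrate correctness of
the estimators and pipeline plumbing under realistic magnitudes and
noise, not robustness to every artifact of real scanner data.

## Numerical choices and edge cases

* Frame averaging uses composite Simpson quadrature (64 subintervals
  per frame; ≤1e-6 relative error for smooth curves).
* The ODE solver runs at rtol 1e-8/atol 1e-10; `K1 = 0` short-circuits
  to the exact blood-volume solution.
* Patlak fits require ≥2 usable frames and positive plasma activity at
  every used frame; FUR requires a positive plasma integral.
* The truncated-normal sampler uses the inverse-CDF construction
  (exact; impossible specifications such as sd = 0 with mean below the
  bound are rejected at spec construction).
* Zero-variance comparisons return t = 0, p = 1 (identical groups)
  rather than erroring, matching the convention that no evidence of a
  difference exists; zero-variance voxels are excluded from the FDR
  family.
* Correlation requires ≥3 complete pairs per stratum and errors on
  zero variance rather than returning NaN.
* All simulation and analysis is deterministic given the seed; the
  pipeline itself contains no randomness.

## Problem sizes used in the shipped checks

The package's tests and the acceptance script use: a 0–90 min, 18-frame
schedule with `t_star` 45 min for influx-recovery checks (noise-free,
plus 100 noisy replicates); 1,000 replicates for the power of the
two-group M-value design and 10,000 for its null calibration; 10,000
fuzzed inputs for the EGP identity; 1,000 random vectors for the BH
oracle comparison; 8×8×4 maps with 10 subjects per group for the
voxelwise check; and the full 22 + 19 default cohort for the end-to-end
pipeline run.

## Known limitations

* FUR-based adipose uptake carries the documented positive bias at
  mid-scan frame times; use Patlak windows late in the scan when
  absolute accuracy matters.
* The brain lumped constant default (0.65) is a convention; absolute
  brain uptake scales inversely with it.
* Liver Patlak rests on three frames at 40–55 min; with realistic noise
  its per-subject precision is poor (a property of the design, visible
  in the widened liver group comparisons).
* Whether R_d should be normalized per kg body weight or per kg
  fat-free mass before the EGP subtraction is ambiguous in clamp
  practice; the pipeline subtracts in per-kg-body-weight units and
  rescales to fat-free mass afterwards.
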