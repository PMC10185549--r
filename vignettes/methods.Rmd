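---
title: "Estimating phantom electrical properties from inversion-recovery relaxometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating phantom electrical properties from inversion-recovery relaxometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Electrical property tomography (EPT) aims to estimate the relative
permittivity $\varepsilon$ and conductivity $\sigma$ (S/m) of tissue
non-invasively from MRI. One family of approaches exploits the empirical
correlation between the longitudinal relaxation time T1 and the dielectric
state of aqueous materials: water content dominates both. `t1ept`
implements a complete in-silico version of a phantom study of this idea at
7 T: a cohort of 140 water/sucrose/NaCl/KCl phantoms whose ground-truth
dielectric properties are known, multi-TI inversion-recovery imaging of
those phantoms, pixel-wise relaxometry, and two competing estimators of the
electrical properties — closed-form curve fits and regression learning
(Gaussian process regression, a linear baseline, and a one-hidden-layer
neural fit) — evaluated at map level against the emulated probe
measurements.

## Signal model and the T0 normalisation

Every pixel of an inversion-recovery series is modelled as

$$S(TI) = a\,(1 - b\,e^{-TI/T_1}),$$

with amplitude $a$ (proton density scale), inversion coefficient $b$
(2 for a perfect inversion; lowered by transmit-field inhomogeneity, which
is substantial at 7 T) and relaxation time $T_1$. `fit_ir_signal()` and the
vectorised `fit_ir_field()` estimate $(a, b, T_1)$ by Levenberg–Marquardt
with starting values $a_0 = \max |S|$, $b_0 = 2$, and $T_{1,0}$ seeded
from the interpolated sign change of the signal when one is observed
(falling back to $TI_{\min S}/\ln 2$), with bounds $b \in [1, 2.5]$,
$T_1 \in [50, 10^4]$ ms. These initialisation rules and bounds are our own
robustness choices for the seven-TI protocol (TI = 200…4000 ms, TR
12000 ms); they are not data-derived.

Because $b$ absorbs the local inversion efficiency, the zero-crossing time

$$T_0 = T_1 \ln b$$

is a transmit-robust normalisation of $T_1$ ([t0_from_fit()]); it is the
time at which the fitted signed signal crosses zero. The natural logarithm
is forced by that zero-crossing identity (a base-10 reading would
contradict $S(T_0) = 0$); a `log_base` argument exists for comparison runs
only. Signed (real-valued) reconstruction is the default simulation and
fitting mode; a magnitude mode with a two-candidate polarity-restoration
step is available behind flags.

## Dielectric models

Permittivity follows a Debye-type dispersion in $T_0$:

$$\varepsilon(T_0) = e_1 + \frac{e_2 - e_1}{1 + (c\,T_0)^2},$$

fit by `fit_permittivity_curve()` (with Jacobian-based 95% CIs — the
standard first-order NLLS approximation). Conductivity relates to the loss
index via $\sigma = \omega\varepsilon_0\varepsilon''$; the package provides
the sodium-scaled relation
$\sigma = \omega\varepsilon_0 s_1 f T_0 / (1 + (s_2 f T_0)^2)$
(`fit_conductivity_t0()`), the per-sodium-level family
$\sigma = s_1 T_0/(1+(s_2 T_0)^2)$ with linear $s_1(\mathrm{Na})$ and
quadratic $s_2(\mathrm{Na})$ trends (`fit_sodium_family()`), and the
semicircle relation
$\sigma = \omega\varepsilon_0\sqrt{k^2 - (\varepsilon - cr)^2}\,sc$
fitted within T0 bins (`fit_semicircle()`). The two $\sigma$–$T_0$ forms
are implemented independently; the relation between their coefficient sets
is left open by design. Choices we had to make ourselves:

* evaluation frequency: the probe band is 200–400 MHz and no single
  frequency is canonical, so $\omega$ defaults to $2\pi \cdot 297.2$ MHz,
  the 7 T proton Larmor frequency (configurable via
  `physical_constants()`);
* the sodium fractions $f$ and $sc$ are mapped to $[0,1]$ as
  $\mathrm{Na}/2.4$, 2.4% being the largest sodium level in the mixture
  panels;
* semicircle fits use four equal-count T0 bins, and map prediction picks
  the bin with the nearest median T0.

## The synthetic cohort

`build_cohort()` reproduces the seven 20-phantom panels: water–sucrose
(0–70%), water–NaCl and water–KCl (0.25–5% in 0.25 steps), sucrose–salt
double mixtures ({12, 24, 36, 48, 60}% × {0.5, 1, 1.5, 2}%), NaCl–KCl
doubles, and a triple panel (13 phantoms at 25% sucrose, Na spread over
0.5–2.4%, K alternating 0.75/1.5%; 7 phantoms at 30–60% sucrose with Na
1.2%, K 1%). Several of the published counts and step sizes are mutually
inconsistent (e.g. "0–70% in steps of 4%" gives 18 values, not 20); we
resolve them by preserving the counts and the stated ranges: 20 evenly
spaced sucrose values, salt grids starting at 0.25%, and the triple-panel
layout above. The exact grids are not recoverable from the text, and
nothing downstream depends on them beyond counts and ranges.

Ground-truth dielectric values come from the single-solute concentration
fits about the pure-water baseline ($\varepsilon = 80.09$,
$\sigma = 0.022$ S/m at 20 °C): quadratic sucrose terms, linear salt
terms ($-2.15$/%Na and $+0.59$/%K for $\varepsilon$; 1.48/%Na and
0.52/%K for $\sigma$). For mixtures we combine permittivity additively,
but attenuate the ionic conductivity by a sucrose mobility factor
$v(S) = \max(1 - 0.009\,S,\ 0.2)$: dissolved sucrose raises viscosity and
displaces water, which slows ionic transport. A purely additive rule would
make conductivity independent of sucrose at fixed salt and erase the
$\sigma$–$T_0$ dependence that the per-sodium-level family fits rely on;
with $v(S)$ the fits see curves of the expected shape. $v(0) = 1$, so the
single-solute models are reproduced exactly.

Relaxation ground truth (`cohort_relaxation()`): the zero-crossing time is
driven by the water–sucrose matrix. We invert the Debye-type relation at a
*relaxation-relevant* matrix permittivity — a monotone quadratic in
sucrose through the water endpoint (80.09) and the 70% endpoint of the
measured model (48.8), with its 25% midpoint (76.3, i.e. T0 ≈ 1035 ms)
calibrated to the curve-vs-measurement mismatch that mid-sucrose mixtures
show — clipped so that $T_0 \in [200, 1500]$ ms, and then depress T0 by
13.5 ms per S/m of *ionic* conductivity. The measured-permittivity
polynomial itself is not used here because its small positive linear term
makes it flat below ~29% sucrose, which would freeze every dilute phantom
at the T0 cap; physically, dilute sucrose shortens T1 even where it barely
changes permittivity. The
physical reading: dissolved salts leave water-proton relaxation almost
unchanged (hence salt-only phantoms all sit in a narrow 1400–1500 ms
band regardless of concentration) while ionic T1 shortening and ionic
conduction both scale with ionic strength, making the small residual
depression proportional to the salt conductivity contribution. This
choice also gives every phantom a distinct zero-crossing time, as real
cohorts have. The inversion coefficient is
$b = \mathrm{clip}(2 e^{-\beta\sigma}, 1.2, 2)$ with
$\beta = \ln(4/3)/8$ per (S/m): conductive loading degrades the transmit
field. The net effect is the documented phenomenology: salt-only phantoms
have nearly constant T0 but T1 spread over roughly 1500–3600 ms.
`dielectric_to_relaxation()` exposes the plain inverse mapping (no salt
term) for arbitrary materials.

## Measurement emulation and noise calibration

`emulate_dak()` emulates a coaxial-probe session: per phantom one
between-phantom deviation (preparation, contact, and true deviation from
the concentration models) shared by three replicates, plus
within-replicate noise, plus the replicate mean as a fourth
pseudo-measurement. The defaults are
$(\sigma_{b,\varepsilon}, \sigma_{w,\varepsilon},
  \sigma_{b,\sigma}, \sigma_{w,\sigma}) = (1.0, 0.10, 0.20, 0.08)$.

The split was frozen after a Monte-Carlo calibration (grids of candidate
splits, 10–20 cohort seeds each) against the study's reference fit
statistics. Three facts shape it. First, the cohort design itself places a
structural residual of about 2.7 permittivity units around the Debye-type
curve: all salt-only phantoms cluster at T0 1400–1500 ms while their true
permittivity spans ~69–83, so the curve cannot pass through them — this is
exactly why the reference curve fit explains far less variance than the
regression learners. The reference total curve-fit scatter (RMSE ≈ 3.4) is
therefore a *sum* of structure and measurement noise, not pure noise, and
the calibrated noise budget is correspondingly smaller. Second, the
between-phantom component is what separates phantoms in the learners'
feature space, while the within-replicate component smears a phantom's
replicates apart; only a strongly asymmetric split (probe repeatability on
liquids is far better than between-phantom variability) lets the
conductivity learner reach its reference cross-validation floor. Third, the
within-replicate components set the cross-validation floors themselves
(≈1.15× the within SD), which pins them near 0.1 for permittivity and
0.08 S/m for conductivity.

Image noise is calibrated the same way. The acquisition's SNR is not part
of the protocol description, but a 12 s TR spin-echo series on water
phantoms at 7 T is an extremely high-SNR regime; the default
`noise_sd = 0.002` (SNR 500 at unit amplitude) reproduces the study's
reference regression-learning permittivity map error (~0.7%) and is the frozen
default of `simulate_ir_stack()` and `pipeline_config()`.

## Regression learning

`build_datasets()` assembles the study's tables: `De` (permittivity from
T0) and `Ds1`/`Ds2`/`Ds3` (conductivity from permittivity and T0 for
sodium-containing, potassium-containing, and all phantoms). Replicate
$r \in \{1,2,3\}$ is paired with slice $r$'s T0 and the mean row with the
slice-average T0; this 4×4 pairing is our own convention — the published
matrix description does not specify it. The conflicting slice counts in
the source (three imaged slices vs four dataset slices) are resolved the
same way: the slice-average serves as the fourth.

`train_cv_model()` trains GPR with one of four kernels (the "exponential"
kernel is Matern $\nu = 1/2$), or a linear baseline, under 5-fold CV.
Folds are assigned at the *row* level (replicates of one phantom may fall
in different folds), keyed to (id, replicate) so the assignment is
reproducible and row-order invariant. Row-level folding mirrors an
app-level protocol in which the learner never sees the replicate
structure; it is also the only reading under which the very high reference
CV scores are attainable, because a held-out replicate can then be
informed by its siblings. A phantom-grouped mode (`grouped = TRUE`) is
provided for honest generalisation estimates and is markedly worse — which
is worth remembering before reading the CV numbers as out-of-cohort
accuracy. GPR hyperparameters (isotropic length-scale on standardised
features, signal and noise SDs, plus the rational-quadratic shape) are
chosen by marginal-likelihood maximisation; ARD is deliberately off.

`train_nnf()` is a one-hidden-layer tanh network with linear output and a
70/15/15 split: Levenberg–Marquardt on the residual vector (analytic
Jacobian) with validation early stopping; a "Bayesian regularisation"
variant approximated as L2 weight decay selected on the validation split
(the full evidence framework is out of scope — the trainer is a baseline
here, not a contribution); and a conjugate-gradient trainer.

## Maps and evaluation

`permittivity_map()` applies a fitted model pixel-wise to the T0 map
(output clipped to the physical range [1, 90]);
`conductivity_map()` first box-averages the T0 and permittivity maps
(3 × 3 by default, mask-aware) because the two-input models amplify pixel
noise, then applies the model and clips negatives to zero. For the
curve-fit conductivity map the nearest-T0-bin semicircle model is used;
the sodium-family model is available as an alternative.
`roi_compare()` averages a 5 × 5 ROI at each disk centre (20 × 20 for the
tabular T0 extraction; even windows anchor top-left of the centre pixel)
and reports signed percent errors per phantom. Conductivity maps are
evaluated on whole-disk ROIs instead (`roi_px = Inf`): the two-input
conductivity models amplify T0 noise strongly, and disk-level averaging is
the footing on which such maps are judged in this literature. The headline summary is the
mean of absolute percent errors (MAPE); signed means are reported
alongside, since both conventions appear in this literature. All metrics
(RMSE, $R^2$, MAPE) flow through one implementation,
`regression_metrics()`.

## Numerical choices and degenerate inputs

* Whole-slice relaxometry solves the per-pixel 3×3 damped normal equations
  in closed form across all pixels simultaneously; pixels whose samples
  never exceed twice the noise floor are skipped (they cannot pass the
  amplitude mask, which requires the fitted $a$ to exceed 3× the noise SD —
  an invented but necessary plumbing threshold). The noise SD is estimated
  from the median absolute deviation of the first-TI image when not given.
* Degenerate pixel fits (all-zero signal, $b$ at its lower bound,
  non-convergence) are flagged and masked, never raised, so map fitting
  always completes; masked pixels carry `NA`, never 0.
* NLLS fits run to tight tolerances (`ftol = ptol = 1e-14`) so that
  noiseless recovery tests are meaningful to ~1e-6 relative.
* GPR adds a jitter of $10^{-10}\,\mathrm{sd}(y)^2$ to the kernel diagonal;
  with the noise variance optimised this is irrelevant, and with
  `sn = 0` it keeps the interpolating Cholesky stable.
* Semicircle predictions outside the fitted circle are clipped to zero and
  counted; degenerate T0 bins are skipped with a warning.

## Problem sizes used in the shipped checks

The package's own test-suite and the acceptance script run the full
140-phantom tabular analyses (560-row datasets) exactly as described, and
image-based checks at the native 320 × 320 geometry for the evaluated
triple-mixture slice (one slice, ten cohort seeds, medians reported).
Unit tests exercise the imaging chain on coarser 64–128 pixel grids with
the same ring geometry, which keeps the whole suite fast without changing
any algorithmic path.

## What the synthetic cohort does and does not show

The generator reproduces the cohort design, the reference concentration
models, the T0 phenomenology (salt-insensitive zero crossings, sucrose
contrast, transmit-loading effects on $b$), replicate measurement
structure, and Gaussian image noise. It does not model Bloch dynamics,
susceptibility or motion artifacts, Rician magnitude bias, temperature
drift, or probe bias; its mixture rule is first-order (interactions beyond
the sucrose mobility factor are absorbed into between-phantom noise); and
its T0–salt depression is an invented surrogate chosen for qualitative
fidelity. Consequently, passing checks demonstrate that the *pipeline*
(estimators, protocols, metrics) behaves as documented under the study's
own conditions — not that the fitted coefficients would transfer to any
particular real phantom set, and certainly not to tissue.

## Known limitations

* Conductivity estimation inherits permittivity-map errors by
  construction; the curve-fit conductivity route (semicircle bins) is
  clearly the weakest link of the estimator family.
* Pixel-wise conductivity mapping hits an information limit on this
  cohort: same-sucrose phantoms differ in T0 only through the small
  salt-driven depression (a few ms apart), so the learned conductivity
  surface has structure at the 1.5–3 ms scale. Under any realistic pixel
  noise the map mixes adjacent phantoms, biasing disk means by roughly the
  between-phantom measurement deviation (~10% of conductivity) even though
  the noiseless pipeline is exact to 0.3% and T0 ROIs are accurate to
  ±0.3 ms. The comparison between estimators is unaffected — the
  regression-learning conductivity map is still several times more
  accurate than the curve-fit one — but absolute sub-percent conductivity
  map errors are not reachable under these conditions.
* Row-level CV overstates generalisation; use `grouped = TRUE` for
  honest estimates.
* The neural-fit trainers are compact reimplementations (LM, decay-based
  regularisation, CG) rather than a full toolbox replica; wide networks
  can produce non-monotone responses, which is reproduced but not
  "fixed".
* Larmor frequency, ROI anchoring, bin count and the 4×4 replicate/slice
  pairing are all documented conventions, not measured facts.
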