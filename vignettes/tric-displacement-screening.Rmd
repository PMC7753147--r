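---
title: "TRIC displacement screening: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TRIC displacement screening: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tricscreen)
```

This vignette is the package's account of the science it implements: the
competitive-binding equilibrium at the core of displacement affinity
measurements, the trace model behind the synthetic data generator, the
screening and quality-control statistics, the dose-response machinery, and
the design decisions that were genuinely open. The benchmark system used
throughout is the gephyrin-E / glycine-receptor-β interaction: a fluorescent
tracer with an effective K~D~ of 1.54 nM bound to nanomolar receptor,
displaced by unmodified peptides with affinities around 12 µM.

## The displacement equilibrium

A labeled-protein titration measures the binding of a dye-conjugated target
directly, but dye conjugation can perturb binding and label every
interaction partner indiscriminately. The displacement geometry inverts the
problem: a high-affinity fluorescent *tracer* is pre-bound to the receptor,
and the unlabeled peptide of interest competes it off. The readout is the
tracer's bound fraction, and the peptide itself stays label-free.

For receptor total $R_0$, tracer total $T_0$ (dissociation constant $K_D$)
and competitor total $C_0$ (inhibition constant $K_i$), the free receptor
concentration $R$ satisfies the cubic

$$R^3 + aR^2 + bR + c = 0,\qquad
a = K_D + K_i + T_0 + C_0 - R_0,$$
$$b = K_i(T_0 - R_0) + K_D(C_0 - R_0) + K_D K_i,\qquad
c = -K_D K_i R_0,$$

whose unique root in $[0, R_0]$ gives all species through the individual
binding isotherms. `solve_competitive()` implements this closed form. Two
numerical points matter in practice:

* Over the nine-orders-of-magnitude concentration range of these assays
  (pM tracer systems, mM peptide stocks), the textbook trigonometric root
  formula loses the root to cancellation whenever the free-receptor
  concentration is many orders below the cubic's coefficients. The
  implementation therefore polishes the root with safeguarded
  Newton-bisection steps, seeded from whichever of the trigonometric root
  and the cancellation-free small-root limit $-c/b$ has the smaller cubic
  residual. This is still the exact cubic — just evaluated carefully.
* An independent route, `solve_competitive(method = "fixed_point")`, iterates
  the free-species mass balances with damping 0.5 and switches to bisection
  on the monotone scalar balance when the iteration contracts too slowly
  (which happens in stiff titration regimes where totals sit far above both
  constants). The test suite requires the two routes to agree to a relative
  1e-8 across a thousand random systems spanning 1 pM–1 mM; they typically
  agree to ~1e-10.

Computing bound species as `total - free` loses up to 15 significant digits
when binding is vanishingly weak; both solvers instead evaluate the
algebraically identical isotherm form $T_0 (R/K_D)/(1 + R/K_D)$.

### From EC50 to K~i~

A titration measures the competitor concentration at half-displacement
(EC50), which overstates $K_i$ because the competitor must also out-compete
the tracer. `ec50_to_ki()` offers the classical Cheng–Prusoff correction
$K_i = \mathrm{EC}_{50}/(1 + [T]_\mathrm{free}/K_D)$ — exact only when the
receptor barely depletes the tracer — and an exact mode that inverts the
cubic numerically: find the $K_i$ whose predicted half-displacement equals
the measured EC50. At the benchmark's working concentrations (5 nM receptor,
2 nM tracer, $K_D$ 1.54 nM) tracer depletion is far from negligible, which
is why the exact mode is the default everywhere downstream. Below the
stoichiometric floor (tight-binding regime) no $K_i$ can reproduce a given
EC50 and the conversion raises an error rather than extrapolating — the
assay, not the arithmetic, is at fault there.

## The synthetic trace generator

No instrument data accompany this package, so every analysis stage is
validated against a generator with known ground truth. The model is
deliberately the simplest one that reproduces the phenomenology of a
temperature-jump intensity trace: before the IR laser fires the trace sits
at a cold baseline; after it fires, each tracer state (bound / free) relaxes
mono-exponentially to a hot quasi-plateau,

$$F_s(t) = F_{0,s}\,\bigl(1 + A_s\,(1 - e^{-t/\tau_s})\bigr),\qquad
s \in \{\text{bound}, \text{free}\},$$

and a well's trace is the bound-fraction-weighted mixture
$F(t) = \theta F_\mathrm{bound}(t) + (1-\theta) F_\mathrm{free}(t)$ with
multiplicative Gaussian noise per sample. Defaults: recording from −1 s to
1.5 s at 100 Hz; $\tau$ = 0.15 s (bound) / 0.12 s (free); amplitudes −0.12 /
−0.06 (the dye dims on heating, more so when bound); noise CV 0.5%. The
schedule and photophysics are parameters, not assertions about any
instrument: real trace durations and laser powers are not public, so all of
them are config-exposed. Because F~norm~ is affine in the bound fraction
under this model, ground truth is exactly recoverable from noiseless traces
— the round-trip property the simulator tests enforce.

What the generator does *not* emulate: thermophoretic depletion (full MST),
spatial temperature fields, capillary optics, pipetting bias, plate-edge
effects, or peptide synthesis impurities. Passing tests therefore
demonstrate the correctness and calibration of the *analysis*, not
robustness to every artifact of real plates — with the exception of the four
artifact classes injected deliberately (below).

Four artifact classes mimic the failure modes that instrument-side QC
catches in practice: `autofluorescent` wells (baseline scaled up, as from an
intrinsically fluorescent peptide), `quenched` wells (scaled down),
`aggregated` wells (1–3 smooth Gaussian bumps, width 0.05–0.3 s, riding the
heating window — aggregates drifting through the detection volume), and
`bubble` wells (a step discontinuity).

## Trace analysis: F~norm~, QC, and the area statistic

**F~norm~** is the ratio of mean hot-window to mean cold-window fluorescence
in per-mille, `1000 * mean(F1) / mean(F0)`. Windows default to
[−0.8, 0] s and [1.0, 1.4] s: the cold window ends at laser-on and the hot
window sits on the quasi-plateau, comfortably after three relaxation times.
As a ratio it is invariant under any positive rescaling of the raw trace,
so detector gain cancels.

**Quality control** treats the plate as its own reference population
(requiring ≥ 8 wells):

* Baseline flags: a well whose cold baseline deviates from the plate median
  by more than +20% / −15% is flagged autofluorescent / quenched. With 0.5%
  trace noise averaged over ~80 baseline samples, the baseline estimate has
  ~0.06% precision, so these thresholds sit hundreds of standard errors from
  the null — false flags are driven by real composition effects, not noise.
* Aggregation flag: the heating-phase trace is smoothed by a running median
  and compared against its best-fitting mono-exponential relaxation
  $c_0 + c_1 e^{-t/\tau}$ over a grid of time constants; the flag fires when
  the maximum deviation exceeds 6 robust noise units (1.4826 × MAD of the
  high-pass residual). A monotone (isotonic) reference was evaluated first
  and rejected: an aggregation bump that rides the decreasing heating
  transient without breaking monotonicity is invisible to it, while the
  relaxation reference separates cleanly (artifact scores ≥ 7.5 vs clean
  ≤ 5.1 at the default conditions). Any clean well is a two-state relaxation
  mixture, which a single exponential tracks to well below the noise floor,
  so the reference is unbiased on nulls.
* Bubble flag: the largest single-sample jump, in robust noise units of the
  differenced trace, with an absolute floor of 5% of the signal level so
  that near-noiseless traces cannot divide by a vanishing noise estimate.
  Instrument-side axial-scan verdicts, where available, enter as an external
  flag column in the layout and are honored in addition to this software
  proxy.

**The area statistic** is the single-dose screen readout: normalize each
trace to its own baseline, average QC-passing test wells and control wells
(tracer–receptor complex, no competitor) separately, and integrate the
absolute difference over the heating window. The absolute value makes the
binder call one-sided in magnitude — whether a dye brightens or dims on
binding depends on the dye, not the biology. The raw integral is divided by
a calibration scale (default 0.04) chosen so that a fully displacing
competitor in a fully bound assay scores ≈ 2: the analytic integral of the
difference between the pure free-state and pure bound-state curves under the
default photophysics is ≈ 0.079, and 0.079 / 0.04 ≈ 2. On this scale the
conventional binder threshold of 0.5 (strict inequality) is meaningful and
portable: under benchmark conditions true binders score ≈ 1.1–1.6, while
non-binder areas — which are positively biased because the absolute
difference of noisy means never integrates to zero — stay near 0.1.
Peptides whose every well fails QC are reported *unevaluable*, never
silently scored zero.

## Dose-response fitting

Titrations follow the standard layout: twelve two-fold dilutions from a top
concentration (default 400 µM for the benchmark affinity), each well's
F~norm~ against competitor concentration. Two models are fitted by
Levenberg–Marquardt least squares:

* `competitive_exact` (default): $F_\mathrm{norm} = a + b\,\theta(C; K_i)$
  with the exact cubic as forward model and $K_i$ a free parameter. No
  low-depletion approximation enters, which matters at 2 nM tracer against a
  1.54 nM K~D~.
* `logistic4`: the four-parameter logistic on log~10~ concentration, the
  field's descriptive standard; its EC50 is converted through
  `ec50_to_ki()` (exact mode by default). Both EC50 and K~i~ are always
  reported together with the conversion used, since the two are frequently
  conflated in practice.

A series is fittable with at least 8 QC-passing points spanning ≥ 2 decades.
When the fitted displacement across the measured range does not exceed 4
residual standard deviations, the verdict is *no displacement* and the
affinity is censored one-sided as $K_i >$ top concentration — matching how
non-binding variants are reported in positional scans. The observed
prediction range, not the plateau difference, defines this amplitude: a flat
noise series can send the affinity parameter to a bound where the
*extrapolated* plateaus are absurd while the fitted curve is flat across
every measured point.

**Outlier exclusion** removes at most two points, one at a time, each of
which must be both statistically outlying — externally studentized residual
above 3.0, with leverage taken from the fit's Jacobian and the variance
estimated with the candidate's contribution deleted — and practically
significant: the deletion residual $r_i/(1-h_i)$ must exceed 8% of the
fitted amplitude. The second condition is a deliberate design decision. With
a dozen points and a t-calibrated threshold of 3.0, some point exceeds the
statistical criterion in roughly one clean series in six — a mathematical
property of the threshold, not a defect of the data — yet discarding such
points is pointless: their influence on the fit is negligible at the scale
of the signal. The amplitude floor eliminates those exclusions (measured 0%
across clean benchmark series) while a genuine 10-σ gross outlier, which at
realistic noise is 15%+ of the amplitude, is identified as the single
excluded point in ≥ 99% of series.

**Replicate summaries** report mean, SD, median, quartiles (linear
interpolation), 1.5 × IQR whiskers and outliers on the linear concentration
scale — the convention in which replicate K~i~ values are usually quoted —
with the geometric mean alongside, since affinities are log-normal in
general.

## Libraries, arrays, and the array–TRIC comparison

`make_overlapping_library()` tiles a parent sequence with 15-mers at offset
1 (the standard binding-site-mapping design), and `make_positional_scan()`
substitutes each position with all 20 residues, keeping WT-identical entries
marked — they are the normalization anchor of a scan. Coordinates are
1-based inclusive in the parent's own residue numbering, so a window labeled
414–428 is directly comparable with structure-derived numbering; generators
are pure functions and windows always slice back to their exact
subsequence.

Microarray spot tables are normalized per array: negative-control mean
subtracted (floored at zero; switchable off), then divided by that array's
mean WT intensity, then averaged across replicate arrays with per-cell SD.
This makes the heatmap scale-invariant per array, which is the only honest
treatment when absolute scanner units are arbitrary.

The array–TRIC comparison is a Spearman rank correlation between relative
spot intensity and −log~10~ K~i~. Censored affinities (non-binders) cannot
be ranked among finite values; the default policy ties them jointly below
every finite-affinity peptide, preserving their order information without
inventing numbers, and an `exclude` policy drops them instead. At least
three pairs are required.

The synthetic array generator drives spot intensity with receptor occupancy
at the probing concentration (50 nM, a typical array probing level for this
system), scaled so that specific signal for binders sits well above the
additive background (defaults: full-occupancy signal 2×10⁵, background 100,
10% log-normal spot noise, three replicate arrays). The ground-truth
affinity model multiplies the parent K~i~ by log-uniform penalties: 10^0.5^
to 10^1.2^ per substitution inside the binding motif, 10^−0.2^ to 10^0.3^
elsewhere. These defaults keep a full scan inside the determinable range of
a 12-point, 400 µM titration — mirroring the situation where the variants
carried into titration retain residual binding — while still concentrating
mutation sensitivity in the motif; optional complete non-binders are
available for testing the censoring policies. With one shared truth feeding
both the array generator and the trace simulator, the end-to-end rank
correlation is exactly 1 without noise and ≈ 0.97 at default noise across a
300-variant scan.

## Problem sizes and determinism

The validation suite runs at desk scale by design: 1,000 random systems for
the equilibrium cross-check, 100 simulated titrations for parameter
recovery and outlier properties, 50 noisy replicate screens of a
220-peptide library (456 wells on two plates, duplicate wells, 16 controls),
100 QC plates, and one full 300-variant positional scan in two noise
settings. Every stochastic step takes an explicit seed and is bit-for-bit
reproducible; analysis outputs depend only on inputs and configuration.

## Known limitations

* The equilibrium model is single-site and treats the dimeric tracer as one
  species with one effective K~D~; avidity, ternary complexes and binding
  kinetics are out of scope.
* The trace model is phenomenological. It is adequate for validating the
  statistics built on top of it, not a photophysical theory; conclusions
  about real instruments require real instrument data.
* QC thresholds are calibrated against the simulator's artifact models; a
  real campaign should recalibrate them against its own control wells (all
  thresholds are plain config values).
* The area calibration constant ties the 0.5 binder threshold to the
  default photophysics; changing dye or instrument response means
  recalibrating `area_scale` (a single division, but one that must be done).
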