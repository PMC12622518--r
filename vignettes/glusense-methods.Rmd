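---
title: "Models and methods behind glusense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind glusense}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glusense)
```

glusense analyzes experiments built around a ratiometric fluorescent
glutarate biosensor: a CsiR ligand-binding domain fused to a circularly
permuted yellow fluorescent protein whose 405/488 nm excitation ratio
(emission 528 nm) rises on glutarate binding. This vignette records the
models the package fits, the numerical decisions behind them, and what the
synthetic-data module does and does not emulate.

## The dose-response model

All calibration, quantification and time-course analysis rests on the
four-parameter Hill response

$$R(C) \;=\; R_{max} + \frac{R_{min}-R_{max}}{1+(C/K_d)^p},$$

with $R$ the measured F405/F488 ratio, $C$ the analyte concentration in
µM (the package's canonical unit), $K_d$ the apparent dissociation
constant and $p$ the Hill slope. Two algebraic identities anchor the test
suite: $R(0)=R_{min}$ exactly (the model is evaluated directly at zero
rather than on log-concentrations, so no pseudo-count is needed) and
$R(K_d)=(R_{min}+R_{max})/2$ for every $p$. The dynamic range is
$\Delta R_{max}=(R_{max}-R_{min})/R_{min}$.

`fit_dose_response()` uses Levenberg-Marquardt (`minpack.lm::nlsLM`) with
data-driven starts ($R_{min}$/$R_{max}$ from the extreme-concentration
means, $K_d$ from the concentration nearest half-response, $p=1$) and a
restart ladder over $p\in\{1, 0.5, 2\}$ because the likelihood is
occasionally flat in $p$. Bounds keep the fit physical and honest:
$p\in[0.3,4]$ (a flag fixes $p=1$), and $K_d$ is confined to
[min positive concentration / 10, max concentration × 10] so a calibration
can never report an affinity far outside the sampled range. Data whose
concentration-ratio Spearman correlation is below 0.5 are flagged
`non_monotone_data`; an all-flat plate returns a degenerate fit flagged
`flat_response` instead of erroring, since screens legitimately produce
dead wells. Confidence intervals for $K_d$ (`kd_confint()`) are Wald
intervals on $\log K_d$ with a Student-t quantile at the residual degrees
of freedom; affinity estimates are closer to log-normal than normal, and
the plain z-interval measurably undercovers at calibration-plate sizes.

### Inversion, censoring and quantification

Quantification substitutes a measured ratio into the exact inverse
$C = K_d\,((R-R_{min})/(R_{max}-R))^{1/p}$. Ratios at or below $R_{min}$
are censored `below_range` (reported as concentration 0, a bound), at or
above $R_{max}$ `above_range` — censoring is data, not an error.
`quantify_samples()` inverts the *replicate-mean* ratio rather than
averaging per-replicate inversions: the inverse curve is convex near
saturation, so per-replicate inversion acquires a heavy right tail and a
systematic upward bias exactly where the assay is least precise; inverting
the mean suppresses both. Its confidence interval combines, in quadrature,
the delta-method variance propagated from the calibration covariance
(numeric gradient of the inverse in $R_{min},R_{max},K_d,p$) with the
replicate ratio scatter mapped through the local inverse slope. The
dilution argument accepts per-sample factors because bench protocols
dilute concentrated samples into the sensor's informative range before the
3:1 sample:sensor mixing step (factor 4/3); the reported
`dilution_factor` column makes the applied denominator explicit, as does
`normalize_to_control()`, which always divides by the stated control mean.

The limit of detection is the classic blank-based 3σ criterion: the
concentration whose predicted ratio equals mean(blanks) + 3 sd(blanks).
With noiseless blanks the LOD is exactly 0, and it is monotone in the
blank scatter; when the criterion exceeds $R_{max}$ the LOD is undefined
and flagged rather than clipped.

pH stabilization divides the sensor ratio by the ratio of the unfused
reporter fluorophore measured alongside: both share the chromophore's pH
response, so a common factor cancels. The simulated pH series in the test
suite builds both readouts from one shared pH factor and asserts that
correction flattens the series that the raw ratio does not.

## Thermal-shift analysis

Tm is defined by the derivative-melt-curve convention: the temperature of
the maximum of dF/dT (dye fluorescence rises through unfolding), not a
half-amplitude midpoint, and no two-state thermodynamic fit is attempted.
The estimator computes a Savitzky-Golay quadratic first derivative
(default window 21 points) and refines the peak by the vertex of a
quadratic fitted to the contiguous block of derivative points at or above
50% of the peak height. This pairing was chosen numerically: on a 0.1 °C
grid with 1% amplitude noise, narrow-window smoothing with a 3-point
vertex refinement has a Tm standard deviation near 0.5 °C, far too noisy
to separate programmed shifts of 1.9 and 2.1 °C around the 2 °C binder
threshold, while the wide-window/50%-region estimator reaches ~0.04 °C
with no measurable bias and remains exact on noiseless logistic curves for
any grid step up to 0.5 °C (a symmetric kernel cannot displace a symmetric
peak). Both the window and the refinement fraction are arguments.

Post-transition quenching — fluorescence decaying after the unfolding
transition — is tolerated by restricting the peak search to temperatures
at or below the global maximum of the smoothed trace, inside a default
search range of 30-90 °C that avoids edge artifacts. Curves whose
derivative is nowhere positive in the window (aggregated or pre-unfolded
protein) return a `no_transition` flag with an undefined Tm, which
propagates through `delta_tm()` as NA. Binder calls use a strict
inequality, ΔTm > 2 °C, so a shift of exactly 2 °C is not a binder; when
a concentration series is available the call also reports whether ΔTm is
non-decreasing with concentration, the qualitative trend expected of
genuine binding.

## Transporter kinetics

Ratio time courses from cells expressing the sensor are
reference-corrected, inverted pointwise through the calibration (censored
points carried as bounds; a trace more than half outside the sensor range
is rejected), and summarized as an initial rate: the OLS slope over the
first 60 s by default, matching one-minute kinetic sampling, with an
adaptive mode that shrinks the window until the quadratic curvature term
of a local polynomial fit is insignificant. On a concave saturating trace
the windowed OLS slope is a slight underestimate of the true initial
derivative, bounded by the window's curvature — the test suite asserts
this on generator traces. Rates are reported per assay well at the assay's
fixed cell density (OD600 5.0 suspensions); no per-cell conversion is
attempted.

`fit_michaelis_menten()` fits $v = V_{max}S/(K_m+S)$ by
Levenberg-Marquardt with a small multi-start over $K_m$ (the
half-response start, the substrate median, and scaled extremes), flags
substrate series that fail to bracket [Km/3, 3Km], and on total failure
reports a Lineweaver-Burk double-reciprocal estimate in the error message
only — the linearization is never silently promoted to a result.
Inhibitor panels are classified by thresholds, as in the underlying assay
logic: a protonophore-class treatment at or above 90% inhibition while
thiol and metabolic classes stay under 50% yields `proton_coupled`
(analogously `thiol_sensitive`, `metabolically_gated`); everything under
50% is `unaffected`; anything else, or a panel missing a protonophore, is
`indeterminate`. The 90/50 defaults are configuration, since "complete
suppression" is not a number. Efflux experiments run through the same
machinery on extracellular-sensor traces; direction is metadata, not a
separate code path.

## Isotopologue correction and flux partitioning

Measured GC-MS isotopologue intensities convolve the tracer labeling state
with natural isotope abundance (and tracer impurity).
`build_correction_matrix()` constructs that forward operator explicitly
for a fragment formula: column $j$ (molecules carrying $j$ tracer labels)
is the convolution of a binomial natural-13C distribution over the $n-j$
unlabeled tracer positions, a binomial purity distribution over the $j$
labeled positions, and the natural mass-shift distribution of every other
atom in the fragment — including derivatization atoms such as Si, which
dominate the +1/+2 envelope of TBDMS fragments. Fragment formulas are
inputs, not a hardcoded library, because the derivatized fragment
compositions are assay-specific. Isotope abundances are IUPAC/CIAAW 2021
values compiled as package constants; distributions are truncated only
beyond cumulative probability $1-10^{-12}$. Correction solves
$\min\lVert Mx - \text{raw}\rVert^2,\ x\ge 0$ by nonnegative least squares
and renormalizes, guaranteeing physical MIDs under noise where a direct
inverse can go negative; condition numbers above $10^8$ set a flag. The
brute-force oracle in the tests enumerates every per-atom isotope state
for fragments up to 12 atoms and agrees with the convolution construction
to $10^{-10}$.

The flux question is a two-source mixing problem, not a full
atom-mapping 13C-MFA network — that is a deliberate non-goal. The
corrected wild-type MDV of a downstream metabolite fragment is modeled as
$f\,H + (1-f)\,D$, where the boundary signatures $H$ (hydroxylation
route) and $D$ (dehydrogenation route) come from the single-pathway
knockout strains measured in the same experiment. The default estimator is
the closed-form least-squares projection
$f = \langle obs - D, H - D\rangle / \lVert H-D\rVert^2$ clipped to
[0, 1]; the one-channel m+5 ratio estimator
$(obs_5 - D_5)/(H_5 - D_5)$ is always computed alongside, because the two
coincide exactly when the boundaries differ only in the m+0 and
fully-labeled channels and diverge otherwise — reporting both makes that
ambiguity visible. The two reported fractions sum to 1 exactly by
construction. Uncertainty comes from a percentile bootstrap over
biological replicates (deterministic given a seed), since the mixing
fraction has no convenient closed-form variance under renormalized NNLS
corrections. Boundaries identical within tolerance are an unidentifiable
design and raise an error.

## The synthetic-data module

Every generator is a pure function of (config, seed); per-dataset streams
are derived from (seed, role) so adding one dataset never perturbs
another, and generators restore the caller's RNG state. The defaults in
`scenario_config()` are the study conditions the estimators are validated
against: sensor truth $R_{min}=1$, $R_{max}=7.46$ (ΔRmax 646%),
$K_d = 60.68$ µM, $p=1$; melt transition at 52.3 °C on a 0.1 °C grid over
25-95 °C with width 1.5 °C, mild post-transition quench and 1% amplitude
noise; transporter $K_m = 23.34$ µM probed at 8 substrate levels spanning
5-400 µM with 60 µM/min $V_{max}$, 15 s sampling over 60 s and a
95/10/10% CCCP/PCMB/iodoacetamide inhibition panel; a 50:50
labeled/unlabeled glutarate feed at tracer purity 0.99 split
93.38%/6.62% between hydroxylation and dehydrogenation; spike-recovery
levels from 0 to 2000 µM. Noise defaults are 3% multiplicative Gaussian on
ratios (plate reader), 5% on uptake traces, additive Gaussian at 1% of
total area on isotopologue channels (clipped at zero), and 2% on the
reference method.

Two generator choices deserve their rationale. First, the citrate-fragment
boundary MDVs default to an m+5/m+4-heavy $H$ and an m+2/m+3-heavy $D$ —
qualitative encodings of 2-ketoglutarate-route versus acetyl-CoA-route
labeling. They are illustrative shapes, not outputs of a TCA atom map, and
are configurable; every flux-recovery claim in the tests is relative to
these programmed boundaries. Second, the spike-recovery generator assigns
each spike the smallest pre-dilution from {1, 2, 5, 10, 20, 50, 100} that
brings its expected in-well concentration to roughly 1.5 $K_d$ or less,
mirroring how a lab actually measures a 2 mM sample on a 60 µM-$K_d$
sensor. Without that step, concentrations beyond ~5 $K_d$ in-well sit on
the saturating shoulder where the inverse curve amplifies 3% ratio noise
into tens of percent of concentration error, and method agreement there
reflects arithmetic, not chemistry.

What the generators do not emulate: instrument drift and well-position
effects, spectral bleed-through, matrix-specific quenching beyond a
shared baseline, chromatographic peak integration, substrate depletion
during uptake (external substrate is treated as constant over the 60 s
window), or realistic TCA-cycle label scrambling. Passing recovery tests
therefore demonstrates estimator correctness under the stated statistical
structure, not robustness to every artifact of real instruments.

## Problem sizes and numerical conventions

The validation suite uses 200 seeded calibrations for dose-response
recovery, 100 melt curves and 100 four-ligand screens for Tm and binder
calls, 100 labeling datasets for flux recovery, 100 uptake experiments
for the end-to-end $K_m$ pipeline, and 1000 bootstrap draws — sizes chosen
so each Monte-Carlo summary is stable to well within the tolerance the
corresponding test asserts.
Reports serialize numbers at 17 significant digits so deserializing and
re-serializing reproduces files byte-exactly; all tabular I/O is
comma-separated UTF-8 with `.` decimals (a flag accepts tabs), column
layouts are explicit config rather than guessed, and concentrations are
canonicalized to µM on read.

## Known limitations

Hill fits assume homoscedastic ratio noise; strongly
concentration-dependent error would call for weights the interface does
not currently expose. The LOD criterion is the blank-based 3σ convention;
matrix-specific reported LODs are treated as order-of-magnitude
consistency anchors, not exact targets, because the criterion behind them
is not stated. The flux model is two-source mixing with
knockout-derived boundaries; if both pathways were active in the boundary
strains, or the feed's mole fraction diverged from its mass fraction
(assumed equal for the 50:50 feed), the estimated split inherits that
bias. Transport classification is threshold logic over measured rates,
not a mechanistic membrane model.
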