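---
title: "Models and methods: membrane NMR and ESR lineshape analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: membrane NMR and ESR lineshape analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinorder)
```

# Scope

`spinorder` analyzes the one-dimensional spectra used to characterize how a
hydrophobic drug (cyclosporin A, CYSP), a poly-alpha-cyclodextrin copolymer
host (POLYA), and their amorphous solid dispersion (ASD) interact with model
DMPC membranes:

* ²H NMR powder patterns of chain-perdeuterated DMPC (DMPC-d54) — de-Pake-ing,
  quadrupolar splittings, C–D order parameters, fluidity profiles;
* ³¹P NMR powder lineshapes — chemical shift anisotropy (CSA) and isotropic
  components;
* nitroxide (5-DOXYL stearate) first-derivative ESR spectra — hyperfine
  splittings and the apparent order parameter;
* gel → liquid-crystal transition detection from any observable-vs-temperature
  series;
* ¹H fast-exchange titrations — continuous-variations (Job) stoichiometry and
  the apparent 1:1 association constant.

No instrument raw data accompany the study, so a synthetic-spectrum generator
with explicit ground truth stands in for the spectrometer; every analysis
stage is validated as a generator → analysis round trip.

# The ²H powder model and de-Pake-ing

A C–D bond at angle θ between the bilayer normal and the field contributes a
doublet at ν = ±Δν⁹⁰·(3cos²θ − 1)/2, where Δν⁹⁰ is the 90°-orientation
(horn) splitting. A powder of randomly oriented bilayers is uniform in cosθ,
so each chain position produces the classical Pake doublet: horns separated
by Δν⁹⁰, 0° shoulders at twice that. The generator integrates this on a
uniform-cosθ grid (2000 orientations by default — an unbiased powder
average), convolves with a Lorentzian (FWHM `broadening_khz`), sums
components with deuteron-count weights, and adds seeded Gaussian noise last.

Splittings convert to order parameters through
Δν_Q = (3/4)·(e²qQ/h)·S_CD with e²qQ/h = 170 kHz for aliphatic C–D bonds, so
S_CD = Δν_Q/127.5 kHz. The angular form S_CD = (3cos²β − 1)/2 is implemented
exactly as printed in the source literature; note that the accompanying text
there describes β against "the direction perpendicular to the bilayer
normal", which conflicts with the usual bilayer-normal convention — the
package implements the formula, not the prose, and leaves the convention
question open.

`depake()` treats de-Pake-ing as an explicit linear inverse problem: the
forward operator K maps a unit weight at grid splitting Δ to its broadened
powder doublet (the same orientation model as the generator), and the
oriented-splitting distribution w solves

    min ‖Kw − s‖² + λ‖Dw‖²,  w ≥ 0,

with D a second-difference penalty, solved by a fast active-set non-negative
least-squares routine on the normal equations. This produces the same object
as classical de-Pake-ing — an oriented-sample splitting distribution with
overlapping doublets resolved — but is well conditioned and directly
testable against the generator. λ = `"auto"` picks the corner of a discrete
L-curve (maximum Menger curvature over a 7-point log-spaced candidate grid);
a numeric λ (including 0) is accepted. The default grid is 0.5–40 kHz in
0.1 kHz steps; the spectrum axis must cover the largest grid splitting,
since the 0° shoulders sit there.

`extract_splittings()` peak-picks the weight vector above a floor of
3×MAD(w) (with a 0.5 %-of-maximum guard against an all-but-zero MAD), merges
peaks closer than `min_separation_khz` (default 1 kHz) into weighted
centroids, and reports components in descending weight. `assign_profile()`
maps sorted splittings to chain positions — smallest → CD3, largest → the
C2–C8 "plateau" treated as one effective component, intermediates → C14…C9 —
and `relative_fluidity()` forms R = (QS_X − QS_ref)/QS_ref per matched label.

**Resolution limit.** Round-trip tests (20 random 2–9-component profiles,
splittings 2–35 kHz, broadening up to 1 kHz, SNR ≥ 50) recover every true
splitting within max(0.5 kHz, grid step) with no spurious component above
10 % of the largest weight — *provided components are separated by at least
about three Lorentzian linewidths*. Below that separation two low-weight
doublets blur into a shared mode that no regularization level separates;
this is an information limit of the data, not of the solver, and the
property tests draw component sets in the resolvable regime.

**Fixtures.** `dmpc_d54_fixture()` encodes the measured 298 K endpoint
splittings of the four systems (DMPC 4.0/29.0, +CYSP 4.2/31.0, +POLYA
3.6/26.6, +ASD 4.4/28.0 kHz). The six intermediate C14…C9 splittings are not
reported individually anywhere; the fixture interpolates linearly between
the endpoints (the measured profile is monotone), and a custom interpolation
function can be supplied. The 308 K lists are synthetic stand-ins scaled
from the 298 K values to match the qualitative high-temperature picture
(overall fluidization; CYSP effects nearly gone; POLYA fluidization more
pronounced; ASD mildly rigidifying); they are labelled as such and carry no
measured authority.

# ³¹P CSA analysis

The axially symmetric powder lineshape is generated from
σ(θ) = σ⊥ + (σ∥ − σ⊥)cos²θ with σ⊥ = iso + CSA/3 (the intensity maximum, at
low field for the motionally averaged phospholipid tensor) and σ∥ =
iso − 2·CSA/3, so the lowfield/highfield edge separation is exactly the CSA.

`measure_csa()` smooths (Savitzky–Golay), removes a median baseline (outer
10 % of points), brackets the pattern by the outermost crossings of
`edge_threshold`×max (default 5 %), and then *refines* the edges: a
fixed-fraction crossing sits where the Lorentzian tail, not the edge, falls
through the threshold, which for a broadened inverse-square-root horn is
1–3 ppm outside the true edge — a bias larger than the quantity's
reproducibility. Instead, the edge adjacent to the global maximum (the
perpendicular singularity coincides with that edge in an axially symmetric
pattern) is read at the interpolated peak itself, and the opposite shoulder
edge at the steepest-slope point of its outer flank, where the inflection
of a broadened step sits at the step. Both refinements are invariant under
axis translation and intensity scaling. Lineshapes whose measured width
falls below `near_isotropic_below` (5 ppm) are flagged near-isotropic. The
derivative used for the slope refinement is smoothed over ~2 % of the trace
length; edge slopes are broad features and survive this, noise derivatives
do not.

`detect_isotropic()` looks for a line at the isotropic position
(lowfield_edge − CSA/3 for this tensor). A dominant central line is located
directly at the global maximum when that maximum sits well inside the
threshold bracket; otherwise the search window centers on the expected
isotropic position. A Lorentzian plus linear local-powder baseline is
fitted (window widened adaptively up to 8 fitted half-widths for broad
lines), and the analytic area πAγ over the total integrated intensity gives
the area fraction. Classification follows the linewidth: ≤ 100 Hz is a
resolved solubilization line, 100 Hz–2 kHz a broad membrane-fragment
component, otherwise none; the cutoffs generalize the described contrast
between a resolved line of a few tens of Hz and 600 Hz–1 kHz fragment
lines, and are arguments, not constants.

# ESR hyperfine analysis

The generator builds the first-derivative trace phenomenologically from the
two measurable splittings: a central derivative line, Gaussian wings placed
so the outermost maximum/minimum are separated by exactly 2T∥ (positive at
low field), and an inner pair (low-field minimum, high-field maximum)
separated by exactly 2T⊥ — the geometry of a membrane-incorporated 5-DOXYL
stearate spectrum. Slow-motion simulation is deliberately out of scope: the
downstream analysis uses only the two splittings.

`measure_hyperfine()` smooths at the hyperfine feature scale (~2 % of the
trace by default), keeps extrema that clear both an amplitude floor (5 % of
the maximum) and a prominence floor (4 % of the maximum or 10× the smoothed
noise, whichever is larger — noise riding on a decaying wing tail creates
arbitrarily outlying local maxima of small prominence), reads 2T∥ from the
outermost maximum/minimum pair, 2T⊥ from the flanking inner pair, and
refines positions by windowed least-squares parabolas (a 3-point vertex is
too noise-sensitive on broad wings). Three narrow lines with nearly equal
inner and outer separations are the signature of unincorporated, freely
rotating probe; measurements with 2T∥ − 2T⊥ below 8 G are flagged.

The order parameter is computed *exactly as printed* in the source
formula: with T∥ = 2T∥/2, T⊥ = 2T⊥/2 and the polarity correction
C = 1.4 − 0.053·(T∥ − T⊥),

    S = 1.723 · (2T∥ − 2T⊥ − C) / (T∥ + 2T⊥ + C),

whose numerator uses full separations while the denominator mixes a half
and a full separation. The formula as printed can therefore leave [0, 1],
and the package reports it as-is; whether the denominator was meant to be
the conventional all-half-separation form cannot be decided from the text
(no numeric S values are printed to disambiguate), so that variant is
available as `form = "half-separation"` — never silently.

# Transition fitting

Observable-vs-temperature series (CSA, splittings, ESR order) are fitted
with the logistic

    obs(T) = high + (low − high)·plogis((midpoint − T)/width)

by Levenberg–Marquardt, initialized at the temperature of maximum absolute
slope. A logistic rather than an error-function shape is a modelling choice;
the source plots the jump but never parameterizes it, and at the tested
noise levels the two are indistinguishable. A fitted amplitude below 4× the
residual noise, or a midpoint escaping the data range, returns a
`no_transition` flag instead of an error, so flat series flow through
pipelines. Fewer than 6 points is an error.

# Binding analysis

The 1:1 equilibrium is solved exactly:
[HG] = (s − sqrt(s² − 4·H0·G0))/2 with s = H0 + G0 + Kd, Kd = 10^(−log Ka);
observed host shifts are the fast-exchange population average
δ_free + (δ_bound − δ_free)·[HG]/H0. The continuous-variations response is
y(F) = |δ_obs − δ_free|·F (host-observed weighting; the alternative Δδ·H0
weighting differs only by the constant total concentration and peaks at the
same stoichiometric fraction — both are available). δ_free comes from the
stored pure-host anchor or is supplied explicitly; maxima are located by
quadratic interpolation and pooled across resonances by the median, with
flat (degenerate) resonances flagged rather than fitted.

`fit_association_constant()` minimizes the summed squared shift residuals
over log Ka (log-parameterized to keep Ka positive) and one bound shift per
resonance with Nelder–Mead simplex. Because the bound shifts are linear
given log Ka, a profiled coarse scan over log Ka ∈ [1, 8] locates the global
basin first; the simplex then polishes from that start plus five spaced
starts, and the lowest-RSS run wins. A series without shift variation
raises a non-identifiability error.

**Identifiability limits.** At 2 mM total concentration, 0.002 ppm shift
noise, nine fractions and six resonances with 0.06–0.12 ppm bound-shift
changes, the median recovery error is below 0.1 log units for true
log Ka ≈ 3.5–4.5. Two regimes are information-limited, not solver-limited
(verified against an exhaustive profiled scan): near-stoichiometric binding
(log Ka ≳ 5.5), where Ka lives only in the corner rounding of the binding
curve, degrades the median toward ~0.1–0.15; and weak binding
(Kd ≫ total concentration), where only the product Ka·Δδ is identified and
errors of an order of magnitude occur. The tests assert the attainable
bounds in each regime.

# Study conditions embodied in the generator defaults

| quantity | default | basis |
|---|---|---|
| total titration concentration | 2 mM | stated experimental design |
| titration noise | 0.002 ppm | assumed instrument scale |
| observed resonances | 6 (host glucose protons) | resonances followed in the study |
| bound-shift changes | 0.06–0.12 ppm | centered on the 0.10 ppm scale used throughout |
| ²H broadening | 0.5 kHz FWHM | typical MLV linewidth |
| spectrum SNR | 100 (fixtures), 50 (degraded) | typical accumulation |
| CSA model | 58 ppm, 1 ppm broadening | liquid-crystalline DMPC at 298 K |
| transition | midpoint 297 K, width 0.8 K | DMPC main transition |
| ESR S(T) range | 0.68 → 0.48 | typical 5-DOXYL order parameters across the transition |
| orientation grid | 2000 points, uniform cosθ | unbiased powder average |
| noise model | additive Gaussian, explicit seed | — |

What the generators do **not** emulate: relaxation and finite-pulse
artifacts, magic-angle spinning, slow-motional ESR lineshapes, probe
partitioning, m:n binding beyond 1:1, the asymmetric Job curves noted for
the real polydisperse host, baseline roll and phase errors. Green round
trips therefore demonstrate correctness of the inversion and measurement
code under the stated lineshape models, not robustness to every instrument
artifact.

# Numerical choices

* Axes are stored ascending; descending files are normalized on read with
  the original order recorded. Units are explicit metadata, never inferred.
* Orientation histograms use first-order (linear) binning; Lorentzian
  convolution uses a kernel truncated at 60 half-widths.
* Powder spectra are symmetrized (even part) before inversion; the
  asymmetry fraction is computed on a smoothed trace so white noise does
  not register, and asymmetry above 5 % warns.
* The NNLS solver works on the normal equations with a Cholesky-jittered
  fallback for rank-deficient active sets; λ = 0 is permitted.
* Peak positions are refined by weighted centroids (splitting
  distributions) or windowed quadratic fits (derivative extrema); ties in
  peak merging resolve toward the heavier component via weighted centroids.
* Degenerate inputs fail loudly and specifically: all-zero spectra, grids
  exceeding axis coverage, flat titrations, sub-minimal point counts each
  raise a classed error; flat temperature series flag rather than throw.
* Problem sizes in the tests and acceptance runs — 1024–2048-point spectra,
  0.1–0.25 kHz inversion grids, 20-replicate property loops — are the sizes
  at which the round-trip tolerances above were established.

# Known limitations

* The de-Pake forward operator assumes the generator's ideal powder model;
  real spectra with orientation bias (partially aligned samples) violate it.
* CSA edge refinement assumes an axially symmetric tensor with the
  perpendicular edge as global maximum; strongly overlapping isotropic
  lines bias `measure_csa()` and are handled only through
  `detect_isotropic()`'s fit-and-classify path.
* The ESR construction is phenomenological; only the two splittings are
  meaningful, not the full lineshape.
* Binding analysis assumes a single effective host site; the polydispersity
  of the real copolymer host (which the source itself flags as making the
  constant "apparent" at best) is not modelled.
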