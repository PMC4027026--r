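# spinorder

Order-parameter and lineshape analysis for membrane NMR and ESR spectra.

`spinorder` is for spectroscopists characterizing drug–membrane and
host–guest interactions in model phospholipid systems — here, cyclosporin A
(CYSP), a poly-alpha-cyclodextrin copolymer (POLYA), and their amorphous
solid dispersion (ASD) interacting with DMPC multilamellar vesicles. It
implements the complete quantitative chain from 1D spectra to the
comparison statistics such studies report:

* **²H NMR**: de-Pake-ing of powder patterns by regularized non-negative
  inversion of an explicit orientation-averaged forward operator
  (`depake()`), extraction of quadrupolar splittings Δν_Q, the segmental
  order parameter S_CD = Δν_Q / ((3/4)·e²qQ/h) with e²qQ/h = 170 kHz,
  per-position fluidity profiles, and the relative local fluidity
  R = (QS_X − QS_ref)/QS_ref against a reference membrane.
* **³¹P NMR**: chemical shift anisotropy (CSA — the lowfield/highfield edge
  separation of the axially symmetric powder pattern) with
  translation/scale-invariant edge refinement, plus detection and
  classification of isotropic components (solubilization vs membrane
  fragments) by fitted linewidth and area fraction.
* **ESR**: hyperfine splittings 2T∥ and 2T⊥ from first-derivative nitroxide
  spectra and the apparent order parameter
  S = 1.723·(2T∥ − 2T⊥ − C)/(T∥ + 2T⊥ + C), C = 1.4 − 0.053·(T∥ − T⊥),
  implemented exactly as printed in the membrane ESR literature (a
  conventional half-separation variant is available behind a flag).
* **Transitions**: logistic fitting of gel → liquid-crystal transitions
  (midpoint, width, amplitude) from any observable-vs-temperature series.
* **Binding**: the exact 1:1 fast-exchange model, continuous-variations
  (Job) analysis peaking at the stoichiometric fraction, and multi-start
  Nelder–Mead (simplex) fitting of the apparent association constant
  log Ka from chemical shift titrations.
* **Synthetic data**: every input the analyses consume can be generated
  with known ground truth (`simulate_pake_spectrum()`,
  `simulate_csa_powder()`, `simulate_esr_spectrum()`,
  `simulate_transition_series()`, `simulate_job_series()`, and the
  DMPC-d54 system fixtures `dmpc_d54_fixture()`), so every stage is
  validated as a generator → analysis round trip.

See `vignettes/membrane-spectra-methods.Rmd` for the models, parameter
choices, and known limitations.

## Worked example

Generate the pure DMPC-d54 fixture spectrum at 298 K, de-Pake it, and build
the fluidity profile:

```r
library(spinorder)

sp <- simulate_pake_spectrum(dmpc_d54_fixture("DMPC", 298),
                             broadening_khz = 0.5, axis_range_khz = 40,
                             n_points = 2048, noise_sd = 0.01, seed = 7)
d <- depake(sp, grid = seq(0.5, 36, by = 0.1), lambda = "auto")
assign_profile(extract_splittings(d), system = "DMPC", temperature = 298)
#> <fluidity_profile> DMPC at 298 K (e2qQ/h = 170 kHz)
#>    label delta_nu_q       s_cd    weight
#>      CD3   3.994115 0.03132639  52.27744
#>      C14   7.580623 0.05945587  36.46340
#>      C13  11.159093 0.08752230  34.24454
#>      C12  14.698538 0.11528265  34.36274
#>      C11  18.288575 0.14343980  34.65853
#>      C10  21.883935 0.17163870  36.13212
#>       C9  25.404237 0.19924892  33.72328
#>  plateau  29.001418 0.22746210 247.28371
```

The inversion resolves all eight chain positions of the messy superposition:
the CD3 doublet at 4 kHz (S_CD ≈ 0.031) and the C2–C8 plateau at 29 kHz
(S_CD ≈ 0.227) recover the generator's ground truth to well under the
0.1 kHz grid step, and the weights reflect the deuteron counts (6 : 4 : 28).
Comparing a POLYA-containing membrane (same pipeline run on the
`"DMPC+POLYA"` fixture) against this reference,

```r
relative_fluidity(profile_polya, profile_dmpc)
#> <relative_fluidity> DMPC+POLYA vs DMPC
#>    label      qs_x    qs_ref           R
#>      CD3  3.596582  3.994115 -0.09952986
#>  ...
#>  plateau 26.598112 29.001418 -0.08286857
```

every chain position shows R ≈ −0.08 to −0.10: a homogeneous ~8–10 %
fluidization of the bilayer, the signature this statistic exists to expose.

The ³¹P, ESR, and binding stages work the same way:

```r
measure_csa(simulate_csa_powder(csa_model(58, broadening = 1),
                                noise_sd = 0.01, seed = 1))
#> <csa_measurement> CSA = 57.71 ppm (edges -38.65 / 19.06, peak 19.06)

ser <- simulate_job_series(binding_ground_truth(4.5,
         delta_free = c(H1 = 5.29, H3 = 4.43),
         delta_bound = c(H1 = 5.39, H3 = 4.55)),
       fractions = seq(0.1, 0.9, 0.1), noise_sd_ppm = 0.002, seed = 42)
job_transform(ser)
#> <job_curve> 9 fractions, 2 resonance(s); pooled argmax F = 0.500
fit_association_constant(ser)
#> <binding_fit> log Ka = 4.389 (RSS 8.97e-05, converged)
#>   bound shifts (ppm): H1 = 5.3924, H3 = 4.5522
```

The Job maximum at F = 0.5 indicates 1:1 stoichiometry, and the simplex fit
recovers the ground-truth log Ka = 4.5 to within the noise-limited
precision (about ±0.1 at this noise level and resonance count).

A full synthetic reproduction — four membrane systems at two temperatures,
profiles, relative-fluidity tables, CSA, transitions, binding — is
orchestrated by `run_report(out_dir, seed)`, or from a shell via the thin
wrapper `inst/cli/spinorder.R` (subcommands `simulate`, `depake`, `csa`,
`esr`, `binding`, `transition`, `report`).

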