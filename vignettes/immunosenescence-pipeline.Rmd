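---
title: "Quantifying immunosenescence: qPCR output markers and CDR3 spectratype perturbation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying immunosenescence: qPCR output markers and CDR3 spectratype perturbation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunosen)
```

## The scientific problem

Immunosenescence — the ageing of the immune system — is characterized by
three measurable features: reduced production of new lymphocytes, shortening
of telomeres in peripheral blood cells, and loss of T-cell receptor (TR)
repertoire diversity. In people who acquired HIV perinatally and have now
lived with the infection for decades, the balance of these markers against
age-matched non-perinatally infected patients and healthy controls tells us
whether lifelong infection under antiretroviral therapy accelerates immune
ageing. This package implements the complete analysis layer for such a
cohort study:

* **Thymic and bone-marrow output** — TREC (T-cell receptor excision circle)
  and KREC (kappa-deleting recombination excision circle) copies per ml of
  blood, from a duplex real-time PCR.
* **Relative telomere length** — the T/S ratio from a monochrome multiplex
  qPCR: nanograms of a reference DNA matching the sample's telomere signal
  (T) divided by nanograms matching its beta-globin single-copy-gene signal
  (S).
* **TR repertoire diversity** — CDR3 spectratyping of 23 TRBV subgroups:
  each subgroup's CDR3 fragment-length distribution is classified into four
  clonality categories and scored for perturbation against a
  healthy-control reference.

Because the clinical datasets of such studies are not public, the package
ships a synthetic cohort generator with known ground truth that emulates the
study design; every pipeline stage is validated end to end against that
truth.

## qPCR quantification

### Standard curves and efficiency

A standard curve is an ordinary least-squares fit of the quantification
cycle Cq on `log10(quantity)` over a serial dilution. The telomere /
beta-globin assay uses eight 1:2 dilutions of a reference DNA from 21 ng per
well down to `r min(standard_ladder())` ng; the excision-circle assay uses a
6-point 10-fold plasmid ladder from 1e6 copies (the duplex assay's usual
standard design). Amplification efficiency follows from the slope:

$$E = 100\,(10^{-1/\text{slope}} - 1)\ \%$$

so a slope of −3.3219 cycles per log10 is perfect doubling (100%). Slopes of
−3.05 and −3.22 correspond to `r round(efficiency_from_slope(-3.05), 1)`%
and `r round(efficiency_from_slope(-3.22), 1)`%. Unknowns are interpolated
as `10^((Cq - intercept)/slope)`; results more than one log10 outside the
standards are flagged as extrapolated.

### Replicate quality control

Samples run in triplicate. The coefficient of variation is computed on the
*interpolated quantities* (not on Cq) with the sample (n−1) standard
deviation, and a replicate group is rejected strictly when CV > 15% —
equality passes. Published descriptions of this assay state the CV rule at
assay level only, so the well-level basis (quantities, sample SD) is an
explicit design choice here. The replicate summary statistic is the
**median** of the interpolated quantities, robust to a single aberrant well;
the alternative (mean) is not exposed because the median is exact on
noiseless data and strictly safer with outliers. A no-template control
amplifying below Cq 38 (configurable) aborts the plate as contaminated.

T/S requires both targets' triplicates to pass QC; otherwise the result is
flagged invalid rather than raising an error, since a failed sample is an
expected event on a real plate. Excision-circle results scale copies per
reaction to blood concentration:

$$\text{copies/ml} = \text{copies/reaction} \times
  \frac{\text{cells/ml}}{\text{cells/reaction}}$$

with both normalization factors required explicitly (defaults 2e6 cells/ml,
1e5 cells per reaction).

## Spectratype analysis

### From peaks to distributions

GeneMapper-style peak tables (sample, TRBV subgroup, fragment size, height,
area) are validated against the closed 23-subgroup IMGT vocabulary. Within a
subgroup, peak areas below 2% of the subgroup total (configurable) are
treated as undetectable — fragment-analysis "detectability" is
instrument-dependent, so the floor is an explicit parameter — and the rest
are renormalized to a relative-area distribution over the 3-nt in-frame
ladder. A subgroup whose total area is below a floor is *undetected*: it is
excluded from classification, scoring and category denominators, never
counted as zero.

### Clonality classification

Each detected distribution falls into one of four categories: normal
(polyclonal), shifted, restricted, or mono/oligoclonal. The published
category definitions (at least 7 peaks with a Gaussian shape, etc.) leave
three quantities unoperationalized; the decision rule here is, in order:

1. **mono/oligoclonal** if the largest peak holds ≥ 40% of the area or the
   two largest hold ≥ 60% — dominance is tested first so a 7-peak profile
   with one towering peak is still called clonal;
2. **restricted** if fewer than 7 detectable peaks remain;
3. **normal** if a 3-parameter discrete Gaussian (amplitude, mean, width),
   fitted by least squares over the ladder, reaches R² ≥ 0.90; otherwise
   **shifted**.

All three thresholds (0.40/0.60 dominance, 7 peaks, 0.90 R²) are exposed as
arguments. The Gaussian fit is solved on a cached (mean, width) grid with
the amplitude profiled out in closed form, then refined by Nelder–Mead; the
grid step (0.05 ladder positions) makes the grid-only score accurate to
<0.001 R², and the refinement removes even that. Classification is
deterministic and invariant to the order of the input peak records.

### Perturbation: generalized Hamming distance

A subject's per-subgroup perturbation against a reference mean distribution
is half the summed absolute difference of the relative-area vectors, in
percent:

$$D = \frac{100}{2}\sum_i |p_i - r_i|$$

This is the total-variation distance scaled so identical distributions score
0 and disjoint ones 100. It is symmetric and a true metric on the shared
ladder; distributions on different ladders are aligned on the union of
positions with absent positions counted as zero.

The reference is built from 12 healthy controls (the study's reference-group
size): a seeded random draw from the HC pool, since the original membership
is unknowable. Per subgroup, the reference mean is the average of the
members' distributions; the flagging statistics (per-subgroup HC mean and SD
of D) are computed by scoring **every** HC — reference members included,
matching the study's figure in which HC columns also carry flags. A
subgroup is flagged `over3sd` when D strictly exceeds mean + 3SD, else
`over2sd` when it strictly exceeds mean + 2SD ("higher than" is read as
strict). A subject's global perturbation is the mean D over detected
subgroups, with the detected count reported.

Category proportions are pooled over (subject × detected TRBV) units —
whether the published proportions were pooled or per-subject averages is not
stated, so the per-subject values are returned as well and either summary
can be derived.

## Statistical layer

Group comparisons use the Kruskal–Wallis H test with tie correction; when
the omnibus p ≤ α (default 0.05) and more than two groups are present,
Dunn's pairwise z-tests on the pooled ranks follow, with Bonferroni
adjustment — the publication workflow says only "corrected", and Bonferroni
is the correction its cited software applies; the method name is recorded in
the output. With exactly two groups the omnibus p is itself the reported
comparison. When every observation is tied the omnibus is reported as
H = 0, p = 1 rather than NaN. Pearson correlations are computed per stratum
(group, gender) with a zero-variance guard. Cohort summary tables report
medians with IQR under the (n+1) percentile convention (R's quantile type
6): on the toy age sample (24, 27, 29) this reproduces the conventional
"27 (24–29)" display, which linear type-7 quantiles would not. Between-group
p-values in the summary table use the unpaired t-test for continuous and
Fisher's exact test for categorical variables, as such cohort tables
conventionally do.

## The synthetic cohort generator

The generator is the package's validation instrument; its defaults *are* the
study conditions:

* **Groups**: 21 perinatally infected (pHIVy), 19 non-perinatally infected
  (npHIVy), 40 healthy controls (HC).
* **Clinical marginals**: medians and IQRs of age, CD4/CD8 counts and
  percentages per group as in the study's cohort table. Cell counts, T/S and
  excision-circle copies are lognormal (positive, right-skewed); ages and
  percentages are normal (clamped). Median/IQR convert to distribution
  parameters through the normal quantile at 0.75.
* **Markers**: TREC and KREC log10 copies/ml identical across groups (mean
  3.7 and 3.9, SD 0.35 — mid-thousands of copies/ml, the expected range in
  young adults), so any detected group difference is a false positive; true
  T/S medians 0.80/0.80/1.00 with SD 0.06 log10 (≈14% CV), a two-SD shift
  between patients and controls.
* **Clonality-category mixes** per group reproducing the published pooled
  proportions (HC: 27.5% normal, 35.5% restricted, 2.9% mono/oligoclonal,
  remainder shifted; patient groups analogously). The published table leaves
  two entries unstated (pHIVy mono/oligoclonal, npHIVy restricted); they are
  set to 6.0% and 39.8% so each row sums to 1 while preserving every stated
  value.
* **Correlations**: a Gaussian copula couples the per-subject latent
  variables. Targets are *Pearson correlations on the measurement scale*
  (copies/ml, cells/µl): because skewed marginals attenuate latent
  correlations, each pairwise latent correlation is calibrated numerically
  (fixed-seed Monte-Carlo inversion) so the realized r hits the target — a
  latent 0.75 would otherwise come out near 0.70 against a lognormal CD4
  margin. Targets on the CD4/CD8 ratio are mapped onto the CD4/CD8 latents
  through the log-ratio contrast (the ratio of two lognormals is lognormal).
  Unspecified latent entries are completed to the positive-definite cone by
  a penalized least-squares completion that holds every target exactly and
  moves free entries minimally; jointly infeasible targets raise a
  configuration error naming the offending pair. Default targets carry the
  study's reported values (TREC–CD4 0.75, T/S–CD4 0.75, perturbation
  propensity–CD4/CD8 −0.81 and –CD4 −0.63, all in pHIVy) plus biologically
  motivated structural pairs (count–percentage 0.7 within lineage, TREC–KREC
  0.7, and diversity-tracking-output couplings in pHIVy).
* **Repertoire ground truth**: each (subject, TRBV) draws its clonality
  class from the group mix — so group-level category proportions are exact
  in expectation — and a per-subject *perturbation propensity* (Beta(3,2)
  in the HIV groups, Beta(2,3) in HC) drives how far that subject's profiles
  sit from the canonical polyclonal shape. The propensity acts through a
  positional shift of each profile along the CDR3 ladder (alternating sign
  across subgroups, magnitude `shift_max × propensity`, default 0.9
  positions, amplified ×3.3 for the integer-positioned restricted blocks and
  dominant peaks) and through the multiplicative noise amplitude
  (0.6–1.4×). The shift was chosen as the coupling mechanism because the
  Hamming distance is highly sensitive to ladder position while every
  classification diagnostic (peak count, dominance shares, Gaussian family
  fit) is position-invariant: perturbation rises monotonically with
  propensity without disturbing the configured class mixes. At the chosen
  default the realized correlation between true global perturbation and the
  CD4/CD8 ratio in pHIVy is about −0.5 — an attenuated image of the −0.81
  latent target, because the class draws add position-independent variance;
  pushing the shift further starts to clip against the 8-position ladder and
  to erode classification accuracy, so the default stays at 0.9.
* **Determinism**: one master seed; every subject draws from a
  counter-based substream keyed by (group index, subject index), so
  enlarging one group never perturbs any other subject's data, and a fixed
  configuration reproduces byte-identical output files.

### Archetype shapes

The four class archetypes are free design choices (the study publishes only
group-level summaries): normal is a discretized Gaussian over eight 3-nt
ladder positions (mean jitter ±0.3, width 1.8–2.1 — wide enough that edge
peaks stay above the 2% detectability floor); shifted is a balanced bimodal
mixture (centers near positions 2.5 and 6, width 0.95) that no single
Gaussian fits above R² 0.90; restricted is a centered block of 4–6 peaks
with weights in [0.7, 1] of the maximum (bounded so the dominance thresholds
are never tripped); mono/oligoclonal puts 45–80% of the area on one peak or
65–88% on two adjacent peaks over a faint polyclonal background. With these
defaults the classifier recovers the generating labels on >99% of profiles,
with the residual confusion confined to normal↔shifted, which share the
≥7-peak structure and differ only in shape.

### What the generator does *not* emulate

Raw electropherogram signal (stutter, pull-up, baseline), PCR amplification
bias across subgroups, subgroup-specific ladder offsets beyond a fixed size
shift, real inter-assay drift, longitudinal trajectories, and the fine
structure of real CDR3 length distributions (real polyclonal profiles are
smoother and their perturbations smaller — simulated global perturbation
medians sit near 20–27% versus 10–15% in real cohorts). Passing the
validation suite therefore demonstrates that the *arithmetic and inference
machinery* is correct and recovers known truth, not that the generator's
profiles are photorealistic spectratypes.

## Validation design and problem sizes

The test suite validates each stage against independent oracles:
closed-form OLS for curve fitting, brute-force total-variation sums for the
perturbation score (1,000 random pairs to 1e-9), direct CV computation for
replicate QC, hand rank-sum arithmetic for Kruskal–Wallis, hypergeometric
enumeration for Fisher's exact test, and noiseless round-trips for all qPCR
quantities. Cohort-level behavior is checked by simulation: classification
recovery on 1,000 profiles per class; copula correlation recovery at
n = 2000 (±0.05); and the full pipeline on 100 independently seeded default
cohorts, where the study's qualitative pattern — TREC and KREC
non-significant, T/S and global perturbation significant at α = 0.05 — must
appear in at least 90% of seeds. With two truly null markers tested at
α = 0.05 the expected joint false-positive-free rate is ≈0.93 (TREC and KREC
are correlated, which raises it above the independent 0.90), so this
criterion operates close to its design margin by construction.

## Known limitations

* Single-plate consolidation only: samples measured on several runs are not
  reconciled against an inter-assay CV; the first accepted run would be
  used.
* The Gaussian-fit R² threshold, dominance thresholds and detectability
  floor are calibrated to the synthetic archetypes; real GeneMapper exports
  may need different settings (all are exposed).
* Absolute perturbation levels and the realized perturbation–covariate
  correlation are attenuated relative to the real study, as discussed above.
* The copula calibration targets pairwise Pearson correlations; higher-order
  dependence (tail behavior, nonlinearity) is not controlled.
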