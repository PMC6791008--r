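# immunosen

Immunosenescence — reduced output of new lymphocytes, telomere shortening
and loss of T-cell receptor (TR) repertoire diversity — is a central question
in people who acquired HIV perinatally and have now lived with the infection
for decades. Studies of such cohorts compare three marker families across
perinatally infected young adults (pHIVy), age-matched non-perinatally
infected patients (npHIVy) and healthy controls (HC). This package
implements that entire analysis layer for R users working with qPCR plate
exports and fragment-analysis peak tables, plus a ground-truth synthetic
cohort generator so the whole pipeline can be validated end to end without
access to patient data.

## What it computes

**Thymic and bone-marrow output.** TREC and KREC copies per ml of blood from
duplex real-time PCR: standard-curve fitting (OLS of Cq on log10 quantity),
efficiency `100·(10^(−1/slope) − 1)`, triplicate CV quality control
(quantities rejected strictly above 15% CV), and scaling of copies per
reaction by cells/ml ÷ cells/reaction.

**Relative telomere length.** The monochrome-multiplex qPCR T/S ratio: T
(ng of reference DNA matching the sample's telomere signal) over S (ng
matching its beta-globin single-copy-gene signal), each the median of
accepted triplicate interpolations on its own standard curve — eight 1:2
dilutions from 21 ng down to 0.16 ng per well.

**TR repertoire diversity.** CDR3 spectratyping of the 23 IMGT TRBV
subgroups: each subgroup's fragment-length distribution is classified as
normal (≥7 peaks, Gaussian shape), shifted (≥7 peaks, non-Gaussian),
restricted (<7 peaks) or mono/oligoclonal (one or two dominant peaks), and
scored for perturbation with the generalized Hamming distance

    D = ½ Σᵢ |pᵢ − rᵢ| × 100

against the mean distribution of a 12-HC reference group, with per-subgroup
flags above the HC mean+2SD and mean+3SD.

**Cohort statistics.** Kruskal–Wallis H with tie correction, Dunn's post-hoc
z-tests (Bonferroni-corrected) gated on the omnibus test, Pearson
correlations per stratum, and Table-1 style summaries (median/IQR, Fisher
exact and unpaired t tests).

## Worked example

The numbered scripts under `analysis/` run the complete study on a simulated
cohort (21 pHIVy / 19 npHIVy / 40 HC, seed 1):

```sh
Rscript analysis/01_simulate.R     # writes results/sim/ (cohort, peaks, plates)
Rscript analysis/02_qpcr.R         # T/S and TREC/KREC per subject
Rscript analysis/03_spectratype.R  # classification, reference, perturbation
Rscript analysis/04_stats.R        # group comparisons and correlations
Rscript analysis/05_figures.R      # figures
```

`04_stats.R` prints, among others:

```
Kruskal-Wallis [trec_copies_per_ml]: H = 1.285 (df 2), p = 0.5261
Kruskal-Wallis [krec_copies_per_ml]: H = 1.561 (df 2), p = 0.4582

Kruskal-Wallis [ts_ratio]: H = 32.733 (df 2), p = 7.802e-08
  HC       n=40  median 0.9884 (IQR 0.876-1.14)
  npHIVy   n=19  median 0.7865 (IQR 0.7042-0.8685)
  pHIVy    n=21  median 0.7757 (IQR 0.7247-0.8748)
  Dunn HC vs npHIVy: z = 4.736, adj. p = 6.53e-06
  Dunn HC vs pHIVy: z = 4.603, adj. p = 1.248e-05

Kruskal-Wallis [global_perturbation]: H = 40.597 (df 2), p = 1.53e-09
  HC       n=40  median 21.01 (IQR 18.57-23.88)
  npHIVy   n=19  median 28.9 (IQR 23.87-30.57)
  pHIVy    n=21  median 27.11 (IQR 25.36-31.1)

Correlations in the perinatal group (n = 21):
  TREC ~ CD4                 r =  0.778   p = 3.3e-05
  T/S ~ CD4                  r =  0.743   p = 1.1e-04
  perturbation ~ CD4/CD8     r = -0.364   p = 0.105
```

Reading: thymic (TREC) and bone-marrow (KREC) output do not differ between
groups, while telomere length and repertoire perturbation separate both HIV
groups from healthy controls — the generator's truth, recovered by the
pipeline. In the perinatal group, TREC and T/S track the CD4 count (the
generator's copula targets both at r = 0.75); the perturbation–CD4/CD8
correlation is induced at latent level −0.81 but is attenuated in the
realized repertoires (about −0.5 on average, and noisy at n = 21 — here
−0.36) because class composition adds perturbation variance unrelated to the
clinical covariates; see the methods vignette.

## Package layout

- `R/` — qPCR quantification, spectratype analysis, cohort statistics,
  synthetic cohort generator, end-to-end pipeline.
- `analysis/` — numbered driver scripts (the study workflow).
- `tests/testthat/` — oracle-based unit and property tests plus the
  end-to-end validation suite.
- `vignettes/immunosenescence-pipeline.Rmd` — the methods vignette: model
  assumptions, thresholds and their defaults, generator design, numerical
  choices and known limitations.
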