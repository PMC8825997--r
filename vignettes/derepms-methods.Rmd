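---
title: "Methods: dereplication and chemometric profiling with derepms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dereplication and chemometric profiling with derepms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(derepms)
```

## The problem

Crude extracts of cultured *Streptomyces* isolates contain complex mixtures
of secondary metabolites. Before committing to isolation work, a natural-
products laboratory wants to know (i) which constituents are already-known
compounds (*dereplication*), (ii) how the chemical profiles of a panel of
extracts relate to one another (*chemometrics*), and (iii) how the extracts'
cytotoxic potencies compare (*bioactivity*). `derepms` implements this
workflow for LC-HRMS peak lists acquired in positive and negative
electrospray mode.

The ingestion boundary is the finished peak list (one detected ion per row:
m/z, retention time, intensity). Chromatographic peak picking from raw
profile data is deliberately out of scope; centroided mzML can be ingested
through the optional `mzR` reader, and aligned-table exports from common
peak-picking tools are parsed directly.

## Ion annotation

An ion of measured m/z and a registered adduct imply a neutral monoisotopic
mass:

$$M = m/z \cdot |z| - \Delta_{\text{adduct}}$$

The default registry contains the singly charged protonated `[M+H]+`
(shift $+1.00728$ Da) and deprotonated `[M-H]-` (shift $-1.00728$ Da)
species — the only adducts assumed by default because they dominate
small-molecule electrospray spectra; other adducts can be registered by the
caller. The proton constant is the electron-corrected proton mass, which
reproduces published molecular-weight tables computed the same way at
4-decimal rounding.

**Alignment.** Same-polarity ions are clustered across samples greedily:
the most intense unassigned ion seeds a cluster that absorbs everything
within `ppm_tol` (default 5 ppm, typical Orbitrap mass accuracy with
margin) and `rt_tol` (default 0.1 min). Because per-sample mass jitter can
span more than the tolerance between the extreme ions of one compound, a
second pass merges any cluster centroids that still fall within the
tolerances, iterated to a fixed point. The output clusters are therefore
pairwise separated, which makes alignment exactly idempotent. Cluster m/z
and retention time are intensity-weighted means; ties are broken
deterministically (intensity, then m/z, then retention time).

**Polarity merging.** Features from the two modes whose neutral masses
agree within `ppm_tol` and retention times within `rt_tol` merge into one
`both_modes` feature. Pairing is greedy best-first on absolute ppm
discrepancy with ties broken by earlier retention time; each feature merges
at most once, intensities are summed per sample, and the merged mass is the
intensity-weighted mean. Total intensity is conserved by construction.

## Molecular-formula enumeration

Candidate elemental compositions for a neutral mass are enumerated
exhaustively over an integer box (defaults C 0–60, H 0–100, N 0–10, O 0–25,
P 0–3, S 0–3, wide enough for microbial secondary metabolites beyond
1 kDa including phosphorus-bearing ones). The non-hydrogen elements are
swept as a pruned grid, heaviest element first so the mass bound bites
early, and the hydrogen count is solved arithmetically from the mass
remainder; this is exhaustive over the box and refuses boxes implying more
than $10^8$ combinations. Candidates within the ppm tolerance (default
5 ppm) are filtered on RDBE

$$\mathrm{RDBE} = C - \tfrac{H}{2} + \tfrac{N+P}{2} + 1 \in [0, 40]$$

and annotated with the nitrogen rule (integer RDBE for an even-electron
neutral). Nitrogen-rule *filtering* is off by default: discarding
candidates on a rule the source data may violate is worse than annotating.
Output order is fully deterministic: ascending |ppm error|, then fewer
atoms, then lexicographic Hill string, ranks consecutive from 1.

## Dereplication

A feature hits a library compound when its neutral mass is within `tol_ppm`
(default 5 ppm; surfaced prominently because any database-matching
tolerance is a policy choice) of the compound's formula-derived
monoisotopic mass. Matching is on neutral mass only: retention times are
not comparable across laboratories and are carried in reports for human
inspection. All isobaric hits are reported, sorted by |ppm| with
alphabetical ties — mass spectrometry alone cannot distinguish compounds
with the same formula, and forcing a unique assignment would fabricate
certainty. A source-organism text filter (`filter_hits_by_source`)
reproduces the secondary screen of checking whether hits are of
actinobacterial origin.

The bundled 40-record mini-library of *Streptomyces* secondary metabolites
serves both as the default match target and as the seed compound set of the
simulator; any user library with `name` and `formula` columns works the
same way. One bundled record (row 39) carries an ion/MW pair that is
internally inconsistent with the adduct arithmetic (its m/z duplicates a
negative-mode record under a positive-mode label); it is kept verbatim and
flagged in tests rather than silently corrected.

## Chemometrics

* **Pareto scaling** (mean-centre, divide by $\sqrt{sd}$) is the default
  normalisation for MS intensity matrices: it damps the dominance of
  high-intensity metabolites without erasing magnitude information.
  Zero-variance features map to zero and are flagged.
* **Missing values** (a feature absent from a sample) are imputed as half
  the matrix-wide minimum positive intensity before scaling, the common
  stand-in for values below the detection limit.
* **PCA** is computed by singular value decomposition of the centred
  matrix. $R^2$ is the cumulative explained-variance fraction. $Q^2$ is
  estimated by leave-one-out cross-validation: refit without each sample,
  project the held-out sample on the training loadings, and accumulate
  PRESS; $Q^2 = 1 - \mathrm{PRESS}/\mathrm{TSS}$, cumulative over
  components. The conventional reading applies: $Q^2 > 0.5$ indicates a
  predictive model, white noise scores near zero. The estimator is stated
  explicitly because "$R^2$/$Q^2$" alone underdetermines the scheme.
* **PLS-DA** fits the scaled matrix against the centred one-hot class
  matrix by NIPALS with deflation of both blocks. Sparsity
  (`keep_per_component`) truncates each weight vector to its
  largest-magnitude entries before normalisation; the default keeps all
  features (plain PLS-DA) since a sparsity level is another policy choice
  best made explicitly. **VIP** follows
  $\mathrm{VIP}_j = \sqrt{p \sum_a \mathrm{SSY}_a w_{ja}^2 / \sum_a
  \mathrm{SSY}_a}$; with unit-norm weight vectors the mean of
  $\mathrm{VIP}^2$ is exactly 1, a useful built-in self-check.
* **HCA** wraps Euclidean distances and Ward linkage by default (the usual
  pairing in metabolomics practice; average/complete/single are
  available). Trees are standard `hclust` structures and export to Newick.
* **ANOVA feature ranking** computes a per-feature one-way F-test and
  returns the `n` smallest p-values (ties by larger F), with Fisher's LSD
  pairwise p-values attached as post hoc context only — they never affect
  the ranking. With fewer than 2 samples in a group the ranking falls back
  to feature variance, with a warning. For simulated lognormal intensities
  the univariate ranking is run on log-intensities (the planted effects are
  defined in log-sd units and raw-scale F statistics on heavy-tailed data
  are erratic); the multivariate analyses use Pareto scaling on the raw
  intensities.
* Every fit is deterministic: loadings and weight vectors are sign-fixed so
  their largest-magnitude element is positive, and all tie-breaks are
  stated. No fitting step consumes random numbers.

## Bioactivity

MTT viability uses background-corrected absorbances
($A_{570} - A_{690}$ per well; the assay protocol's mixed mention of a
450 nm reading is resolved in favour of the 690 nm background channel) and
the blank-corrected control ratio
$100 (A_\text{well} - A_\text{blank}) / (A_\text{control} -
A_\text{blank})$, clipped below at zero with a flag. IC50 comes from a
four-parameter logistic fit on log10 concentration by Levenberg–Marquardt
least squares, with the top asymptote capped at 120% and the bottom at
−5%: a 5-dose series is minimal for four free parameters and unconstrained
asymptotes make such fits unstable. If the optimiser fails, the estimate
falls back to log-linear interpolation between the doses bracketing 50%,
and the method used is recorded. Estimates outside the tested range, or
from curves that never cross 50%, are flagged extrapolated. IC50s are
reported as mean ± sd over replicate experiments, and cancer-vs-normal
comparisons use the two-sample pooled-variance (Student's) t-test with the
conventional tiers (* p < 0.05, ** p < 0.01, *** p < 0.001).

## The synthetic-data generator

No raw instrument data accompany the study design this package targets, so
the generator emulates its statistical structure and every stage is tested
against planted ground truth:

* **Study layout**: five extracts, both ionization modes. The 40 library
  compounds split into a 16-compound core present everywhere, 8 compounds
  for each of two chemically similar pairs, and 8 unique to one
  deliberately distinct outlier extract. 160 decoy features (masses kept
  ≥ 20 ppm from every library mass and from each other) split 50% unique
  to the outlier, 30% shared by all, 10% per pair.
* **Noise model**: Gaussian mass error of sd 2 ppm (Orbitrap-class),
  retention jitter of sd 0.02 min around a per-compound retention time,
  and log-normal intensities with a per-compound base level (meanlog 12,
  sdlog 1) plus a per-extract deviation (sdlog 0.5) — abundance is largely
  compound-specific, which is what makes shared metabolites carry
  similarity signal between extracts. Planted presence is thinned at
  dropout rate 0.1; the emitted ground truth reflects what was written.
* **Grouped matrices** for the supervised analyses: 5 groups × 3
  replicates × 200 features, 10 discriminatory features shifted by 3
  log-sd in their designated group.
* **Dose-response plates**: 4PL viabilities at the five-dose series 100,
  25, 6.3, 1.6, 0.4 µg/ml, three technical wells per dose and three
  replicate experiments, converted to 570/690 nm absorbance pairs with
  additive noise; untreated-control and medium-blank wells included.

All generators are pure functions of their seed (the caller's RNG stream is
restored afterwards).

What the simulator does **not** emulate: isotope envelopes, in-source
fragments, multiply charged species, chromatographic peak shapes,
correlated (drift-like) mass error, or realistic retention behaviour.
Passing tests therefore demonstrate that the pipeline's logic is correct
under the stated statistical model, not that it is robust to every artefact
of real instrument data.

## Problem sizes and verification

The test-suite designs are sized for quick, repeated runs: 5 extracts ×
~200 features per mode for the closed loop; 15 × 200 for the supervised
analyses; 50 random masses in 100–700 Da for the enumeration cross-check
against a naive nested-loop oracle; 1000 replicates for the t-test
calibration; 5 seeded simulations for the IC50 recovery error. The
independent oracles (nested-loop enumeration, covariance
eigendecomposition, hand-traced linkage on a 3-4-5 triangle, textbook
t-test values, a minimal separate NIPALS, and `mixOmics` as an external
cross-check) live in the test code, separate from the implementation paths
they verify.

## Known limitations

* Dereplication by neutral mass alone cannot resolve isobars; all are
  reported.
* The Q2 scheme is one of several in use; absolute values from other
  software will differ even when the qualitative conclusion agrees.
* The 4PL fit needs viabilities that approach both asymptotes; 5-dose
  curves far from 50% yield extrapolated, low-confidence IC50s.
* The greedy aligner assumes features are separated by more than the
  tolerances; genuinely overlapping features (co-eluting isobars within a
  few ppm) merge.
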