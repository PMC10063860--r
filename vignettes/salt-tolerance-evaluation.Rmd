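---
title: "Methods: composite salt-tolerance evaluation of rice germplasm panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite salt-tolerance evaluation of rice germplasm panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltpanel)
```

## The evaluation model

`saltpanel` scores seedling-stage salt tolerance of a germplasm panel
from a battery of indices measured under control (CK) and salt stress
(SST, 125 mmol L⁻¹ NaCl). The 13 default indices are the visual
salt-tolerance score (STS, 1–9 scale, higher = less injured), relative
SPAD chlorophyll content (RSPAD, % of the same accession's control),
five chlorophyll-fluorescence parameters (Fm, Fv/Fm, Y, NPQ, ETR) and
shoot/root Na⁺ and K⁺ contents (mg g⁻¹ DW) with their ratios.

The composite score is built in five steps:

1. **Index matrix.** Replicate means per accession and index at one
   treatment/timepoint slice (`build_index_matrix()`). Assembly is
   complete-case: a missing cell aborts with the gap named, because
   silent imputation would quietly distort the ranking.
2. **PCA.** The indices mix scales (scores, %, ratios, mg g⁻¹), so the
   PCA is run on the correlation matrix: columns are z-scored with the
   n−1 SD and the correlation matrix eigen-decomposed. Eigenvalues then
   sum to the number of indices, loadings are eigenvectors × √λ (index —
   component correlations), and scores are the z-scored data on the unit
   eigenvectors. Components with eigenvalue > 1 are retained (Kaiser
   rule, strict inequality, floor of one so the score is always
   defined).
3. **Membership functions.** Per retained component, scores are min-max
   mapped to [0, 1]: u = (x − min)/(max − min). A constant score column
   is a degenerate-membership error rather than an arbitrary constant.
4. **Weights.** wⱼ = Pⱼ / ΣPⱼ over the retained components' variance
   proportions.
5. **D value and ranking.** D = Σ uⱼ wⱼ per accession, ranked
   descending; ties break lexicographically by accession name (flagged
   in the output). The top and bottom accessions are returned as the
   typical tolerant/sensitive picks.

Assumptions worth stating: the membership step assumes the retained
components are oriented so that "more" means "better" on the dominant
component. Eigenvector sign is solver-arbitrary, so each component is
flipped to make its largest-|loading| entry positive; no further
direction correction is applied to negatively loaded components, and
memberships are computed on the raw scores. This reproduces the
published convention, and it works because in practice the strongly
separated, positively directed indices (STS, RSPAD, fluorescence)
dominate PC1. If a panel were dominated by inversely directed indices,
PC1 — and hence D — would track sensitivity instead; the synthetic
generator's defaults are deliberately realistic on this point (see
below).

## Statistical layer

- `summarize_values()`: range and CV% = 100 × SD(n−1)/mean.
- `variance_ratio_f()`: the classical two-sample variance-ratio F,
  reported SPSS-style with the larger variance in the numerator and a
  two-sided p. This is a deliberate reading of "independent samples
  F-test" as the classical variance-ratio test (not Levene's), matching
  the one-F-one-t-per-cell presentation of screening tables; the choice
  is isolated in one function if a user prefers otherwise. When one
  sample is constant (e.g. control STS identically 9) the test is
  reported not-applicable — the dash seen in printed tables — and the t
  test is still computed against the constant.
- `independent_t()`: pooled t when the F pre-test does not reject at
  0.05, Welch otherwise (the equal-variances-assumed convention of
  classical software); stars ** p < 0.01, * p < 0.05.
- `correlation_matrix()`: Pearson r with p from the t transform on n−2
  df, stars at 0.001/0.01/0.05. The matrix stores r (not r²); r² is
  recoverable by squaring, and the sign is scientifically meaningful.
- Haplotypes: one group per distinct allele tuple, labels Hap1..HapK by
  decreasing size then first occurrence (labels are presentation only;
  tests compare partitions). Association uses one-way ANOVA followed —
  only if significant at α (protected LSD, switchable) — by pairwise
  LSD t comparisons on the ANOVA mean-square error, summarised with an
  insert-and-absorb compact letter display whose letter-sharing relation
  is property-tested to match the brute-force pairwise significance
  matrix exactly. Groups below `min_group_size = 2` are excluded and
  left unlettered: a singleton contributes no within-group variance.
- SSR dose trends: Spearman rank correlation of repeat count against the
  phenotype (asymptotic p in the presence of ties).
- qPCR: Livak comparative-Ct with configurable efficiency (default 2);
  ΔCt is computed per matched replicate, the calibrator is each
  accession's own 0 h sample per (gene, tissue), and the stratum-level
  fold is efficiency^−(mean ΔΔCt) — the geometric-mean fold, which is
  exactly 1 at the calibrator stratum. (The arithmetic mean of replicate
  folds would not be 1 there, which is why the geometric form is used
  for display; replicate-level folds are kept for the t tests, with a
  switch to testing on the ΔCt scale.)

## The synthetic panel generator

`generate_panel()` emulates only the statistical shape of the measured
tables — no photochemistry, ion-flux kinetics or regulatory dynamics.
The model:

- Each accession carries a latent tolerance in (0, 1): tolerant class
  ~ N(0.8, 0.1), sensitive ~ N(0.2, 0.1), truncated. These are free
  parameters (replicate-level variances per index are not published for
  real panels); they give clear between-class separation with realistic
  within-class spread.
- Trait value = baseline + stress effect + Gaussian replicate noise.
  Under CK the classes share one distribution. Under SST the effect
  interpolates between the sensitive-class and tolerant-class effects by
  the latent, so the latent drives every stress index coherently.
- Noise is independent Gaussian per replicate with **per-treatment SDs**
  (`sd`, `sd_stress`). A single SD per index cannot emulate real panels:
  the spread of the ionic indices under stress is roughly an order of
  magnitude larger than under control (stress means of ~60–100 mg g⁻¹
  against control means near 4), and control-scale SDs would make those
  indices separate the classes by >30σ, dominate PC1 and — under the
  sign convention above — flip D to track sensitivity. The defaults give
  the seven positively directed indices ≥3σ class separation under
  stress and the ionic indices ~1σ (their ranges overlap in real
  screens), which is what makes the D ranking recover tolerance.
  `sd_stress` defaults to `sd` when omitted.
- STS is generated by rounding and clamping a Gaussian latent to the 1–9
  integer scale; control STS (baseline 9, SD 0.15) is therefore almost
  surely constant at 9, reproducing the not-applicable F cells of
  screening tables.
- Genotypes are drawn per locus with class-specific allele frequencies;
  allele effects (for SSRs, an additive effect per repeat above the
  smallest configured count) shift STS under stress before
  rounding. The default SSR effect is −0.5 STS per AGA repeat, which
  keeps the sensitive class off the floor of the 1–9 scale.
- Ct records: reference-gene Ct ~ N(20, 0.15) cycles; target ΔCt =
  baseline − (stress induction + class effect × latent) at post-0 h
  timepoints.
- One global seed spawns four independent substreams (latents, traits,
  genotypes, Ct), so extending one table never perturbs another;
  identical (config, seed) gives identical panels.

What passing tests on synthetic panels do **not** show about real data:
real replicate noise is not Gaussian or homoscedastic within treatment,
indices are measured on partially overlapping plants (correlated errors
the generator omits beyond the shared latent), allele effects need not
be additive, and expression dynamics are far richer than a step
induction. The generator is a test harness for the statistics, not a
biological simulator.

## Numerical choices and degenerate inputs

- Reports round to 3 decimals, matching the print precision of the
  tables the method reproduces.
- Weight normalisation is checked to 1e-6 in `d_value()`; eigenvalue /
  loading consistency to 1e-6 in the PCA and 0.01 against 3-decimal
  printed tables.
- More indices than accessions is allowed but warned about (trailing
  eigenvalues are zero).
- Zero-variance columns: hard error in PCA (the index carries no
  information and would divide by zero in z-scoring); NA-with-warning in
  the correlation matrix; not-applicable F in the variance-ratio test.
- Both-samples-constant t test returns t = 0, p = 1 rather than 0/0.
- TSV writers emit doubles with 17 significant digits so panels
  round-trip losslessly.

## Validation design

The test suite validates three distinct layers, at these problem sizes:

- **Printed-fixture arithmetic** (`reference_panel()`): weights from the
  published proportions (0.648/0.216/0.136), all 12 D values within
  ±0.001 of print, the exact 1–12 ranking, cumulative contribution
  90.254% from the printed eigenvalues over 13 indices, and per-component
  Σ(loading²) within 0.01 of the printed eigenvalues. Fixture mode
  consumes the published membership values directly, isolating the
  downstream arithmetic from the unrecoverable raw data.
- **Oracle equivalence**: F, t, Pearson p (tolerance 1e-10) and LSD
  letter relations (exact) against first-principles brute-force
  implementations on 1,000 random small instances each.
- **Monte-Carlo behaviour**: type-I error of the class contrast under a
  null generator (no class effect) over 1,000 single-index 12-accession
  panels, expected 0.05 ± 0.02; Spearman(D, latent) ≥ 0.8 in ≥95% of 100
  default 12-accession panels; and detection (ρ < 0, p < 0.05) of a −1
  STS/repeat SSR effect in ≥95% of 100 fifty-accession panels. Sizes
  were chosen to keep each study's Monte-Carlo error well below the
  margins being asserted while the whole suite runs in about a minute.

## Known limitations

- The eigenvalue-1 rule and min-max memberships are conventions, not
  optimal estimators; no rotation or parallel analysis is offered.
- Whether the published evaluation fed absolute stress-day values or
  control-relative coefficients into the PCA is not recorded for the
  non-relative indices; `build_index_matrix()` defaults to absolute
  values for the requested slice, and callers can pre-transform with
  `relative_index()` if they prefer.
- No multiple-testing correction across the descriptive test grid (the
  convention of the screening literature this package follows), and
  none across haplotype association tests beyond the protected-LSD
  gate.
- The D value inherits the sign caveat discussed above on panels whose
  variation is dominated by inversely directed indices.
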