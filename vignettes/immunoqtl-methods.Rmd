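---
title: "Mapping HLA variation onto TCR V-gene usage: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping HLA variation onto TCR V-gene usage: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunoqtl)
```

## The scientific question

T cells recognise peptide antigens presented by MHC (in humans, HLA)
molecules. The germline-encoded CDR1/CDR2 loops of the TCR β chain are fixed
by the TRBV gene segment an individual's T cells rearrange, and they touch
the conserved helices of the MHC. If particular TRBV segments pair better
with particular HLA variants, thymic selection should shift the *usage* of
TRBV genes — the proportion of a repertoire's reads assigned to each V
segment — as a function of HLA genotype. `immunoqtl` implements the
statistical machinery to test this: it treats per-individual TRBV usage
proportions as quantitative phenotypes and HLA variation, encoded as
additive dosages at three genetic levels, as the genotypes of a QTL scan.
An immunoglobulin heavy-chain (IGHV) usage family, which has no biological
reason to covary with HLA, serves as the negative control.

## Dosage encoding

Four-digit HLA genotypes (two classical alleles per locus per individual)
are translated into dosage matrices at three levels:

* **allele** — one variant per observed four-digit allele; the dosage is the
  number of copies carried (0/1/2).
* **SNP** and **amino acid** — each polymorphic position of a
  pre-built allele translation table is expanded to one variant per
  observed symbol. The expansion takes each symbol in turn as the
  *reference* and pools all others: a bi-allelic site with symbols A and C
  yields two complementary columns (genotypes AA/AC/CC count 2/1/0 on the A
  column), and a tri-allelic site yields exactly three columns. The
  expanded dosages of one site always sum to 2 per individual.

Sites monomorphic in the cohort yield no variants. Variants with minor
allele frequency below 0.05 (computed from dosage means; a MAF exactly at
the threshold is kept) are removed before testing. Missing genotypes are a
hard error — the upstream caller selects best-guess alleles, so the
pipeline never imputes silently. Amino-acid positions are used exactly as
numbered in the translation table; no renumbering is attempted, and the
compact label form `HLA-A.I97M` is accepted on input as a synonym for the
canonical `HLA-A.amino_acid.97.M`.

## The association model

For every (variant, gene) pair the scan fits ordinary least squares of the
phenotype on an intercept and the dosage; two-sided p-values come from the
t distribution with $n-2$ degrees of freedom. The implementation is a
closed-form vectorised solve, and the test suite pins it to a per-pair
`lm()` refit at $10^{-10}$ tolerance. No covariates enter by default. The
phenotype is the raw usage proportion; a `log2(u + pseudo)` view (with the
field's pseudo-usage constants, 0.01 for TRBV-like targets and $10^{-5}$
for the IGHV-like control family) is available through
`phenotype_mode = "log2"` and recorded in run metadata, because published
analyses are not always explicit about which scale entered the regression.

Multiple testing is controlled by Benjamini–Hochberg adjustment at 5% FDR,
applied *within each genetic level* across all of that level's gene ×
variant tests jointly (a per-gene scope is available via `fdr_scope`).
Genomic inflation is summarised by the genomic-control factor
$\lambda = \mathrm{median}(\chi^2_{obs}) / 0.4549364$, reported together
with a bootstrap 95% interval and the QQ coordinates at plotting positions
$(i - 0.5)/m$; the interval is always reported and any display threshold is
left to the caller, since "significant inflation" is a presentation rule,
not a statistic.

## Conditional fine-mapping

Linkage disequilibrium in the MHC is extreme — amino-acid positions are
functions of a modest number of common alleles, so whole blocks of variants
rise and fall together. To name the variants most likely to drive an
association, `conditional_scan()` runs forward stepwise conditional
regression per gene over the FDR-significant candidates: the top marginal
variant enters first; every remaining candidate is then refit with the
selected set as covariates; the best conditional p-value is admitted while
it is `< 0.05` (equality stops — the admission and stopping rules as
usually stated leave the boundary undefined, and we close it on the stop
side). Numerical choices worth knowing:

* Candidates whose residual norm after projection on the selected set falls
  below a relative tolerance of `1e-7` are excluded at that step, which
  silently absorbs the complementary coding of an already-selected site and
  any perfectly linked position.
* Ties in p-value (complementary codings have identical statistics up to
  floating-point rounding, so a relative tolerance of `1e-9` on the p-value
  defines a tie) are broken by byte-wise variant-id order, making the
  procedure fully deterministic.
* Candidates are ranked by conditional p-value at every step; signals are
  reported in entry order with their marginal, at-entry and final-joint
  p-values, so the output record is self-auditing.

Candidates are pooled across loci (an association block on one locus can be
explained away by a stronger signal on another), and the identical contract
applies at the SNP level.

## Variance explained

For each gene with signals, the fraction of usage variance attributable to
the MHC is the adjusted $R^2$,
$1 - (1 - R^2)(n-1)/(n-p-1)$, of linear models fit with the signal dosages:
one single-predictor model per signal plus the joint model, with the joint
model's overall F-test adjusted across genes by the same BH machinery.
Per-signal attribution is deliberately the *single-predictor* adjusted
$R^2$, not a sequential decomposition: for correlated signals the parts
then need not sum to the joint value (and can exceed it), which is the only
convention consistent with reporting top-signal, second-signal and
both-signal columns independently. Adjusted values can be negative in small
samples and are reported as computed. A switch to sequential attribution
would be a one-line change in `variance_partition()` and is intentionally
not exposed until someone needs it.

## Structural overlay

Contact information is consumed as pre-annotated presence/absence tables —
per solved TCR–pMHC complex, which MHC positions touch the TCR β V region
or the presented peptide. Computing contacts from 3D coordinates would
require choosing atom selections and a distance cutoff that annotation
databases have already standardised, so it is out of scope by design. The
per-position contact frequency is the fraction of a locus's complex roster
with at least one such contact (duplicate records collapse to presence;
positions contacted by one partner get an explicit 0 for the other). The
overlay pairs each position's contact frequencies with its association
strength, summarised as the minimum p across genes on a $-\log_{10}$ scale
(per-gene rows are available via `per_gene = TRUE`); positions present on
only one side are kept with `NA`, never dropped.

## The synthetic cohort generator

Real cohorts of this design are access-restricted, so the package ships a
generator that emulates the *statistical structure* the analysis assumes,
at the study's scale: 201 individuals by default; eight classical HLA loci
with the reported allele diversity (23 HLA-A, 46 HLA-B, 21 HLA-C, 28 DRB1,
16 DPB1, 4 DPA1, 14 DQB1, 15 DQA1 alleles); 48 target genes plus a 20-gene
control family.

* **Genotypes** are two i.i.d. draws per locus from the pool frequencies
  (Hardy–Weinberg), frequencies themselves drawn once from a skewed
  Dirichlet to mimic the few-common-many-rare HLA spectrum.
* **LD arises mechanistically**, not from an explicit correlation matrix:
  the synthetic translation table partitions each locus's alleles into
  residue groups per position, so positions sharing a partition are
  perfectly linked and others partially — exactly how MHC amino acids are
  correlated in real data. The default of 18 amino-acid positions per locus
  gives roughly 300 testable amino-acid dosage columns after MAF filtering
  at cohort scale, a testing burden comparable to the real encoding.
* **Usage** is compositional by construction: each gene receives a latent
  log-score `log(baseline) + sum(beta * dosage) + noise`, and an
  individual's usage row is the softmax over the genes detected in that
  individual. Dropout (default rate 0.02, emulating sporadically
  undetected genes) is applied *before* normalisation, mirroring
  proportions computed over mapped reads only, and dropped genes are
  recorded as exactly 0. Baseline proportions come from a symmetric
  Dirichlet with concentration 5. The noise standard deviation (default
  0.3 on the log scale, i.e. a realistic ~30% coefficient of variation in
  usage between individuals) is a free parameter: no published estimate of
  between-individual TRBV usage variance at fixed genotype exists to
  calibrate it against.
* **Planted truths** — effect sizes, the dropout mask and the baseline —
  are returned alongside the usage matrix so recovery can be measured, and
  `plant_phenotype()` builds phenotypes whose planted variance fractions
  are exact on the analysis scale for calibration experiments.

What the generator does *not* emulate: read-level noise, imputation
uncertainty in the HLA calls, clonal expansion, or age structure (the
umbilical-cord-blood design of the motivating setting exists precisely to
exclude the last two). A pass on synthetic data therefore demonstrates
that the statistical machinery is correct and calibrated under the model's
assumptions — not that those assumptions hold in any particular cohort.

## Problem sizes used by the test suite

The shipped experiments run at the sizes a desk machine handles comfortably
while keeping every estimate's Monte-Carlo error well inside its acceptance
band: null calibration pools 50 seeded cohorts of 200 individuals
(~200,000 tests per replicate set); recovery experiments use 100
replicates of two 3-common-allele loci (for the two-signal case, ~55
amino-acid columns of which ≥20 are linkage passengers) or one bi-allelic
locus (for the single-signal stop-rule case, where every passenger is a
perfect-linkage recoding); variance recovery uses 100 replicates per
planted fraction. The choice of few-common-allele loci for the recovery
experiments is deliberate: it reproduces the low-rank LD regime
(every amino-acid column a linear function of a handful of allele dosages)
in which conditional analysis is actually used, and class II loci of that
diversity exist (HLA-DPA1 segregates ~4 alleles in cohorts of this size).
Planted variants are chosen by `choose_planted_variants()` to have
intermediate frequency and no non-twin linkage partner above |r| = 0.75,
i.e. the planted signal is taggable in principle — the analogue of asking
fine-mapping to name a causal variant that is not perfectly shadowed.

## Known limitations

* The linear model has no covariate adjustment (none is used in the
  motivating design); a mixed-model or kinship-aware extension is out of
  scope.
* Allele-level rare variants are dropped by the MAF filter, not pooled.
* The conditional procedure is greedy forward selection with a fixed
  entry threshold; it inherits the usual caveats (no guarantees under
  severe multicollinearity beyond the explicit collinearity guard, and no
  credible-set semantics as in Bayesian fine-mapping).
* Empirical FDR statements are made under the generator's null; real
  repertoire data carry compositional and technical correlations the
  generator only partially reproduces.
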