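---
title: "Back-solved GWAS with APY inversion: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Back-solved GWAS with APY inversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apygwas)
```

## The model

Large single-step genomic evaluations predict breeding values (GEBVs) for
every genotyped animal but do not, by themselves, locate the genomic regions
driving a trait. The workflow in this package recovers that information from
the evaluation's own outputs. Under an additive model the GEBV vector
$\hat{u}$ and the SNP effect vector $a$ are linked through the centered
dosage matrix $Z$ ($z_{ij} = m_{ij} - 2p_j$): $u = Za$ and
$\mathrm{Var}(u) = Z Z' \sigma_u^2 = G\,\sigma_a^2$ under the VanRaden
scaling $G = ZZ'/k$, $k = 2\sum_j p_j(1-p_j)$. Best linear prediction of $a$
given $\hat{u}$ then yields the back-solving equation

$$\hat{a} = (1-\beta)\, b\, \frac{\sigma_u^2}{\sigma_a^2}\, Z' G_b^{-1}\hat{u},$$

where $G_b = (1-\beta)G + \beta T$ is the blended GRM ($T = I$ here) and $b$
a tuning constant. The additive variance attributed to SNP $i$ is
$\sigma_{a_i}^2 = \hat{a}_i^2\, 2 p_i (1-p_i)$, and consecutive-SNP windows
summing these variances, ranked as a percentage of $\sigma_a^2$, point at
candidate regions.

At hundreds of thousands of genotyped animals $G_b^{-1}$ is unobtainable
densely; the Algorithm for Proven and Young (APY) exploits the limited
dimensionality of $G$ (the number of independently segregating chromosome
segments) by inverting only a core block $G_{cc}$ and treating every noncore
animal recursively, with conditional variance
$m_{jj} = g_{jj} - g_{jc}' G_{cc}^{-1} g_{jc}$. `apy_matvec()` applies the
factored inverse in one core solve plus $O(n_{noncore})$ work, which is all
back-solving needs.

## Assumptions the pipeline inherits

* GEBVs are treated as fixed inputs; their reliabilities are whatever the
  upstream evaluation produced. The back-solve is linear in $\hat{u}$, so
  GEBV shrinkage propagates directly into $\hat{a}$.
* Fixed effects are assumed absorbed upstream; the only adjustment applied
  here is mean-centering (in the simulator's GBLUP).
* One shared $Z$ (one set of allele frequencies, from the post-QC panel) is
  used for all traits. Base-population frequencies are unavailable in
  practice; observed frequencies stand in for them.
* Ranking, not testing: windows are ordered by explained variance. No
  p-values and no multiple-testing correction are computed, so "top"
  windows are candidates, not significant findings.

## Tunable parameters

| Parameter | Default | Units / range | Why this default |
|---|---|---|---|
| `maf_min` | 0.05 | frequency | routine post-imputation panel QC |
| `hwe_dev_max` | 0.15 | frequency difference | heterozygote-deviation screen |
| `call_rate_min` | 0.90 | fraction | routine panel QC |
| `autosomes` | 1–29 | chromosome ids | bovine autosomes |
| `beta` | 0.05 | blending weight | standard 5% identity blend for invertibility |
| `variance_threshold` | 0.98 | fraction of Var(G) | core sizes at 98% retain GEBV accuracy while shrinking the inversion |
| `b` | 1 | unitless | no rescaling of back-solved effects |
| `sigma_u2` | $\sigma_a^2/k$ | variance | the SNP/genetic variance relation implied by the VanRaden scaling |
| window size | 175 SNPs at production scale | SNPs | ≈ 1.02 Mb at the production panel's density; see below |
| `step` | 1 | SNPs | moving windows; `step = window_size` gives a disjoint tiling |
| top selection | fraction 0.01, greedy non-overlap | — | report distinct regions rather than shifted copies of one peak |

**Window sizing from $N_e$.** In a population of effective size $N_e$ the
mean independent chromosome (Stam) segment is $1/(4N_e)$ Morgans, and eight
segments capture most QTL variance. `window_size_from_ne(196)` gives
0.00128 Morgans per segment and a span of 0.0102 Morgans = 1.02 Mb at
1 cM = 1 Mb; multiplying by a panel's SNPs/Mb converts the span to a SNP
count (about 175 SNPs at a production density of ~172 SNPs/Mb). The
analysis scripts use 25-SNP windows because the synthetic panel is ~30-fold
sparser than a production panel; the span in Mb, not the SNP count, is the
invariant quantity.

## What the simulator emulates — and what it does not

`simulate_genotypes()` produces founders by binomial sampling from per-locus
base frequencies and descendants by gene dropping in a two-generation
half/full-sib family design, so the GRM has genuine off-diagonal structure
and the APY core-selection problem is non-trivial. `simulate_truth()` plants
sparse QTL and rescales them so the realized additive variance equals
$\sigma_a^2$ exactly; `solve_gblup()` generates GEBVs with the shrinkage
structure back-solving assumes (single-trait GBLUP with a mean fixed effect
on genotyped animals only — the pedigree, multi-trait and threshold-model
machinery of production evaluations affects GEBV accuracy but not the
back-solving algebra, which consumes only $\hat{u}$, $\sigma_a^2$ and $G$).

Real data differ in ways the simulator deliberately ignores: linkage
disequilibrium decays smoothly with distance rather than arising only from
family co-segregation; allele frequencies are shaped by selection;
genotyping errors and imputation artifacts violate Hardy–Weinberg in
structured ways; and effective population size varies along the genome.
Passing tests therefore demonstrate the *algebraic and statistical
correctness* of the machinery (filters, inversion, back-solving, window
accounting, recovery of planted QTL), not calibrated discovery power on any
real cattle population.

The default study conditions used by the analysis scripts and the
recovery checks are 1,000 animals × 5,000 SNPs on 5 chromosomes, 100
families, 20 QTL, $\sigma_a^2 = 1$, $h^2 = 0.5$, 25-SNP windows, top 20 —
sizes at which every matrix is dense and a laptop reproduces the whole
study in seconds while leaving the core-selection and recursion structure
intact.

## Numerical choices

* **Core block inversion** uses a Cholesky factorization; failure raises an
  error naming the condition rather than silently regularizing.
* **Recursion variances** $m_{jj}$ must exceed $10^{-10}\max_j g_{jj}$;
  smaller values indicate a core that does not span the noncore animal's
  relationships (or a non-PD $G$) and raise an error naming the animal.
* **Missing dosages** are mean-imputed at centering ($z_{ij} = 0$), the
  convention that adds no spurious relationship signal.
* **Core sizing** uses singular values of $Z$ (squared) rather than an
  eigendecomposition of $G$, with a $10^{-12}$ guard on the cumulative
  fraction so a threshold of exactly 1.0 returns the numerical rank.
* **Ties in window ranking** are broken by (chromosome, start bp) so ranks
  are a deterministic permutation.
* **Degenerate inputs**: all-fixed panels (scale $k = 0$), all-missing SNP
  columns, windows longer than every chromosome, and empty gene sets all
  have defined behavior (error, error, warned empty table, empty table).

## Design choices that were genuinely open

* **Blending target**: identity by default. A pedigree block ($A_{22}$) is
  accepted as a supplied matrix but never required, keeping the package free
  of pedigree file handling.
* **HWE statistic**: the absolute heterozygote-frequency deviation, not an
  exact test; it is the statistic production QC software applies at this
  threshold (0.15), and it is sign-symmetric because excess and deficit both
  indicate technical problems.
* **Filter attribution order** (autosome → call rate → MAF → HWE) is fixed
  so that per-filter counts are reproducible. Because each statistic is
  computed per SNP independently, the order affects only which filter a
  doubly-failing SNP is attributed to, never the retained set.
* **Blending precedes APY**: $M_{nn}$ is computed from the blended $G$,
  since back-solving applies $\beta$ and $G_{APY}^{-1}$ together.
* **Top-window overlap policy**: step-1 moving windows overlap heavily, so
  the default report keeps the best-ranked *non-overlapping* windows
  (greedy in rank order), matching how distinct regions are tabulated;
  `keep-all` exposes the raw ranking. Both a top-fraction (1%) and a fixed
  count (20) are supported because at production scale the two differ by
  how overlapping windows were collapsed upstream.
* **Gene overlap**: any ≥ 1 bp intersection reports a gene ("located
  within" a window includes genes larger than the window); strict
  containment is available as a flag.
* **Uniform-placement baseline** for QTL recovery: the fraction of *all*
  candidate windows containing a planted QTL, which is exactly the hit
  probability of a uniformly placed window on the same map.

## Known limitations

* Dense $G$ construction bounds the package to desk scale (~10⁴ animals);
  the APY *representation* is memory-light but the GRM build is not
  out-of-core.
* Single-trait back-solving only; traits are processed independently.
* No p-values, no genomic control, no iterative SNP-weighted reweighting of
  $G$.
* The annotation stage is positional only — no ontology or pathway
  enrichment — and trusts the user's gene file coordinates.
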