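# apygwas

Genome-wide association from genomic estimated breeding values (GEBVs) in
large genotyped livestock populations, built around the Algorithm for Proven
and Young (APY). National cattle evaluations now genotype hundreds of
thousands of animals; at that scale the genomic relationship matrix **G**
cannot be inverted directly, and GWAS is run by *back-solving* per-SNP
effects from the GEBVs the evaluation already produces, using an APY
inverse of **G**. This package implements that workflow end to end for
quantitative geneticists who want to apply it — or study its behavior —
without access to proprietary evaluation data: a gene-dropping simulator
supplies genotypes, QTL, phenotypes and GBLUP GEBVs with the statistical
structure the method assumes.

## The method

1. **Marker QC.** Keep autosomal SNPs with call rate ≥ 0.90, minor allele
   frequency ≥ 0.05 and Hardy–Weinberg deviation ≤ 0.15, where the HWE
   statistic is the absolute difference between observed and expected
   heterozygote frequencies, `|het_obs − 2p(1−p)|`.
2. **GRM.** VanRaden's first method, `G = ZZᵀ / (2Σpᵢ(1−pᵢ))` with
   `Z = M − 2p` the centered dosage matrix, blended as
   `G_b = (1−β)G + βI` (β = 0.05) to guarantee invertibility.
3. **APY inverse.** A core set c is sized by the smallest number of
   eigenvalues of **G** (squared singular values of **Z**) explaining 98% of
   its variance, drawn at random, and

   ```
   G_APY⁻¹ = [ G_cc⁻¹  0 ]   [ −G_cc⁻¹ G_cn ]        [ −G_nc G_cc⁻¹  I ]
             [ 0       0 ] + [      I       ] M_nn⁻¹
   ```

   with `m_jj = g_jj − g_jcᵀ G_cc⁻¹ g_jc` for every noncore animal j. Only
   the factors are stored; products `G_APY⁻¹ v` cost one core solve plus
   work linear in the noncore count.
4. **Back-solving.** `â = (1−β) · b · (σ²ᵤ/σ²ₐ) · Zᵀ (G_APY⁻¹ û)`, with
   `σ²ᵤ = σ²ₐ / (2Σpᵢ(1−pᵢ))` by default and b = 1.
5. **Windows.** Per-SNP variance `σ²ₐᵢ = âᵢ² · 2pᵢ(1−pᵢ)` is summed over
   sliding windows of adjacent SNPs within a chromosome, expressed as a
   percentage of σ²ₐ, and ranked; the top windows (top 1%, or a fixed
   count, optionally forced non-overlapping) are retained. The window span
   is motivated by effective population size: a Stam segment averages
   `1/(4Nₑ)` Morgans and eight segments capture most QTL variance, so for
   Nₑ = 196 a window spans 0.0102 Morgans ≈ 1.02 Mb.
6. **Annotation.** Top windows are intersected with gene intervals
   (BED/GFF3) by 1-based inclusive overlap.

## Worked example

The numbered drivers under `analysis/` run the whole study on synthetic
data (1,000 animals, 5,000 SNPs, 20 QTL, h² = 0.5):

```sh
Rscript analysis/01_simulate_data.R
Rscript analysis/02_quality_control.R
Rscript analysis/03_grm_apy.R
Rscript analysis/04_backsolve_windows.R
Rscript analysis/05_annotate.R
```

which prints, stage by stage:

```
genotype_panel: 1000 animals x 5000 SNPs on 5 chromosome(s), 0.999% missing
truth: 20 QTL, var(true_bv) = 1.0000, sigma_e2 = 1.000
GBLUP GEBVs: cor(gebv, true_bv) = 0.800
qc_report: 5000 SNPs in, 4685 retained
  removed: autosome=0, call_rate=0, maf=315, hwe=0
grm: 1000 x 1000, blended (beta = 0.05), mean diag = 0.9863
core size at 98% variance: 843 of 1000 animals (84.3%)
APY vs dense inverse on a random vector: rel. error 0.074 (core) / 0.135 (all)
window_size_spec: Ne = 196 -> Stam segment 0.00128 Morgans; 8 segments span 0.0102 Morgans = 1.02 Mb
4565 windows scanned; top 20 non-overlapping explain 1.979% of sigma_a2
top windows containing a true QTL: 8 of 20
```

Reading the output: the simulator hits its variance targets exactly by
construction; GBLUP GEBVs correlate 0.80 with true breeding values at
h² = 0.5; QC removes the SNPs simulated below the MAF threshold; the APY
core sized at 98% variance covers 84% of animals at this small scale (the
fraction shrinks with population size, which is the algorithm's point); the
Nₑ arithmetic reproduces the analytic window-sizing numbers; and 8 of the
20 top non-overlapping 25-SNP windows contain one of the 20 simulated QTL —
far above the ≈10% hit rate a uniformly placed window achieves. Each stage
writes TSV/JSON artifacts under `results/`. The same flow is available as a
single call, `run_pipeline(config)`, driven by a YAML/JSON config.

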