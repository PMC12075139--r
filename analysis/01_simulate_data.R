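#!/usr/bin/env Rscript
# Stage 1: build the synthetic study population.
#
# Emulates a genotyped beef-cattle evaluation at desk scale: 1,000 animals in
# 100 half/full-sib families genotyped at 5,000 SNPs on 5 chromosomes, a
# polygenic-but-sparse architecture of 20 QTL carrying additive variance
# sigma_a2 = 1 at heritability 0.5, and GEBVs from a GBLUP solve on the
# blended genomic relationship matrix so that back-solving sees realistic
# shrinkage. All downstream stages read the TSVs written here.

suppressPackageStartupMessages(library(apygwas))

seed <- 20260101L
outdir <- "results/data"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

# maf_low below the 0.05 QC threshold so the MAF filter has work to do
panel <- simulate_genotypes(1000, 5000, n_chromosomes = 5, n_families = 100,
                            maf_low = 0.02, maf_high = 0.5,
                            seed = seed, miss_rate = 0.01)
print(panel)

truth <- simulate_truth(panel, n_qtl = 20, sigma_a2 = 1, h2 = 0.5,
                        seed = seed + 1L)
cat(sprintf("truth: 20 QTL, var(true_bv) = %.4f, sigma_e2 = %.3f\n",
            var(truth$true_bv), truth$sigma_e2))

y <- simulate_phenotypes(truth, seed = seed + 2L)
cat(sprintf("phenotypes: var(y) = %.4f (target %.1f)\n",
            var(y), truth$sigma_a2 + truth$sigma_e2))

zc <- center_genotypes(panel)
gb <- blend_grm(build_grm(zc), beta = 0.05)
gebvs <- solve_gblup(gb, y, truth$sigma_a2, truth$sigma_e2, "trait1")
cat(sprintf("GBLUP GEBVs: cor(gebv, true_bv) = %.3f\n",
            cor(as.numeric(gebvs$gebv), truth$true_bv)))

write_genotypes(panel, file.path(outdir, "genotypes.tsv"),
                file.path(outdir, "snp_map.tsv"))
write_gebvs(gebvs, file.path(outdir, "gebvs.tsv"),
            file.path(outdir, "varcomp.json"))
utils::write.table(
  data.frame(snp_index = truth$qtl_indices,
             snp_id = panel$snp_map$snp_id[truth$qtl_indices],
             effect = truth$true_effects[truth$qtl_indices]),
  file.path(outdir, "truth_qtl.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
cat("wrote genotypes, map, GEBVs, variance components and QTL truth to",
    outdir, "\n")
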