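#!/usr/bin/env Rscript
# Stage 4: SNP-effect back-solving and sliding-window variance ranking.
#
# Back-solves per-SNP effects from the GEBVs through the APY inverse,
# attributes additive variance to each SNP as a_i^2 * 2 p_i (1 - p_i), scans
# 25-SNP sliding windows per chromosome, and keeps the top 20 non-overlapping
# windows. Also prints the Ne-based window-sizing arithmetic (Ne = 196) that
# motivates window spans of about eight Stam segments.

suppressPackageStartupMessages(library(apygwas))

qcdir <- "results/qc"
datadir <- "results/data"
outdir <- "results/gwas"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

# the analytic sizing rule, at the effective population size of Nellore
print(window_size_from_ne(196, n_segments = 8, mb_per_morgan = 100))

panel <- read_genotypes(file.path(qcdir, "genotypes_qc.tsv"),
                        file.path(qcdir, "snp_map_qc.tsv"), "matrix-tsv")
gt <- read_gebvs(file.path(datadir, "gebvs.tsv"),
                 file.path(datadir, "varcomp.json"))
core_meta <- jsonlite::read_json(file.path("results/grm", "apy_core.json"),
                                 simplifyVector = TRUE)

zc <- center_genotypes(panel)
gb <- blend_grm(build_grm(zc), beta = core_meta$beta)
apy <- build_apy_inverse(gb, core_meta$core_indices)

trait <- gt$trait_names[1]
params <- backsolve_params(sigma_a2 = gt$sigma_a2_per_trait[[trait]],
                           beta = core_meta$beta)
eff <- backsolve_snp_effects(zc, apy, gt$gebv[, trait], params, trait)
write_snp_effects(eff, file.path(outdir, sprintf("snp_effects_%s.tsv", trait)))

wt <- window_scan(eff$per_snp_variance, panel$snp_map, window_size = 25,
                  step = 1, denominator = "sigma_a2",
                  sigma_a2 = gt$sigma_a2_per_trait[[trait]])
top <- select_top_windows(wt, "count", 20, "greedy-nonoverlap")
write_window_table(wt, file.path(outdir, sprintf("windows_%s.tsv", trait)),
                   trait)
write_window_table(top, file.path(outdir,
                                  sprintf("top_windows_%s.tsv", trait)),
                   trait)

cat(sprintf("%d windows scanned; top 20 non-overlapping explain %.3f%% of sigma_a2\n",
            nrow(wt), sum(top$pct_of_additive)))

# how often do the kept windows contain a simulated QTL?
qtl <- utils::read.table(file.path(datadir, "truth_qtl.tsv"), header = TRUE,
                         sep = "\t")
hit <- vapply(seq_len(nrow(top)), function(i) {
  any(qtl$snp_id %in%
        panel$snp_map$snp_id[top$first_snp_index[i] +
                               seq_len(top$n_snps[i]) - 1L])
}, logical(1))
cat(sprintf("top windows containing a true QTL: %d of %d\n",
            sum(hit), nrow(top)))
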