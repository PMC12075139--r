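#!/usr/bin/env Rscript
# Stage 2: marker quality control.
#
# Applies the standard panel filters — autosomes only, call rate >= 0.90,
# MAF >= 0.05, Hardy-Weinberg heterozygote deviation <= 0.15 — attributing
# each removed SNP to the first filter it fails, and writes the audit trail.

suppressPackageStartupMessages(library(apygwas))

datadir <- "results/data"
outdir <- "results/qc"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

panel <- read_genotypes(file.path(datadir, "genotypes.tsv"),
                        file.path(datadir, "snp_map.tsv"), "matrix-tsv")
res <- qc_filter(panel, qc_thresholds())
print(res$report)

write_qc_report(res$report, file.path(outdir, "qc_fate.tsv"),
                file.path(outdir, "qc_summary.json"))
write_genotypes(res$panel, file.path(outdir, "genotypes_qc.tsv"),
                file.path(outdir, "snp_map_qc.tsv"))
cat("post-QC panel and report written to", outdir, "\n")
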