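#!/usr/bin/env Rscript
# Stage 5: positional candidate-gene annotation.
#
# Annotates the top windows against a gene interval file. No real annotation
# ships with this workflow, so a SYNTHETIC gene set (random 50-500 kb
# intervals, labelled synthetic throughout) is generated here; point `genes`
# at a real BED/GFF3 (e.g. an Ensembl ARS-UCD1.2 export) to annotate against
# the genome.

suppressPackageStartupMessages(library(apygwas))

outdir <- "results/annotation"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
set.seed(20260105)

genes_path <- file.path(outdir, "synthetic_genes.bed")
starts <- sort(sample.int(95e6, 400))
writeLines(sprintf("%d\t%d\t%d\tSYNGENE%03d",
                   sample(1:5, 400, replace = TRUE), starts,
                   starts + sample(5e4:5e5, 400, replace = TRUE), 1:400),
           genes_path)
genes <- read_gene_intervals(genes_path, "bed")

top <- utils::read.table("results/gwas/top_windows_trait1.tsv",
                         header = TRUE, sep = "\t")
ann <- annotate_windows(top, genes, trait = "trait1")
utils::write.table(ann, file.path(outdir, "annotation_trait1.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("%d window-gene overlaps; %d distinct genes across %d annotated windows\n",
            nrow(ann), length(unique(ann$gene_id)),
            length(unique(ann$window_id))))
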