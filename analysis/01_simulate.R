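#!/usr/bin/env Rscript
# Step 1: generate the synthetic study dataset.
#
# Emulates the experimental design: 24 arrays = 2 accessions (low-P
# tolerant / sensitive) x 2 tissues (root / leaf) x 2 phosphate treatments
# (normal / low) x 3 biological replicates, with 151 planted genes among
# 6000 (global low-P responders, root- and accession-specific responders,
# concordant/opposite accession differences, and a block of "active" genes
# induced only in the tolerant root under low P). Also writes a toy
# annotation with one term enriched for the planted genes.

library(lowpdeg)
options(lowpdeg.verbose = TRUE)

seed <- 20160305L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- scenario_spec(rng_seed = seed)
ds <- simulate_dataset(spec)
write_expression_matrix(ds$matrix, file.path(out, "expression_raw.tsv"))
write_sample_sheet(ds$sheet, file.path(out, "sample_sheet.tsv"))

planted <- ds$truth$gene_id[ds$truth$block != "null"]
ann <- simulate_annotation(ds$truth$gene_id, n_terms = 16, target = planted,
                           odds = c(8, 5, rep(1, 14)), rng_seed = seed)
write_gene_sets(ann, file.path(out, "annotation.gmt"))

truth_df <- data.frame(gene_id = ds$truth$gene_id, block = ds$truth$block,
                       ds$truth$ratios, check.names = FALSE)
write.table(truth_df, file.path(out, "planted_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("simulated %d genes x %d arrays; %d planted genes in %d blocks\n",
            nrow(ds$matrix), ncol(ds$matrix), length(planted),
            length(spec$blocks)))
cat("wrote expression_raw.tsv, sample_sheet.tsv, annotation.gmt,",
    "planted_truth.tsv under", out, "\n")
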