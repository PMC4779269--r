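#!/usr/bin/env Rscript
# Step 5: hypergeometric over-representation of the common active genes
# against the full array background, on the toy annotation.

library(lowpdeg)

cfg <- pipeline_config(rng_seed = 20160305L)
sheet <- read_sample_sheet("results/data/sample_sheet.tsv")
mat <- read_expression_matrix("results/data/expression_normalized.tsv", sheet)
ann <- read_gene_sets("results/data/annotation.gmt")
common <- readLines("results/tables/common_active_genes.txt")

out <- enrich_sets(common, ann, rownames(mat), cfg)
write.table(out, "results/tables/enrichment.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("%d terms tested, %d enriched at P < %.2f\n",
            nrow(out), sum(out$enriched), cfg$enrichment_alpha))
print(head(out[, c("term_id", "term_name", "K", "k", "p_value", "enriched")]))
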