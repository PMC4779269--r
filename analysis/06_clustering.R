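#!/usr/bin/env Rscript
# Step 6: two-way hierarchical clustering of the treatment DEGs.
#
# Correlation distance over gene profiles, Euclidean over samples, average
# linkage; the replicate triples of each array group should form tight
# clades when the experiment is well behaved.

library(lowpdeg)

cfg <- pipeline_config(rng_seed = 20160305L)
sheet <- read_sample_sheet("results/data/sample_sheet.tsv")
mat <- read_expression_matrix("results/data/expression_normalized.tsv", sheet)

degs <- unique(unlist(lapply(
  grep("^treatment", contrast_table()$name, value = TRUE),
  function(cn) {
    res <- read.delim(file.path("results/contrasts", paste0(cn, ".tsv")),
                      stringsAsFactors = FALSE)
    res$gene_id[res$is_deg]
  })))
cat(sprintf("clustering %d treatment DEGs over %d arrays\n",
            length(degs), ncol(mat)))

cl <- cluster_expression(mat[degs, ], cfg)
writeLines(cl$newick_genes, "results/tables/dendrogram_genes.nwk")
writeLines(cl$newick_samples, "results/tables/dendrogram_samples.nwk")
write.table(data.frame(gene_id = cl$gene_order),
            "results/tables/heatmap_gene_order.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cells <- split(sheet$sample_id,
               paste(sheet$accession, sheet$tissue, sheet$treatment, sep = "_"))
coherent <- clades_present(cl$samples, cells)
cat(sprintf("replicate triples forming clades: %d of %d cells\n",
            sum(coherent), length(coherent)))
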