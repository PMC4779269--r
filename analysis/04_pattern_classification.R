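#!/usr/bin/env Rscript
# Step 4: cross-accession / cross-tissue pattern classification and the
# set algebra down to the common "active" genes.
#
# Every low-P DEG of the accession and tissue comparisons is classified by
# its normal-P behavior (concordant / opposite / unchanged), unchanged
# genes are rescued when their low-P change exceeds 4-fold, and the
# marked sets (opposite + rescued) are intersected with the non-redundant
# treatment DEG union.

library(lowpdeg)

cfg <- pipeline_config(rng_seed = 20160305L)
read_res <- function(name)
  read.delim(file.path("results/contrasts", paste0(name, ".tsv")),
             stringsAsFactors = FALSE)

ct <- contrast_table()
patterns <- do.call(rbind, lapply(unique(na.omit(ct$comparison)), function(cm) {
  lowc <- ct$name[!is.na(ct$comparison) & ct$comparison == cm &
                    ct$treatment_arm == "lowP"]
  norc <- ct$name[!is.na(ct$comparison) & ct$comparison == cm &
                    ct$treatment_arm == "normalP"]
  classify_patterns(read_res(lowc), read_res(norc), cfg, comparison = cm)
}))
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
write.table(patterns, "results/tables/patterns.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

mk_mat <- marked_degs(patterns[grepl("^material", patterns$comparison), ])
mk_tis <- marked_degs(patterns[grepl("^tissue", patterns$comparison), ])
cat(sprintf("marked DEGs: material %d raw / %d non-redundant; tissue %d\n",
            mk_mat$raw_total, mk_mat$nonredundant, mk_tis$raw_total))

treat_sets <- list()
for (cn in ct$name[ct$family == "treatment"]) {
  res <- read_res(cn)
  for (dir in c("up", "down"))
    treat_sets[[paste(cn, dir, sep = "_")]] <- res$gene_id[res$direction == dir]
}
acc <- nonredundant_union(treat_sets)
cat(sprintf("treatment DEGs: %d raw, %d non-redundant\n",
            acc$raw_total, acc$distinct_count))

common <- overlap_genes(acc$union, mk_mat$sets$marked_all,
                        mk_tis$sets$marked_all)
cat(sprintf("overlaps: treatment x material %d, treatment x tissue %d, common %d\n",
            overlap_genes(acc$union, mk_mat$sets$marked_all)$cardinality,
            overlap_genes(acc$union, mk_tis$sets$marked_all)$cardinality,
            common$cardinality))
writeLines(common$genes, "results/tables/common_active_genes.txt")

# sanity against the planted truth
truth <- read.delim("results/data/planted_truth.tsv", check.names = FALSE)
planted_common <- sum(common$genes %in%
                        truth$gene_id[truth$block %in%
                                        c("active_root_tolerant",
                                          "active_root_tolerant_down")])
cat(sprintf("%d of %d common genes come from the planted active blocks\n",
            planted_common, common$cardinality))
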