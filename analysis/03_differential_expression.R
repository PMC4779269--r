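#!/usr/bin/env Rscript
# Step 3: per-contrast differential expression.
#
# Runs the SAM-style permutation test on all twelve canonical contrasts
# (treatment within each cell, accession within each tissue under both
# treatments, tissue within each accession under both treatments) and
# applies the three-part DEG criterion: |log2 ratio| >= 1, FDR-adjusted
# q < 0.05, complete triplicates.

library(lowpdeg)

cfg <- pipeline_config(rng_seed = 20160305L)
sheet <- read_sample_sheet("results/data/sample_sheet.tsv")
mat <- read_expression_matrix("results/data/expression_normalized.tsv", sheet)

dir.create("results/contrasts", recursive = TRUE, showWarnings = FALSE)
ct <- contrast_table()
counts <- data.frame(contrast = ct$name, family = ct$family,
                     n_up = NA_integer_, n_down = NA_integer_)
for (i in seq_len(nrow(ct))) {
  res <- run_contrast(
    mat,
    sheet_samples(sheet, ct$exp_accession[i], ct$exp_tissue[i],
                  ct$exp_treatment[i]),
    sheet_samples(sheet, ct$ctl_accession[i], ct$ctl_tissue[i],
                  ct$ctl_treatment[i]),
    cfg, name = ct$name[i])
  counts$n_up[i] <- sum(res$direction == "up")
  counts$n_down[i] <- sum(res$direction == "down")
  write.table(res, file.path("results/contrasts",
                             paste0(ct$name[i], ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
write.table(counts, "results/contrasts/deg_counts.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
print(counts)
cat("wrote per-contrast tables under results/contrasts/\n")
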