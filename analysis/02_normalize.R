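#!/usr/bin/env Rscript
# Step 2: between-array quantile normalization.
#
# Removes the per-array additive offsets ("abiologic" between-array
# variation) by forcing a common intensity distribution — the
# between-array step of the RMA workflow.

library(lowpdeg)

sheet <- read_sample_sheet("results/data/sample_sheet.tsv")
raw <- read_expression_matrix("results/data/expression_raw.tsv", sheet)

cat(sprintf("raw column means span %.3f log2 units\n",
            diff(range(colMeans(raw)))))
norm <- quantile_normalize(raw)
cat(sprintf("normalized column means span %.2e log2 units\n",
            diff(range(colMeans(norm)))))

write_expression_matrix(norm, "results/data/expression_normalized.tsv")
cat("wrote results/data/expression_normalized.tsv\n")
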