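# Small builders shared across test files.

# a light scenario for fast end-to-end tests: planted fraction kept small
# relative to the array so quantile normalization stays valid
small_scenario <- function(n_genes = 1500, noise_sd = 0.25, rng_seed = 1L,
                           array_offset_sd = 0.3) {
  lowP <- paste(rep(c("tolerant", "sensitive"), each = 2),
                rep(c("root", "leaf"), 2), "lowP", sep = "_")
  blocks <- list(
    effect_block("up", 15, list(list(cells = lowP, range = c(2, 4)))),
    effect_block("down", 10, list(list(cells = lowP, range = c(-4, -2))))
  )
  scenario_spec(n_genes = n_genes, blocks = blocks, noise_sd = noise_sd,
                array_offset_sd = array_offset_sd, rng_seed = rng_seed)
}

# deterministic toy contrast-result table
toy_results <- function(log2_ratio, q, n_rep = 3L, ids = NULL) {
  n <- length(log2_ratio)
  if (is.null(ids)) ids <- sprintf("g%03d", seq_len(n))
  df <- data.frame(gene_id = ids, contrast = "toy",
                   mean_experimental = 8 + log2_ratio, mean_control = 8,
                   log2_ratio = log2_ratio, fold_change = 2^log2_ratio,
                   d_statistic = log2_ratio * 10, p_value = q, q_sam = q,
                   q_bh = q, q_value = q,
                   n_complete_replicates = rep_len(n_rep, n),
                   stringsAsFactors = FALSE)
  call_degs(df)
}

# brute-force tail of the hypergeometric distribution via binomial
# coefficients only (independent of phyper)
hyper_tail_brute <- function(N, K, n, k) {
  if (k == 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# brute-force SAM d for two vectors, written independently of the package
d_brute <- function(e, c_, s0) {
  r <- mean(e) - mean(c_)
  if (r == 0) return(0)
  n1 <- length(e); n2 <- length(c_)
  sp2 <- ((n1 - 1) * var(e) + (n2 - 1) * var(c_)) / (n1 + n2 - 2)
  r / (sqrt((1 / n1 + 1 / n2) * sp2) + s0)
}
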