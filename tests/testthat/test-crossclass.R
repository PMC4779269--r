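cfg <- pipeline_config()

test_that("pattern categories follow the normal-P behavior and rescue rule", {
  # low-P DEGs: up concordant, up opposite, up 5-fold rescued, up 3-fold
  # dropped, down rescued (< 1/4), down dropped
  low <- toy_results(log2_ratio = c(1.5, 1.5, log2(5), log2(3), -log2(5), -1.5, 0.2),
                     q = c(rep(0.001, 6), 0.9))
  nor <- toy_results(log2_ratio = c(1.2, -1.2, 0.1, -0.2, 0.3, 0.4, 0.1),
                     q = c(0.001, 0.001, 0.9, 0.8, 0.7, 0.6, 0.5),
                     ids = low$gene_id)
  out <- classify_patterns(low, nor, cfg, "material_root")
  expect_equal(nrow(out), 6)   # the non-DEG is absent
  expect_identical(out$category,
                   c("concordant", "opposite", "rescued", "dropped",
                     "rescued", "dropped"))
  expect_identical(out$normalP_status[3], "no_difference")
  expect_identical(out$lowP_direction[5], "down")
})

test_that("the 4-fold rescue threshold is strict", {
  low <- toy_results(log2_ratio = c(2, 2 + 1e-9), q = c(0.001, 0.001))
  nor <- toy_results(log2_ratio = c(0, 0), q = c(0.9, 0.9), ids = low$gene_id)
  out <- classify_patterns(low, nor, cfg, "cmp")
  expect_identical(out$category, c("dropped", "rescued"))
})

test_that("a low-P DEG missing from the normal-P table is an error", {
  low <- toy_results(log2_ratio = c(2, 3), q = c(0.001, 0.001))
  nor <- toy_results(log2_ratio = 0, q = 0.9, ids = low$gene_id[1])
  expect_error(classify_patterns(low, nor, cfg, "cmp"), low$gene_id[2])
})

test_that("the normal-difference rule is switchable", {
  # |normal ratio| 1.3 but not significant: a DEG-criteria difference says
  # "no difference" (not a normal-P DEG), the fold-only rule says same
  low <- toy_results(log2_ratio = 2.5, q = 0.001)
  nor <- toy_results(log2_ratio = 1.3, q = 0.9, ids = low$gene_id)
  a <- classify_patterns(low, nor, cfg, "cmp")
  expect_identical(a$category, "rescued")
  cfg2 <- pipeline_config(normal_diff_rule = "fold_only")
  b <- classify_patterns(low, nor, cfg2, "cmp")
  expect_identical(b$category, "concordant")
})

test_that("partition identity holds on randomized inputs", {
  set.seed(14)
  for (i in 1:10) {
    n <- 200
    low <- toy_results(log2_ratio = runif(n, -4, 4),
                       q = sample(c(0.001, 0.3), n, replace = TRUE),
                       n_rep = sample(2:3, n, replace = TRUE))
    low <- call_degs(low, cfg)
    nor <- toy_results(log2_ratio = runif(n, -3, 3),
                       q = sample(c(0.001, 0.3), n, replace = TRUE),
                       ids = low$gene_id)
    nor <- call_degs(nor, cfg)
    out <- classify_patterns(low, nor, cfg, "cmp")
    expect_equal(nrow(out), sum(low$is_deg))
    tab <- table(factor(out$category, c("concordant", "opposite",
                                        "rescued", "dropped")))
    expect_equal(sum(tab), nrow(out))
    # marked = opposite U rescued, disjoint from concordant/dropped
    mk <- marked_degs(out)
    expect_equal(mk$raw_total, unname(tab["opposite"] + tab["rescued"]))
    expect_length(intersect(mk$sets$marked_all,
                            out$gene_id[out$category == "concordant"]), 0)
  }
})

test_that("marked sets on the pattern fixture match the printed accounting", {
  fx <- simulate_table2_fixture()
  pats <- do.call(rbind, lapply(names(fx$contrasts), function(cm)
    classify_patterns(fx$contrasts[[cm]]$lowP, fx$contrasts[[cm]]$normalP,
                      cfg, cm)))
  mat <- marked_degs(pats[grepl("^material", pats$comparison), ])
  tis <- marked_degs(pats[grepl("^tissue", pats$comparison), ])
  expect_equal(mat$raw_total, 196)
  expect_equal(mat$nonredundant, 195)
  expect_equal(tis$raw_total, 253)
  expect_equal(tis$nonredundant, 253)
  # per-tissue marked counts and the up-regulated majority
  pc <- mat$per_comparison
  expect_equal(pc$n_marked[pc$comparison == "material_root"], 117)
  expect_equal(pc$n_marked[pc$comparison == "material_leaf"], 79)
  marked_up <- pats[pats$category %in% c("opposite", "rescued") &
                      grepl("^material", pats$comparison) &
                      pats$lowP_direction == "up", ]
  expect_equal(length(unique(marked_up$gene_id)), 143)
})

test_that("empty pattern tables give empty marked sets", {
  low <- toy_results(log2_ratio = c(1.5, 2), q = c(0.001, 0.001))
  nor <- toy_results(log2_ratio = c(1.5, 2), q = c(0.001, 0.001),
                     ids = low$gene_id)
  out <- classify_patterns(low, nor, cfg, "cmp")  # all concordant
  mk <- marked_degs(out)
  expect_equal(mk$raw_total, 0)
  expect_length(mk$sets$marked_all, 0)
})

test_that("non-redundant union accounting is exact", {
  acc <- nonredundant_union(list(a = c("g1", "g2"), b = c("g3", "g4", "g5")))
  expect_equal(acc$raw_total, 5)
  expect_equal(acc$distinct_count, 5)
  same <- nonredundant_union(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(same$raw_total, 4)
  expect_equal(same$distinct_count, 2)
  expect_identical(sort(same$duplicates$gene_id), c("x", "y"))
  # transcript suffixes are distinct identities
  tr <- nonredundant_union(list(a = "Glyma20g33710.1", b = "Glyma20g33710.2"))
  expect_equal(tr$distinct_count, 2)
  # raw total = distinct + multiplicity excess
  set.seed(9)
  sets <- lapply(1:4, function(i) sample(sprintf("g%02d", 1:30), 12))
  acc2 <- nonredundant_union(sets)
  excess <- sum(acc2$duplicates$n_sets - 1)
  expect_equal(acc2$distinct_count + excess, acc2$raw_total)
})

test_that("set intersection is exact, commutative and bounded", {
  out <- overlap_genes(c("g1", "g2", "g3"), c("g2", "g3", "g4"))
  expect_identical(out$genes, c("g2", "g3"))
  expect_equal(out$cardinality, 2)
  expect_equal(overlap_genes(c("g1"), character(0))$cardinality, 0)
  expect_error(overlap_genes(c("g1")), "at least 2")
  set.seed(4)
  a <- sample(letters, 10); b <- sample(letters, 15); c_ <- sample(letters, 8)
  abc <- overlap_genes(a, b, c_)
  expect_identical(abc, overlap_genes(c_, a, b))
  expect_identical(abc$genes, overlap_genes(overlap_genes(a, b)$genes, c_)$genes)
  expect_lte(overlap_genes(a, b)$cardinality, min(length(a), length(b)))
})

test_that("engineered three-way overlaps are recovered exactly", {
  core <- sprintf("core%02d", 1:7)
  ab <- sprintf("ab%02d", 1:5); ac <- sprintf("ac%02d", 1:4)
  a <- c(core, ab, ac, sprintf("a%02d", 1:10))
  b <- c(core, ab, sprintf("b%02d", 1:12))
  c_ <- c(core, ac, sprintf("c%02d", 1:3))
  expect_equal(overlap_genes(a, b)$cardinality, 12)
  expect_equal(overlap_genes(a, c_)$cardinality, 11)
  expect_equal(overlap_genes(a, b, c_)$cardinality, 7)
})
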