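test_that("the canonical design is 24 arrays, 2x2x2 cells x 3 replicates", {
  sheet <- canonical_sample_sheet()
  expect_equal(nrow(sheet), 24)
  expect_equal(unname(table(sheet$accession, sheet$tissue, sheet$treatment))[, , 1],
               matrix(3, 2, 2))
  ds <- simulate_dataset(scenario_spec(n_genes = 50, blocks = list(),
                                       rng_seed = 1))
  expect_equal(dim(ds$matrix), c(50, 24))
  expect_identical(colnames(ds$matrix), sheet$sample_id)
})

test_that("the null scenario plants nothing and group means differ only by noise", {
  ds <- simulate_dataset(scenario_null(n_genes = 300, rng_seed = 4))
  expect_true(all(ds$truth$block == "null"))
  expect_true(all(ds$truth$ratios == 0))
  low <- rowMeans(ds$matrix[, sheet_samples(ds$sheet, "tolerant", "root", "lowP")])
  nor <- rowMeans(ds$matrix[, sheet_samples(ds$sheet, "tolerant", "root", "normalP")])
  # per-gene mean difference ~ N(offset diff, 0.25 * sqrt(2/3))
  expect_lt(sd(low - nor), 4 * 0.25 * sqrt(2 / 3))
})

test_that("planted effects reproduce the requested mean log2 ratio", {
  lowP <- paste(rep(c("tolerant", "sensitive"), each = 2),
                rep(c("root", "leaf"), 2), "lowP", sep = "_")
  blocks <- list(effect_block("fixed3", 100,
                              list(list(cells = lowP, range = c(3, 3)))))
  spec <- scenario_spec(n_genes = 400, blocks = blocks, noise_sd = 0.25,
                        array_offset_sd = 0, rng_seed = 9)
  ds <- simulate_dataset(spec)
  low <- rowMeans(ds$matrix[1:100, sheet_samples(ds$sheet, "tolerant", "root", "lowP")])
  nor <- rowMeans(ds$matrix[1:100, sheet_samples(ds$sheet, "tolerant", "root", "normalP")])
  expect_lt(abs(mean(low - nor) - 3), 3 * 0.25 * sqrt(2 / 3))
})

test_that("planted fold changes stay inside the configured linear range", {
  lowP <- paste(rep(c("tolerant", "sensitive"), each = 2),
                rep(c("root", "leaf"), 2), "lowP", sep = "_")
  rng <- c(log2(2.00), log2(33.78))
  blocks <- list(effect_block("range_up", 200,
                              list(list(cells = lowP, range = rng))))
  ds <- simulate_dataset(scenario_spec(n_genes = 200, blocks = blocks,
                                       rng_seed = 2))
  fc <- 2^ds$truth$ratios[, "treatment_tolerant_root"]
  expect_true(all(fc >= 2.00 & fc <= 33.78))
})

test_that("simulation is reproducible by seed and effect ranges are validated", {
  a <- simulate_dataset(small_scenario(n_genes = 200, rng_seed = 77))
  b <- simulate_dataset(small_scenario(n_genes = 200, rng_seed = 77))
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$truth$ratios, b$truth$ratios)
  lowP <- "tolerant_root_lowP"
  expect_error(effect_block("bad", 5, list(list(cells = lowP, range = c(0.5, 2)))),
               "exclude")
  expect_error(effect_block("bad", 5, list(list(cells = "no_such_cell",
                                                range = c(2, 3)))),
               "cell")
  expect_error(scenario_spec(n_genes = 100), "exceed")
})

test_that("pattern classification on noise-free data recovers every planted category", {
  cfg <- pipeline_config()
  spec <- scenario_spec(n_genes = 400, noise_sd = 1e-4, array_offset_sd = 0,
                        rng_seed = 5)
  ds <- simulate_dataset(spec)
  ct <- contrast_table()
  contrasts <- lapply(seq_len(nrow(ct)), function(i) {
    run_contrast(ds$matrix,
                 sheet_samples(ds$sheet, ct$exp_accession[i], ct$exp_tissue[i],
                               ct$exp_treatment[i]),
                 sheet_samples(ds$sheet, ct$ctl_accession[i], ct$ctl_tissue[i],
                               ct$ctl_treatment[i]),
                 cfg, name = ct$name[i])
  })
  names(contrasts) <- ct$name
  comps <- unique(na.omit(ct$comparison))
  got <- do.call(rbind, lapply(comps, function(cm) {
    lowc <- ct$name[!is.na(ct$comparison) & ct$comparison == cm &
                      ct$treatment_arm == "lowP"]
    norc <- ct$name[!is.na(ct$comparison) & ct$comparison == cm &
                      ct$treatment_arm == "normalP"]
    classify_patterns(contrasts[[lowc]], contrasts[[norc]], cfg, cm)
  }))
  want <- truth_patterns(ds$truth, cfg)
  got <- got[order(got$comparison, got$gene_id), ]
  want <- want[order(want$comparison, want$gene_id), ]
  expect_identical(got$gene_id, want$gene_id)
  expect_identical(got$category, want$category)
  expect_identical(got$lowP_direction, want$lowP_direction)
})

test_that("synthetic annotation plants reproducible term maps with valid nulls", {
  universe <- sprintf("g%04d", 1:400)
  a <- simulate_annotation(universe, 10, rng_seed = 3)
  b <- simulate_annotation(universe, 10, rng_seed = 3)
  expect_identical(a, b)
  expect_length(a, 10)
  expect_true(all(lengths(a) >= 10 & lengths(a) <= 40))
  expect_error(simulate_annotation(character(0), 5), "empty")
  expect_error(simulate_annotation(universe, 0), "n_terms")
})

test_that("treatment fixture reproduces the printed DEG set accounting", {
  fx <- simulate_table1_fixture()
  expect_equal(lengths(fx$sets, use.names = FALSE), c(257, 41, 11, 3, 7))
  acc <- nonredundant_union(fx$sets)
  expect_equal(acc$raw_total, 319)
  expect_equal(acc$distinct_count, 317)
  expect_equal(nrow(acc$duplicates), 2)
})

test_that("pattern fixture reproduces the printed category multiplicities", {
  fx <- simulate_table2_fixture()
  tr <- fx$truth
  ru <- tr[tr$comparison == "material_root" & tr$lowP_direction == "up", ]
  expect_equal(sum(ru$category == "concordant"), 941)
  expect_equal(sum(ru$category == "opposite"), 10)
  expect_equal(sum(ru$category %in% c("rescued", "dropped")), 826)
  expect_equal(sum(ru$category == "rescued"), 93)
  expect_equal(nrow(ru), 1777)
  tu <- tr[tr$comparison == "tissue_tolerant" & tr$lowP_direction == "up", ]
  expect_equal(nrow(tu), 6370)
  expect_equal(sum(tu$category == "rescued"), 97)
  rescued <- with(tr, tapply(category == "rescued",
                             paste(comparison, lowP_direction), sum))
  expect_equal(as.vector(rescued[c("material_root up", "material_leaf up",
                                   "material_root down", "material_leaf down")]),
               c(93, 40, 14, 38))
  expect_equal(as.vector(rescued[c("tissue_tolerant up", "tissue_sensitive up",
                                   "tissue_tolerant down",
                                   "tissue_sensitive down")]),
               c(97, 63, 19, 73))
  # exactly one transcript shared between the two material marked sets
  marked <- tr[tr$category %in% c("rescued", "opposite") &
                 grepl("^material", tr$comparison), ]
  expect_equal(sum(duplicated(marked$gene_id)), 1)
})
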