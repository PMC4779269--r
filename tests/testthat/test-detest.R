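test_that("sam_d evaluates the moderated statistic correctly", {
  expect_equal(sam_d(c(2, 2, 2), c(0, 0, 0), s0 = 1), 2)
  expect_equal(sam_d(c(5, 5, 5), c(5, 5, 5), s0 = 0.5), 0)
  x <- c(1.2, 1.5, 0.9); y <- c(0.1, 0.4, 0.2)
  expect_equal(sam_d(x, y, 0.1), -sam_d(y, x, 0.1))
  expect_equal(sam_d(x + 3, y + 3, 0.1), sam_d(x, y, 0.1))
  # shrinks toward zero as s0 grows
  expect_lt(abs(sam_d(x, y, 1)), abs(sam_d(x, y, 0.1)))
  expect_error(sam_d(c(1), c(1, 2), 0), "at least 2")
  # agrees with an independently coded oracle on random draws
  set.seed(3)
  for (i in 1:20) {
    e <- rnorm(3); c_ <- rnorm(3); s0 <- runif(1, 0, 1)
    expect_equal(sam_d(e, c_, s0), d_brute(e, c_, s0), tolerance = 1e-12)
  }
})

test_that("choose_s0 is deterministic and positive under low-variance contamination", {
  set.seed(11)
  g <- 2000
  r <- rnorm(g, 0, 0.5)
  s <- runif(g, 0.2, 0.6)
  # degenerate: identical s for all genes -> smallest candidate
  expect_equal(choose_s0(r, rep(0.3, g)), 0)
  expect_warning(out <- choose_s0(r, rep(0, g)), "zero")
  expect_equal(out, 0)
  # contamination: 10% of genes with s ~ 0 but non-null r would dominate
  # the d-spread in the low-s bin unless s0 > 0
  idx <- 1:200
  s2 <- s; s2[idx] <- 1e-4
  r2 <- r; r2[idx] <- rnorm(200, 0, 0.5)
  s0_hat <- choose_s0(r2, s2)
  expect_gt(s0_hat, 0)
  expect_identical(choose_s0(r2, s2), s0_hat)
  # chosen value lies on the candidate grid
  cand <- sort(unique(c(0, unname(quantile(s2, seq(0, 1, 0.05))))))
  expect_true(s0_hat %in% cand)
})

test_that("exhaustive 3v3 permutation p-values equal the brute-force oracle", {
  set.seed(21)
  g <- 12
  m <- matrix(rnorm(g * 6, 8, 0.5), g, 6,
              dimnames = list(paste0("g", 1:g), paste0("s", 1:6)))
  m[1:3, 4:6] <- m[1:3, 4:6] + 2.5
  s0 <- 0.1
  res <- permutation_pvalues(m, 4:6, 1:3, s0 = s0)
  expect_equal(res$n_relabelings, 20)
  # oracle: enumerate all 20 relabelings with independent d code, pool
  combos <- combn(6, 3)
  dmat <- sapply(seq_len(ncol(combos)), function(j) {
    e <- combos[, j]; c_ <- setdiff(1:6, e)
    apply(m, 1, function(v) d_brute(v[e], v[c_], s0))
  })
  d_obs <- apply(m, 1, function(v) d_brute(v[4:6], v[1:3], s0))
  pool <- abs(as.vector(dmat))
  p_oracle <- vapply(abs(d_obs), function(t)
    (1 + sum(pool >= t - 1e-12)) / (1 + length(pool)), 0)
  expect_equal(unname(res$p), unname(p_oracle), tolerance = 1e-12)
  expect_true(all(res$p > 0 & res$p <= 1))
})

test_that("a gene constant across all samples gets p = 1", {
  set.seed(2)
  m <- matrix(rnorm(5 * 6), 5, 6, dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  m[3, ] <- 4.4
  res <- permutation_pvalues(m, 4:6, 1:3, s0 = 0.2)
  expect_equal(unname(res$p[3]), 1)
})

test_that("subsampled permutations are reproducible under a fixed seed", {
  set.seed(8)
  m <- matrix(rnorm(30 * 10, 8, 1), 30, 10,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:10)))
  a <- permutation_pvalues(m, 6:10, 1:5, s0 = 0.1, n_permutations = 40,
                           rng_seed = 99)
  b <- permutation_pvalues(m, 6:10, 1:5, s0 = 0.1, n_permutations = 40,
                           rng_seed = 99)
  expect_identical(a$p, b$p)
  expect_equal(a$n_relabelings, 40)
})

test_that("fdr_adjust applies the BH step-up rule", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(fdr_adjust(0.123), 0.123)
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  p <- c(0.001, 0.2, 0.04, 0.9)
  q <- fdr_adjust(p)
  expect_true(all(diff(q[order(p)]) >= 0))
})

test_that("SAM q-values are monotone in |d| and bounded", {
  set.seed(31)
  g <- 300
  m <- matrix(rnorm(g * 6, 8, 0.3), g, 6,
              dimnames = list(paste0("g", 1:g), paste0("s", 1:6)))
  m[1:30, 4:6] <- m[1:30, 4:6] + 3
  perm <- permutation_pvalues(m, 4:6, 1:3)
  qq <- sam_qvalues(perm$d, perm$dstar)
  expect_true(all(qq$q >= 0 & qq$q <= 1))
  expect_true(qq$pi0 >= 0 && qq$pi0 <= 1)
  ord <- order(abs(perm$d), decreasing = TRUE)
  expect_true(all(diff(qq$q[ord]) >= -1e-12))
  # the strongly shifted genes reach small q; almost no nulls do
  expect_lt(max(qq$q[1:30]), 0.05)
  expect_lte(mean(qq$q[31:g] < 0.05), 0.05)
})

test_that("the three-part DEG criterion is enforced exactly", {
  cfg <- pipeline_config()
  res <- toy_results(log2_ratio = c(1.0, 0.9, -2, 1.4, 2.2),
                     q = c(0.01, 0.001, 0.2, 0.01, 0.04),
                     n_rep = c(3, 3, 3, 2, 3))
  out <- call_degs(res, cfg)
  # boundary: log2 ratio exactly 1 with q < alpha is the minimum
  # admissible up-regulated DEG, fold change 2.00
  expect_true(out$is_deg[1])
  expect_identical(out$direction[1], "up")
  expect_equal(out$fold_change[1], 2)
  expect_false(out$is_deg[2])   # fails the fold criterion
  expect_false(out$is_deg[3])   # fails the FDR criterion
  expect_false(out$is_deg[4])   # incomplete triplicates
  expect_true(out$is_deg[5])
  expect_identical(out$direction[3], "none")
})

test_that("d is invariant to adding a constant to all six values of a gene", {
  set.seed(12)
  m <- matrix(rnorm(10 * 6, 8, 0.4), 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  m2 <- m; m2[4, ] <- m2[4, ] + 11
  a <- permutation_pvalues(m, 4:6, 1:3, s0 = 0.1)
  b <- permutation_pvalues(m2, 4:6, 1:3, s0 = 0.1)
  expect_equal(a$d[4], b$d[4], tolerance = 1e-9)
})

test_that("null data keep the DEG fraction at or below the nominal level", {
  # type-I control over repeated null simulations
  frac <- vapply(1:20, function(seed) {
    ds <- simulate_dataset(scenario_null(n_genes = 400, rng_seed = seed))
    res <- run_contrast(ds$matrix,
                        sheet_samples(ds$sheet, "tolerant", "root", "lowP"),
                        sheet_samples(ds$sheet, "tolerant", "root", "normalP"),
                        pipeline_config())
    mean(res$is_deg)
  }, 0)
  expect_lte(mean(frac), 0.05)
})
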