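#' SAM moderated difference statistic for one gene
#'
#' `d = (mean_exp - mean_ctl) / (s + s0)` where `s` is the pooled standard
#' error of the mean difference and `s0` is the exchangeability ("fudge")
#' constant that stabilizes genes with near-zero variance. A zero numerator
#' yields `d = 0` regardless of the denominator.
#'
#' @param values_exp,values_ctl Numeric replicate vectors (each of length
#'   at least 2) for the experimental and control groups.
#' @param s0 Non-negative fudge constant.
#' @return The d statistic (antisymmetric under swapping the groups).
#' @examples
#' sam_d(c(2, 2, 2), c(0, 0, 0), s0 = 1)  # 2
#' @export
sam_d <- function(values_exp, values_ctl, s0 = 0) {
  if (length(values_exp) < 2 || length(values_ctl) < 2)
    stop("each group needs at least 2 replicates (variance undefined)",
         call. = FALSE)
  stopifnot(all(is.finite(values_exp)), all(is.finite(values_ctl)), s0 >= 0)
  r <- mean(values_exp) - mean(values_ctl)
  if (r == 0) return(0)
  s <- pooled_se(values_exp, values_ctl)
  r / (s + s0)
}

# pooled standard error of a two-group mean difference
pooled_se <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  sqrt((1 / n1 + 1 / n2) * sp2)
}

# Vectorized numerator r and pooled standard error s for all genes of a
# matrix under one labeling. NA-tolerant: genes with < 2 finite values in a
# group get NA.
gene_stats <- function(matrix, idx_exp, idx_ctl) {
  xe <- matrix[, idx_exp, drop = FALSE]
  xc <- matrix[, idx_ctl, drop = FALSE]
  ne <- rowSums(is.finite(xe)); nc <- rowSums(is.finite(xc))
  me <- rowMeans(xe, na.rm = TRUE); mc <- rowMeans(xc, na.rm = TRUE)
  ve <- rowSums((xe - me)^2, na.rm = TRUE) / (ne - 1)
  vc <- rowSums((xc - mc)^2, na.rm = TRUE) / (nc - 1)
  sp2 <- ((ne - 1) * ve + (nc - 1) * vc) / (ne + nc - 2)
  s <- sqrt((1 / ne + 1 / nc) * sp2)
  bad <- ne < 2 | nc < 2
  r <- me - mc
  r[bad] <- NA_real_; s[bad] <- NA_real_
  list(r = r, s = s, n_exp = ne, n_ctl = nc,
       mean_exp = me, mean_ctl = mc)
}

d_from_stats <- function(r, s, s0) {
  d <- ifelse(is.na(r), NA_real_, ifelse(r == 0, 0, r / (s + s0)))
  as.numeric(d)
}

#' Choose the SAM fudge factor s0
#'
#' Evaluates candidate values of `s0` — the percentiles of the per-gene
#' pooled standard errors `s`, plus 0 — and returns the one minimizing the
#' coefficient of variation of the spread (MAD) of `d` across bins of `s`.
#' This is the classical SAM tuning rule: it keeps the scale of `d`
#' comparable between low- and high-variance genes.
#'
#' @param r Numeric vector of per-gene mean differences.
#' @param s Numeric vector of per-gene pooled standard errors.
#' @param n_bins Number of `s`-quantile bins for the spread estimate
#'   (default 10, reduced automatically for small gene counts).
#' @return The selected `s0` (smallest candidate on ties). All-zero `s`
#'   returns 0 with a warning.
#' @export
choose_s0 <- function(r, s, n_bins = 10) {
  stopifnot(length(r) == length(s))
  keep <- is.finite(r) & is.finite(s)
  r <- r[keep]; s <- s[keep]
  if (!length(s) || all(s == 0)) {
    warning("all genes have zero pooled standard error; s0 = 0")
    return(0)
  }
  cand <- sort(unique(c(0, unname(quantile(s, seq(0, 1, by = 0.05))))))
  n_bins <- max(2, min(n_bins, floor(length(s) / 20)))
  bin <- cut(rank(s, ties.method = "first"), breaks = n_bins, labels = FALSE)
  cv <- vapply(cand, function(s0) {
    d <- ifelse(r == 0, 0, r / (s + s0))
    mads <- tapply(d, bin, stats::mad)
    m <- mean(mads)
    if (!is.finite(m) || m == 0) return(Inf)
    stats::sd(mads) / m
  }, 0)
  if (all(!is.finite(cv))) return(0)
  cand[which.min(cv)]   # which.min takes the first (smallest) on ties
}

#' Balanced relabelings of a two-group design
#'
#' All distinct assignments of the pooled samples into an experimental
#' group of the original size; for the canonical 3 vs 3 design there are
#' `choose(6, 3) = 20`, including the observed labeling and its complement.
#'
#' @param n_exp,n_ctl Group sizes.
#' @return Integer matrix, one relabeling per column, rows indexing the
#'   experimental members among the pooled `n_exp + n_ctl` samples.
#' @export
balanced_relabelings <- function(n_exp, n_ctl) {
  combn(n_exp + n_ctl, n_exp)
}

#' Permutation p-values for a two-group contrast
#'
#' Computes the observed SAM `d` for every gene and a permutation null from
#' balanced relabelings of the pooled samples, with the null pooled across
#' genes (the SAM convention):
#' `p = (1 + #\{|d*| >= |d_obs|\}) / (1 + total)`.
#' When the exhaustive relabeling count is within `n_permutations` all
#' relabelings are used (removing Monte-Carlo noise; always the case at
#' 3 vs 3); otherwise a seeded subsample without replacement is drawn.
#'
#' @param matrix Numeric genes x samples matrix.
#' @param experimental,control Character vectors of column names (or
#'   integer indices) of the two groups; disjoint, each of size >= 2.
#' @param s0 Fudge constant; `NULL` selects it with [choose_s0()].
#' @param n_permutations Maximum relabelings (default 1000).
#' @param rng_seed Seed for relabeling subsampling.
#' @return List with `d` (observed), `p` (pooled permutation p-values in
#'   (0, 1]), `dstar` (genes x relabelings null matrix), `s0`, and the
#'   per-gene summary statistics.
#' @export
permutation_pvalues <- function(matrix, experimental, control, s0 = NULL,
                                n_permutations = 1000L, rng_seed = 1L) {
  idx_exp <- if (is.character(experimental)) match(experimental, colnames(matrix)) else experimental
  idx_ctl <- if (is.character(control)) match(control, colnames(matrix)) else control
  if (anyNA(idx_exp) || anyNA(idx_ctl))
    stop("contrast names not found among matrix columns", call. = FALSE)
  if (length(intersect(idx_exp, idx_ctl)))
    stop("experimental and control groups overlap", call. = FALSE)
  n1 <- length(idx_exp); n2 <- length(idx_ctl)
  if (n1 < 2 || n2 < 2)
    stop("each group needs at least 2 samples", call. = FALSE)
  perms <- balanced_relabelings(n1, n2)
  if (ncol(perms) < 2)
    stop("fewer than 2 distinct relabelings available", call. = FALSE)
  pooled_idx <- c(idx_exp, idx_ctl)
  if (ncol(perms) > n_permutations) {
    old <- local_seed(rng_seed)
    on.exit(restore_seed(old), add = TRUE)
    keep <- sort(sample.int(ncol(perms), n_permutations))
    perms <- perms[, keep, drop = FALSE]
  }
  obs <- gene_stats(matrix, idx_exp, idx_ctl)
  if (is.null(s0)) s0 <- choose_s0(obs$r, obs$s)
  d_obs <- d_from_stats(obs$r, obs$s, s0)
  dstar <- vapply(seq_len(ncol(perms)), function(j) {
    e <- pooled_idx[perms[, j]]
    c_ <- setdiff(pooled_idx, e)
    st <- gene_stats(matrix, e, c_)
    d_from_stats(st$r, st$s, s0)
  }, numeric(nrow(matrix)))
  pool <- sort(abs(as.vector(dstar[is.finite(dstar)])))
  n_pool <- length(pool)
  exceed <- n_pool - findInterval(abs(d_obs) - 1e-12, pool)
  p <- (1 + exceed) / (1 + n_pool)
  p[!is.finite(d_obs)] <- NA_real_
  list(d = d_obs, p = p, dstar = dstar, s0 = s0, stats = obs,
       n_relabelings = ncol(perms))
}

# save/restore .Random.seed so seeded internals do not disturb the caller
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone in p-rank, capped at 1), delegated
#' to [stats::p.adjust()] after input validation.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs tolerated).
#' @return Adjusted q-values.
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
fdr_adjust <- function(p) {
  ok <- is.na(p) | (p >= 0 & p <= 1)
  if (!all(ok)) stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' SAM q-values from a permutation null
#'
#' The SAM estimate of the false discovery rate at threshold `t = |d|`:
#' the median over relabelings of the number of null `|d*|` values at or
#' above `t`, scaled by the estimated null proportion `pi0`, divided by the
#' observed count at or above `t`; made monotone so each gene reports the
#' best FDR of any threshold that still includes it. The median across
#' relabelings makes the estimate robust to the observed labeling (and its
#' complement) re-appearing among the exhaustive relabelings, which is what
#' defeats rank-based adjustments at triplicate design sizes.
#'
#' @param d Observed d statistics.
#' @param dstar Genes x relabelings matrix of null d statistics.
#' @return List with `q` (per-gene q-values in `[0, 1]`) and `pi0`.
#' @export
sam_qvalues <- function(d, dstar) {
  stopifnot(is.matrix(dstar), nrow(dstar) == length(d))
  fin <- is.finite(d)
  t_obs <- abs(d)
  ord <- order(t_obs, decreasing = TRUE, na.last = TRUE)
  n_fin <- sum(fin)
  thresholds <- t_obs[ord][seq_len(n_fin)]
  R <- seq_len(n_fin)
  V <- vapply(seq_len(ncol(dstar)), function(b) {
    sb <- sort(abs(dstar[is.finite(dstar[, b]), b]))
    length(sb) - findInterval(thresholds - 1e-12, sb)
  }, numeric(n_fin))
  v_med <- if (n_fin == 1) median(V) else apply(V, 1, median)
  pool <- abs(as.vector(dstar[is.finite(dstar)]))
  qlim <- quantile(pool, c(0.25, 0.75))
  pi0 <- min(1, sum(t_obs[fin] >= qlim[1] & t_obs[fin] <= qlim[2]) /
                  (0.5 * n_fin))
  fdr <- pmin(1, pi0 * v_med / R)
  q_sorted <- rev(cummin(rev(fdr)))
  q <- rep(NA_real_, length(d))
  q[ord[seq_len(n_fin)]] <- q_sorted
  list(q = q, pi0 = pi0)
}

#' Apply the three-part DEG criterion
#'
#' A gene is a DEG when simultaneously (a) `|log2_ratio|` is at or above
#' the threshold (default 1, i.e. two-fold), (b) the FDR-adjusted
#' statistic (`q_value`) is below `fdr_alpha`, and (c) complete biological
#' triplicates exist in both groups. Direction is the sign of the ratio.
#'
#' @param results A contrast-result data frame with columns `log2_ratio`,
#'   `q_value` and `n_complete_replicates`.
#' @param config An [pipeline_config()] object.
#' @return The data frame with `is_deg` and `direction` (re)computed.
#' @export
call_degs <- function(results, config = pipeline_config()) {
  stopifnot(all(c("log2_ratio", "q_value", "n_complete_replicates") %in%
                  names(results)))
  pass_fold <- abs(results$log2_ratio) >= config$log2_ratio_threshold
  pass_q <- !is.na(results$q_value) & results$q_value < config$fdr_alpha
  pass_rep <- results$n_complete_replicates >= 3
  results$is_deg <- pass_fold & pass_q & pass_rep
  results$is_deg[is.na(results$is_deg)] <- FALSE
  results$direction <- ifelse(!results$is_deg, "none",
                              ifelse(results$log2_ratio > 0, "up", "down"))
  results
}

#' Run one two-group differential-expression contrast
#'
#' Full SAM-style test for one contrast: observed d statistics, pooled
#' permutation p-values over balanced relabelings, both FDR routes (SAM
#' median-based q and Benjamini-Hochberg on the permutation p-values), and
#' the three-part DEG call. The `q_value` column used by the DEG criterion
#' follows `config$q_method`.
#'
#' @param matrix Numeric genes x samples matrix (log2 scale).
#' @param experimental,control Sample-id vectors of the two groups; the
#'   ratio is oriented experimental over control (low P over normal P,
#'   tolerant over sensitive, root over leaf).
#' @param config A [pipeline_config()] object.
#' @param name Contrast name recorded in the result.
#' @return Data frame with one row per gene: `gene_id`, `contrast`,
#'   `mean_experimental`, `mean_control`, `log2_ratio`, `fold_change`,
#'   `d_statistic`, `p_value`, `q_sam`, `q_bh`, `q_value`,
#'   `n_complete_replicates`, `is_deg`, `direction`.
#' @export
run_contrast <- function(matrix, experimental, control,
                         config = pipeline_config(), name = "contrast") {
  perm <- permutation_pvalues(matrix, experimental, control,
                              s0 = config$s0,
                              n_permutations = config$permutations,
                              rng_seed = config$rng_seed)
  q_bh <- fdr_adjust(perm$p)
  q_sam <- sam_qvalues(perm$d, perm$dstar)$q
  st <- perm$stats
  res <- data.frame(
    gene_id = rownames(matrix),
    contrast = name,
    mean_experimental = unname(st$mean_exp),
    mean_control = unname(st$mean_ctl),
    log2_ratio = unname(st$r),
    fold_change = unname(2^st$r),
    d_statistic = unname(perm$d),
    p_value = unname(perm$p),
    q_sam = unname(q_sam),
    q_bh = unname(q_bh),
    n_complete_replicates = unname(pmin(st$n_exp, st$n_ctl)),
    stringsAsFactors = FALSE
  )
  res$q_value <- if (config$q_method == "sam") res$q_sam else res$q_bh
  res <- call_degs(res, config)
  lp_log("contrast ", name, ": ", sum(res$is_deg), " DEGs (",
         sum(res$direction == "up"), " up, ",
         sum(res$direction == "down"), " down) of ", nrow(res),
         " genes; s0 = ", signif(perm$s0, 3))
  res
}
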