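#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `k` annotated genes in a query of size `n` from a
#' background of `N` genes of which `K` carry the annotation. Computed in
#' log space via [stats::phyper()], numerically stable for backgrounds up
#' to at least 1e5 genes.
#'
#' @param N Background size.
#' @param K Annotated genes in the background.
#' @param n Query size.
#' @param k Annotated genes in the query.
#' @return The tail probability in `(0, 1]` (`k = 0` gives exactly 1).
#' @examples
#' hypergeometric_tail(20, 5, 5, 5)  # 1 / choose(20, 5)
#' @export
hypergeometric_tail <- function(N, K, n, k) {
  stopifnot(length(N) == 1, length(K) == 1, length(n) == 1, length(k) == 1)
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(K, n))
    stop("require 0 <= K <= N, 0 <= n <= N, 0 <= k <= min(K, n)",
         call. = FALSE)
  if (k == 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric over-representation of gene sets
#'
#' Tests each annotation term for over-representation of a query gene set
#' against a background universe (by default the full measured matrix, the
#' "genome background" of an array experiment). Terms are intersected with
#' the background first; terms left empty are dropped with a log line.
#' The significance flag uses the raw p-value by default (`P < alpha`),
#' switchable to BH-adjusted p via `config$enrichment_adjust`.
#'
#' @param query Character vector of query gene ids; must be a subset of
#'   `background`.
#' @param gene_sets Named list of term gene-id vectors (see
#'   [read_gene_sets()]).
#' @param background Character vector of background gene ids.
#' @param config A [pipeline_config()] object.
#' @param empty_query `"error"` (default) to reject an empty query, or
#'   `"empty"` to return a zero-row table.
#' @return Data frame sorted by p-value with one row per tested term:
#'   `term_id`, `term_name`, `N`, `K`, `n`, `k`, `p_value`, `adjusted_p`,
#'   `enriched`.
#' @export
enrich_sets <- function(query, gene_sets, background,
                        config = pipeline_config(),
                        empty_query = c("error", "empty")) {
  empty_query <- match.arg(empty_query)
  query <- unique(query)
  background <- unique(background)
  stray <- setdiff(query, background)
  if (length(stray))
    stop("query genes absent from background: ",
         paste(head(stray, 5), collapse = ", "),
         if (length(stray) > 5) ", ...", call. = FALSE)
  if (!length(query) && empty_query == "error")
    stop("empty query gene set", call. = FALSE)
  desc <- attr(gene_sets, "description")
  if (is.null(desc)) desc <- setNames(names(gene_sets), names(gene_sets))
  restricted <- lapply(gene_sets, function(s) intersect(unique(s), background))
  keep <- lengths(restricted) >= 1
  if (any(!keep))
    lp_log("enrich_sets: dropping ", sum(!keep),
           " term(s) with no background genes")
  restricted <- restricted[keep]
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(restricted), function(id) {
    K <- length(restricted[[id]])
    k <- length(intersect(restricted[[id]], query))
    data.frame(term_id = id, term_name = unname(desc[id]),
               N = N, K = K, n = n, k = k,
               p_value = hypergeometric_tail(N, K, n, k),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(term_id = character(0), term_name = character(0),
               N = integer(0), K = integer(0), n = integer(0), k = integer(0),
               p_value = numeric(0), stringsAsFactors = FALSE)
  out$adjusted_p <- fdr_adjust(out$p_value)
  crit <- if (config$enrichment_adjust) out$adjusted_p else out$p_value
  out$enriched <- crit < config$enrichment_alpha
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  lp_log("enrich_sets: ", nrow(out), " terms tested, ",
         sum(out$enriched), " enriched at alpha ", config$enrichment_alpha)
  out
}
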