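#' Distance matrix over genes or samples
#'
#' Correlation distance (`1 - Pearson r`) is the default for gene
#' profiles; Euclidean distance the default for samples. The result has a
#' zero diagonal and is symmetric.
#'
#' @param matrix Numeric genes x samples matrix.
#' @param axis `"genes"` (rows) or `"samples"` (columns).
#' @param metric `"correlation"` or `"euclidean"`.
#' @return Symmetric non-negative matrix with item ids as dimnames.
#' @export
distance_matrix <- function(matrix, axis = c("genes", "samples"),
                            metric = c("correlation", "euclidean")) {
  axis <- match.arg(axis)
  metric <- match.arg(metric)
  m <- if (axis == "genes") matrix else t(matrix)
  if (nrow(m) < 2) stop("need at least 2 items to compute distances",
                        call. = FALSE)
  if (metric == "correlation") {
    vars <- apply(m, 1, var)
    if (any(vars == 0))
      stop("zero-variance profile under correlation metric: ",
           paste(head(rownames(m)[vars == 0], 5), collapse = ", "),
           call. = FALSE)
    d <- 1 - cor(t(m))
  } else {
    d <- as.matrix(dist(m, method = "euclidean"))
  }
  d[d < 0 & d > -1e-12] <- 0   # clip correlation rounding below zero
  diag(d) <- 0
  d
}

#' Agglomerative hierarchical clustering
#'
#' Standard agglomerative clustering via [stats::hclust()] with a
#' deterministic tie-break: items are pre-ordered lexicographically by id,
#' so equal-distance merges resolve to the smallest id pair and the result
#' is invariant to the row order of the input matrix.
#'
#' @param distances Symmetric distance matrix with dimnames (from
#'   [distance_matrix()]).
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return An object of class `hclust`.
#' @export
hierarchical_cluster <- function(distances,
                                 linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  stopifnot(is.matrix(distances))
  if (!isTRUE(all.equal(distances, t(distances), tolerance = 1e-8)))
    stop("distance matrix must be symmetric", call. = FALSE)
  if (is.null(rownames(distances)))
    rownames(distances) <- colnames(distances) <- paste0("item", seq_len(nrow(distances)))
  ord <- order(rownames(distances))
  d <- distances[ord, ord]
  hclust(as.dist(d), method = linkage)
}

#' Serialize a dendrogram as Newick
#'
#' @param hc An `hclust` object.
#' @return A Newick string (branch lengths from merge heights).
#' @export
as_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

#' Leaf sets of every internal dendrogram node
#'
#' @param hc An `hclust` object.
#' @return List of character vectors, one per merge, each the ids of the
#'   leaves under that node.
#' @export
dendrogram_clades <- function(hc) {
  n <- nrow(hc$merge)
  clades <- vector("list", n)
  for (i in seq_len(n)) {
    members <- unlist(lapply(hc$merge[i, ], function(j) {
      if (j < 0) hc$labels[-j] else clades[[j]]
    }))
    clades[[i]] <- members
  }
  clades
}

#' Are given item groups monophyletic in a dendrogram?
#'
#' Used to check replicate coherence: the three biological replicates of
#' one (accession, tissue, treatment) cell should form their own clade in
#' the sample dendrogram of a well-behaved experiment.
#'
#' @param hc An `hclust` object.
#' @param groups List of character vectors of leaf ids.
#' @return Logical vector, one per group: `TRUE` when some node's leaf set
#'   equals the group exactly (singleton groups are trivially `TRUE`).
#' @export
clades_present <- function(hc, groups) {
  clades <- lapply(dendrogram_clades(hc), sort)
  vapply(groups, function(g) {
    g <- sort(unique(g))
    if (length(g) <= 1) return(TRUE)
    any(vapply(clades, identical, TRUE, y = g))
  }, TRUE)
}

#' Two-way clustering of an expression matrix
#'
#' Clusters genes and samples with the configured metrics and linkage.
#' Optionally z-scores each gene row first (display scaling only; by
#' default distances are computed on the untransformed log2 values).
#'
#' @param matrix Numeric genes x samples matrix.
#' @param config A [pipeline_config()] object.
#' @param standardize_rows Logical; z-score rows before clustering.
#' @return List with `genes` and `samples` (`hclust` objects), the
#'   row/column orders, and Newick serializations.
#' @export
cluster_expression <- function(matrix, config = pipeline_config(),
                               standardize_rows = FALSE) {
  m <- matrix
  if (standardize_rows) {
    mu <- rowMeans(m)
    sd_ <- apply(m, 1, stats::sd)
    if (any(sd_ == 0)) stop("zero-variance gene row; cannot standardize",
                            call. = FALSE)
    m <- (m - mu) / sd_
  }
  hg <- hierarchical_cluster(
    distance_matrix(m, "genes", config$distance_genes), config$linkage)
  hs <- hierarchical_cluster(
    distance_matrix(m, "samples", config$distance_samples), config$linkage)
  lp_log("cluster_expression: ", nrow(m), " genes x ", ncol(m), " samples")
  list(genes = hg, samples = hs,
       gene_order = hg$labels[hg$order],
       sample_order = hs$labels[hs$order],
       newick_genes = as_newick(hg),
       newick_samples = as_newick(hs))
}
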