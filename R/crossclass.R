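#' Classify low-phosphate DEGs by their normal-phosphate pattern
#'
#' The core comparative procedure for inter-accession (tolerant vs
#' sensitive) and inter-tissue (root vs leaf) contrasts. Every DEG of the
#' low-phosphate contrast is assigned exactly one category from its
#' behavior in the matching normal-phosphate contrast:
#'
#' * `concordant` — also a DEG under normal phosphate, same direction;
#' * `opposite` — a DEG under normal phosphate, opposite direction;
#' * `rescued` — no difference under normal phosphate, and the
#'   low-phosphate fold change exceeds the rescue threshold (strictly more
#'   than 4-fold up, or below 1/4 for down-regulated DEGs);
#' * `dropped` — no difference under normal phosphate and below the
#'   rescue threshold.
#'
#' "No difference" defaults to failing any of the three DEG criteria under
#' normal phosphate (`config$normal_diff_rule = "deg_criteria"`); set
#' `"fold_only"` to require only a sub-threshold fold change.
#'
#' @param lowP_results,normalP_results Contrast-result data frames (from
#'   [run_contrast()]) for the same group pair under the two treatments.
#' @param config A [pipeline_config()] object.
#' @param comparison Label stored in the output (e.g. `"material_root"`).
#' @return A pattern-record data frame with one row per low-phosphate DEG:
#'   `gene_id`, `comparison`, `lowP_direction`, `normalP_status`
#'   (`same_direction` / `opposite_direction` / `no_difference`),
#'   `lowP_fold_change`, `category`.
#' @export
classify_patterns <- function(lowP_results, normalP_results,
                              config = pipeline_config(),
                              comparison = "comparison") {
  degs <- lowP_results[lowP_results$is_deg, , drop = FALSE]
  miss <- setdiff(degs$gene_id, normalP_results$gene_id)
  if (length(miss))
    stop("genes present under low P but missing from the normal-P table: ",
         paste(head(miss, 5), collapse = ", "),
         if (length(miss) > 5) ", ...", call. = FALSE)
  if (!nrow(degs)) {
    return(data.frame(gene_id = character(0), comparison = character(0),
                      lowP_direction = character(0),
                      normalP_status = character(0),
                      lowP_fold_change = numeric(0), category = character(0),
                      stringsAsFactors = FALSE))
  }
  np <- normalP_results[match(degs$gene_id, normalP_results$gene_id), ]
  np_differs <- if (config$normal_diff_rule == "deg_criteria") {
    np$is_deg
  } else {
    abs(np$log2_ratio) >= config$log2_ratio_threshold
  }
  np_dir <- ifelse(np$log2_ratio > 0, "up", "down")
  status <- ifelse(!np_differs, "no_difference",
                   ifelse(np_dir == degs$direction,
                          "same_direction", "opposite_direction"))
  log2_rescue <- log2(config$rescue_fold_threshold)
  rescued <- abs(degs$log2_ratio) > log2_rescue   # strict: larger than 4-fold
  category <- ifelse(status == "same_direction", "concordant",
                     ifelse(status == "opposite_direction", "opposite",
                            ifelse(rescued, "rescued", "dropped")))
  out <- data.frame(
    gene_id = degs$gene_id,
    comparison = comparison,
    lowP_direction = degs$direction,
    normalP_status = status,
    lowP_fold_change = degs$fold_change,
    category = category,
    stringsAsFactors = FALSE
  )
  lp_log("classify_patterns ", comparison, ": ", nrow(out), " low-P DEGs -> ",
         sum(category == "concordant"), " concordant, ",
         sum(category == "opposite"), " opposite, ",
         sum(category == "rescued"), " rescued, ",
         sum(category == "dropped"), " dropped")
  out
}

#' Assemble marked DEG sets from pattern records
#'
#' Marked DEGs are the genes retained by the pattern procedure: the
#' opposite-pattern genes united with the rescued genes; concordant and
#' dropped genes are excluded. Counts are reported per comparison and
#' pooled, both raw (with multiplicity across comparisons) and
#' non-redundant (distinct transcript ids).
#'
#' @param patterns A pattern-record data frame (possibly row-bound over
#'   several comparisons) from [classify_patterns()].
#' @return A list of class `"lp_deg_sets"`: `sets` (named list of gene-id
#'   vectors, one per comparison plus `"marked_all"`), `raw_total`,
#'   `nonredundant`, and `per_comparison` (data frame of per-comparison
#'   counts).
#' @export
marked_degs <- function(patterns) {
  marked <- patterns[patterns$category %in% c("opposite", "rescued"), ,
                     drop = FALSE]
  comps <- unique(as.character(patterns$comparison))
  sets <- lapply(comps, function(cm) {
    unique(marked$gene_id[marked$comparison == cm])
  })
  names(sets) <- if (length(comps)) paste0("marked_", comps) else character(0)
  per_comparison <- data.frame(
    comparison = as.character(comps),
    n_opposite = vapply(comps, function(cm)
      sum(marked$comparison == cm & marked$category == "opposite"), 0L),
    n_rescued = vapply(comps, function(cm)
      sum(marked$comparison == cm & marked$category == "rescued"), 0L),
    n_marked = vapply(comps, function(cm) sum(marked$comparison == cm), 0L),
    stringsAsFactors = FALSE, row.names = NULL
  )
  acc <- nonredundant_union(sets)
  out <- list(sets = c(sets, list(marked_all = sort(unique(marked$gene_id)))),
              raw_total = acc$raw_total,
              nonredundant = acc$distinct_count,
              per_comparison = per_comparison)
  class(out) <- "lp_deg_sets"
  lp_log("marked_degs: raw ", out$raw_total, ", non-redundant ",
         out$nonredundant)
  out
}

#' Union with non-redundancy accounting
#'
#' Gene identity is the full transcript-level identifier string, so two
#' transcripts of one locus (e.g. ids ending `.1` and `.2`) are distinct.
#'
#' @param sets A (possibly named) list of gene-id character vectors; each
#'   set is de-duplicated before counting.
#' @return List with `raw_total` (sum of set sizes), `distinct_count`
#'   (size of the union), and `duplicates` (data frame listing every gene
#'   appearing in more than one set, with the set names and multiplicity).
#' @export
nonredundant_union <- function(sets) {
  sets <- lapply(sets, unique)
  if (is.null(names(sets)) && length(sets))
    names(sets) <- paste0("set", seq_along(sets))
  raw_total <- sum(lengths(sets))
  all_genes <- unlist(sets, use.names = FALSE)
  distinct <- unique(all_genes)
  tab <- table(all_genes)
  dup_genes <- names(tab)[tab > 1]
  duplicates <- data.frame(
    gene_id = dup_genes,
    n_sets = as.integer(tab[dup_genes]),
    sets = vapply(dup_genes, function(g) {
      paste(names(sets)[vapply(sets, function(s) g %in% s, TRUE)],
            collapse = ",")
    }, ""),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(raw_total = raw_total, distinct_count = length(distinct),
       union = distinct, duplicates = duplicates)
}

#' Intersection of gene sets
#'
#' Exact, order-invariant multi-way set intersection.
#'
#' @param ... Two or more gene-id character vectors (or a single list of
#'   them).
#' @return List with `genes` (sorted intersection) and `cardinality`.
#' @export
overlap_genes <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]])) sets <- sets[[1]]
  if (length(sets) < 2) stop("need at least 2 sets", call. = FALSE)
  genes <- Reduce(intersect, lapply(sets, unique))
  list(genes = sort(genes), cardinality = length(genes))
}
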