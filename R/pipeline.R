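#' Run the full comparative profiling pipeline
#'
#' Orchestrates the whole workflow on one dataset, in the order the
#' analyses build on each other: between-array quantile normalization;
#' the four treatment contrasts (low P over normal P per accession x
#' tissue cell); the material and tissue contrast pairs under both
#' treatments; pattern classification with the four-fold rescue rule and
#' marked-set assembly per family; the overlap of the treatment DEG union
#' with both marked sets down to the common "active" genes; hypergeometric
#' enrichment of the common set (when annotation terms are supplied); and
#' two-way hierarchical clustering of the treatment DEG union. Results are
#' deterministic given `config$rng_seed`.
#'
#' @param config A [pipeline_config()] object.
#' @param matrix Genes x samples log2 expression matrix (see
#'   [read_expression_matrix()]).
#' @param sheet Sample sheet covering the matrix columns.
#' @param gene_sets Optional named list of annotation terms (see
#'   [read_gene_sets()]); `NULL` skips enrichment.
#' @param out_dir Optional directory; when given, per-stage TSV tables and
#'   a JSON cardinality summary (`summary.json`) are written there.
#' @param normalize Logical; quantile-normalize first (default `TRUE`).
#' @return List of class `"lp_report"`: `contrasts` (named list of
#'   contrast-result tables), `patterns`, `marked_material`,
#'   `marked_tissue`, `treatment_sets`, `overlaps`, `enrichment`,
#'   `clustering`, and `summary` (the nested cardinality list serialized
#'   to JSON).
#' @export
run_pipeline <- function(config, matrix, sheet, gene_sets = NULL,
                         out_dir = NULL, normalize = TRUE) {
  stopifnot(inherits(config, "lp_config"))
  validate_sample_sheet(sheet)
  if (!all(sheet$sample_id %in% colnames(matrix)))
    stop("pipeline stage 'input': matrix lacks sample columns", call. = FALSE)
  mat <- matrix[, sheet$sample_id, drop = FALSE]
  if (normalize) {
    mat <- with_stage("normalize", quantile_normalize(mat))
  }
  ct <- contrast_table()
  groups <- function(i) {
    list(exp = sheet_samples(sheet, ct$exp_accession[i], ct$exp_tissue[i],
                             ct$exp_treatment[i]),
         ctl = sheet_samples(sheet, ct$ctl_accession[i], ct$ctl_tissue[i],
                             ct$ctl_treatment[i]))
  }
  contrasts <- list()
  for (i in seq_len(nrow(ct))) {
    gr <- groups(i)
    contrasts[[ct$name[i]]] <- with_stage(
      paste0("detest:", ct$name[i]),
      run_contrast(mat, gr$exp, gr$ctl, config, name = ct$name[i]))
  }

  # treatment DEG sets and the non-redundant union
  tnames <- ct$name[ct$family == "treatment"]
  treat_sets <- list()
  for (cn in tnames) {
    res <- contrasts[[cn]]
    for (dir in c("up", "down")) {
      treat_sets[[paste(cn, dir, sep = "_")]] <-
        res$gene_id[res$direction == dir]
    }
  }
  treat_acc <- nonredundant_union(treat_sets)

  # pattern classification per comparison pair, then marked sets per family
  comps <- unique(stats::na.omit(ct$comparison))
  patterns <- do.call(rbind, lapply(comps, function(cm) {
    lowc <- ct$name[!is.na(ct$comparison) & ct$comparison == cm &
                      ct$treatment_arm == "lowP"]
    norc <- ct$name[!is.na(ct$comparison) & ct$comparison == cm &
                      ct$treatment_arm == "normalP"]
    with_stage(paste0("classify:", cm),
               classify_patterns(contrasts[[lowc]], contrasts[[norc]],
                                 config, comparison = cm))
  }))
  mk_material <- marked_degs(patterns[grepl("^material", patterns$comparison), ,
                                      drop = FALSE])
  mk_tissue <- marked_degs(patterns[grepl("^tissue", patterns$comparison), ,
                                    drop = FALSE])

  ov_material <- overlap_genes(treat_acc$union, mk_material$sets$marked_all)
  ov_tissue <- overlap_genes(treat_acc$union, mk_tissue$sets$marked_all)
  common <- overlap_genes(treat_acc$union, mk_material$sets$marked_all,
                          mk_tissue$sets$marked_all)

  enrichment <- NULL
  if (!is.null(gene_sets) && length(gene_sets) && common$cardinality > 0) {
    enrichment <- with_stage("enrich",
      enrich_sets(common$genes, gene_sets, rownames(mat), config))
  }

  clustering <- NULL
  if (treat_acc$distinct_count >= 2) {
    sub <- mat[treat_acc$union, , drop = FALSE]
    ok <- apply(sub, 1, var) > 0
    if (sum(ok) >= 2) {
      clustering <- with_stage("cluster",
        cluster_expression(sub[ok, , drop = FALSE], config))
    }
  }

  per_contrast <- lapply(contrasts, function(res)
    list(n_up = sum(res$direction == "up"),
         n_down = sum(res$direction == "down")))
  summary <- list(
    design = list(n_genes = nrow(mat), n_samples = ncol(mat)),
    treatment = list(
      per_contrast = per_contrast[tnames],
      raw_total = treat_acc$raw_total,
      nonredundant = treat_acc$distinct_count,
      n_duplicates = nrow(treat_acc$duplicates)),
    material = list(
      categories = pattern_counts(patterns, "^material"),
      raw_marked = mk_material$raw_total,
      nonredundant_marked = mk_material$nonredundant),
    tissue = list(
      categories = pattern_counts(patterns, "^tissue"),
      raw_marked = mk_tissue$raw_total,
      nonredundant_marked = mk_tissue$nonredundant),
    overlaps = list(treatment_material = ov_material$cardinality,
                    treatment_tissue = ov_tissue$cardinality,
                    common = common$cardinality),
    enrichment = if (is.null(enrichment)) NULL else
      list(n_terms = nrow(enrichment), n_enriched = sum(enrichment$enriched)),
    notes = paste("per-tissue and per-accession DEG totals are computed",
                  "from the per-contrast tables by set union, not taken",
                  "from any external tally")
  )
  report <- structure(list(contrasts = contrasts, patterns = patterns,
                           treatment_sets = treat_sets,
                           treatment_accounting = treat_acc,
                           marked_material = mk_material,
                           marked_tissue = mk_tissue,
                           overlaps = list(material = ov_material,
                                           tissue = ov_tissue,
                                           common = common),
                           enrichment = enrichment, clustering = clustering,
                           summary = summary),
                      class = "lp_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# run a stage, attaching the stage name to any error
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "': ", conditionMessage(e), call. = FALSE)
  })
}

pattern_counts <- function(patterns, prefix) {
  sel <- patterns[grepl(prefix, patterns$comparison), , drop = FALSE]
  out <- list()
  for (cm in sort(unique(sel$comparison))) {
    sub <- sel[sel$comparison == cm, ]
    out[[cm]] <- list(
      total = nrow(sub),
      concordant = sum(sub$category == "concordant"),
      opposite = sum(sub$category == "opposite"),
      rescued = sum(sub$category == "rescued"),
      dropped = sum(sub$category == "dropped"))
  }
  out
}

#' Write a pipeline report to disk
#'
#' One TSV per contrast, the pattern table, the marked sets, the overlap
#' report, the enrichment table (if computed), Newick dendrograms, and the
#' machine-readable JSON cardinality summary.
#'
#' @param report An `lp_report` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (cn in names(report$contrasts)) {
    write.table(report$contrasts[[cn]],
                file.path(out_dir, paste0("contrast_", cn, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(report$patterns, file.path(out_dir, "patterns.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  mk_mat <- report$marked_material$sets$marked_all
  mk_tis <- report$marked_tissue$sets$marked_all
  marked <- data.frame(
    family = c(rep("material", length(mk_mat)), rep("tissue", length(mk_tis))),
    gene_id = c(mk_mat, mk_tis), stringsAsFactors = FALSE)
  write.table(marked, file.path(out_dir, "marked_degs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  ov <- report$overlaps
  overlap_df <- data.frame(
    overlap = c("treatment_material", "treatment_tissue", "common"),
    cardinality = c(ov$material$cardinality, ov$tissue$cardinality,
                    ov$common$cardinality),
    genes = c(paste(ov$material$genes, collapse = ","),
              paste(ov$tissue$genes, collapse = ","),
              paste(ov$common$genes, collapse = ",")))
  write.table(overlap_df, file.path(out_dir, "overlaps.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$enrichment)) {
    write.table(report$enrichment, file.path(out_dir, "enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$clustering)) {
    writeLines(report$clustering$newick_genes,
               file.path(out_dir, "dendrogram_genes.nwk"))
    writeLines(report$clustering$newick_samples,
               file.path(out_dir, "dendrogram_samples.nwk"))
    write.table(data.frame(gene_id = report$clustering$gene_order),
                file.path(out_dir, "heatmap_gene_order.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(report$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(out_dir)
}
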