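#' Pipeline configuration
#'
#' Bundles every tunable threshold of the workflow with validation.
#' Defaults encode the study conventions: a DEG must show at least a
#' two-fold change (`|log2 ratio| >= 1`), FDR-adjusted significance below
#' 0.05, and complete biological triplicates; pattern rescue requires a
#' strictly larger than four-fold change under low phosphate.
#'
#' @param log2_ratio_threshold Non-negative log2 fold-change cutoff for the
#'   DEG call (default 1, i.e. two-fold).
#' @param fdr_alpha Significance level on the FDR-adjusted statistic
#'   (default 0.05).
#' @param rescue_fold_threshold Linear fold-change threshold of the rescue
#'   rule applied to low-phosphate contrasts (default 4; strict inequality).
#' @param enrichment_alpha Significance level for term enrichment
#'   (default 0.05).
#' @param permutations Maximum number of group relabelings for the
#'   permutation null; when the exhaustive count of balanced relabelings is
#'   smaller (20 for 3 vs 3), all of them are used.
#' @param rng_seed Integer seed controlling every stochastic step.
#' @param q_method `"sam"` (default) for the SAM median-false-positive
#'   q-value, or `"bh"` for Benjamini-Hochberg on pooled permutation
#'   p-values. See the methods vignette for why SAM q is the default at
#'   triplicate design sizes.
#' @param normal_diff_rule How "no expression difference under normal
#'   phosphate" is decided in pattern classification: `"deg_criteria"`
#'   (default; the gene fails any of the three DEG criteria) or
#'   `"fold_only"` (only `|log2 ratio| <` threshold).
#' @param enrichment_adjust Logical; if `TRUE` the enrichment flag uses
#'   BH-adjusted p-values, otherwise raw p-values (default, mirroring a
#'   raw `P < 0.05` rule).
#' @param linkage Agglomeration rule for hierarchical clustering:
#'   `"average"` (default), `"complete"` or `"single"`.
#' @param distance_genes,distance_samples Distance metric per axis:
#'   `"correlation"` or `"euclidean"`.
#' @param s0 Optional fixed SAM fudge factor; `NULL` (default) selects it
#'   by the coefficient-of-variation criterion via [choose_s0()].
#'
#' @return An object of class `"lp_config"` (a validated list).
#' @examples
#' cfg <- pipeline_config(fdr_alpha = 0.01)
#' cfg$rescue_fold_threshold
#' @export
pipeline_config <- function(log2_ratio_threshold = 1,
                            fdr_alpha = 0.05,
                            rescue_fold_threshold = 4,
                            enrichment_alpha = 0.05,
                            permutations = 1000L,
                            rng_seed = 1L,
                            q_method = c("sam", "bh"),
                            normal_diff_rule = c("deg_criteria", "fold_only"),
                            enrichment_adjust = FALSE,
                            linkage = c("average", "complete", "single"),
                            distance_genes = c("correlation", "euclidean"),
                            distance_samples = c("euclidean", "correlation"),
                            s0 = NULL) {
  stopifnot(is.numeric(log2_ratio_threshold), length(log2_ratio_threshold) == 1,
            log2_ratio_threshold >= 0)
  if (!is.numeric(fdr_alpha) || fdr_alpha <= 0 || fdr_alpha >= 1)
    stop("fdr_alpha must lie in (0, 1)", call. = FALSE)
  if (!is.numeric(enrichment_alpha) || enrichment_alpha <= 0 || enrichment_alpha >= 1)
    stop("enrichment_alpha must lie in (0, 1)", call. = FALSE)
  if (!is.numeric(rescue_fold_threshold) || rescue_fold_threshold <= 0)
    stop("rescue_fold_threshold must be positive", call. = FALSE)
  stopifnot(is.numeric(permutations), permutations >= 1)
  if (!is.null(s0)) stopifnot(is.numeric(s0), s0 >= 0)
  structure(list(
    log2_ratio_threshold = log2_ratio_threshold,
    fdr_alpha = fdr_alpha,
    rescue_fold_threshold = rescue_fold_threshold,
    enrichment_alpha = enrichment_alpha,
    permutations = as.integer(permutations),
    rng_seed = as.integer(rng_seed),
    q_method = match.arg(q_method),
    normal_diff_rule = match.arg(normal_diff_rule),
    enrichment_adjust = isTRUE(enrichment_adjust),
    linkage = match.arg(linkage),
    distance_genes = match.arg(distance_genes),
    distance_samples = match.arg(distance_samples),
    s0 = s0
  ), class = "lp_config")
}

#' Read a pipeline configuration from JSON or YAML
#'
#' Unknown keys are rejected so that typos in a config file fail loudly.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file whose keys are
#'   arguments of [pipeline_config()].
#' @return An `lp_config` object.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  values <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("unsupported config format: .", ext, call. = FALSE))
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(values), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(pipeline_config, values)
}

ACCESSIONS <- c("tolerant", "sensitive")
TISSUES    <- c("root", "leaf")
TREATMENTS <- c("normalP", "lowP")

#' Validate a sample sheet
#'
#' A sample sheet describes one array per row: `sample_id`, `accession`
#' (`tolerant`/`sensitive`), `tissue` (`root`/`leaf`), `treatment`
#' (`normalP`/`lowP`) and `replicate`. The canonical design has exactly
#' three biological replicates in each of the eight cells (24 arrays).
#'
#' @param sheet A data frame with the five columns above.
#' @return The validated data frame (invisibly unchanged).
#' @export
validate_sample_sheet <- function(sheet) {
  req <- c("sample_id", "accession", "tissue", "treatment", "replicate")
  miss <- setdiff(req, names(sheet))
  if (length(miss))
    stop("sample sheet lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(sheet$sample_id))
    stop("duplicated sample_id in sample sheet", call. = FALSE)
  if (!all(sheet$accession %in% ACCESSIONS))
    stop("accession must be one of: ", paste(ACCESSIONS, collapse = ", "), call. = FALSE)
  if (!all(sheet$tissue %in% TISSUES))
    stop("tissue must be one of: ", paste(TISSUES, collapse = ", "), call. = FALSE)
  if (!all(sheet$treatment %in% TREATMENTS))
    stop("treatment must be one of: ", paste(TREATMENTS, collapse = ", "), call. = FALSE)
  if (!is.numeric(sheet$replicate) || any(sheet$replicate < 1))
    stop("replicate must be a positive integer", call. = FALSE)
  cells <- table(factor(sheet$accession, ACCESSIONS),
                 factor(sheet$tissue, TISSUES),
                 factor(sheet$treatment, TREATMENTS))
  if (any(cells == 0))
    stop("every (accession, tissue, treatment) cell needs at least one replicate",
         call. = FALSE)
  sheet
}

#' Read / write a sample sheet TSV
#'
#' @param path File path.
#' @return `read_sample_sheet` returns a validated data frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_sample_sheet(sheet)
}

#' @rdname read_sample_sheet
#' @param sheet A sample sheet data frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  validate_sample_sheet(sheet)
  write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select sample ids from a sheet by design factors
#'
#' @param sheet A sample sheet.
#' @param accession,tissue,treatment Optional factor levels to filter on.
#' @return Character vector of matching `sample_id`s.
#' @export
sheet_samples <- function(sheet, accession = NULL, tissue = NULL, treatment = NULL) {
  keep <- rep(TRUE, nrow(sheet))
  if (!is.null(accession)) keep <- keep & sheet$accession %in% accession
  if (!is.null(tissue))    keep <- keep & sheet$tissue %in% tissue
  if (!is.null(treatment)) keep <- keep & sheet$treatment %in% treatment
  sheet$sample_id[keep]
}

#' Read an expression matrix TSV
#'
#' The file must have a header whose first column is `gene_id` followed by
#' sample ids, one gene per row, log2 intensities. The returned matrix is
#' aligned to the sample-sheet order and gene identifiers are preserved
#' verbatim, including transcript suffixes such as `".1"` / `".2"` — two
#' transcripts of one locus are distinct rows throughout the pipeline.
#'
#' @param path File path.
#' @param sheet Sample sheet; all of its `sample_id`s must be present as
#'   columns.
#' @return Numeric matrix, genes x samples, with a logical attribute
#'   `"normalized"` (FALSE on read).
#' @export
read_expression_matrix <- function(path, sheet) {
  validate_sample_sheet(sheet)
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
  if (names(raw)[1] != "gene_id")
    stop("expression matrix must start with a 'gene_id' column", call. = FALSE)
  miss <- setdiff(sheet$sample_id, names(raw)[-1])
  if (length(miss))
    stop("expression matrix is missing sample column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  gene_ids <- raw$gene_id
  if (anyDuplicated(gene_ids))
    stop("duplicated gene_id in expression matrix", call. = FALSE)
  vals <- as.matrix(raw[, sheet$sample_id, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = dimnames(vals)))
  bad <- which(is.na(num) & !is.na(vals) & vals != "NA", arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                 vals[bad[1, 1], bad[1, 2]], gene_ids[bad[1, 1]],
                 colnames(vals)[bad[1, 2]]), call. = FALSE)
  }
  rownames(num) <- gene_ids
  attr(num, "normalized") <- FALSE
  num
}

#' @rdname read_expression_matrix
#' @param matrix Numeric genes x samples matrix with dimnames.
#' @export
write_expression_matrix <- function(matrix, path) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)), !is.null(colnames(matrix)))
  df <- data.frame(gene_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each line carries a term id, a description, and one gene per remaining
#' tab-separated field. Duplicate genes within a term are collapsed; a term
#' with no genes is rejected.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors; `attr(, "description")` holds
#'   the term descriptions.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- list()
    attr(out, "description") <- character(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("GMT line ", which(nf < 3)[1],
         " has fewer than 3 fields (term, description, genes...)", call. = FALSE)
  }
  ids <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(ids))
    stop("duplicated term id in GMT: ", ids[duplicated(ids)][1], call. = FALSE)
  desc <- vapply(fields, `[[`, "", 2)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  attr(sets, "description") <- setNames(desc, ids)
  sets
}

#' @rdname read_gene_sets
#' @param gene_sets Named list of character vectors; optional
#'   `"description"` attribute.
#' @export
write_gene_sets <- function(gene_sets, path) {
  desc <- attr(gene_sets, "description")
  if (is.null(desc)) desc <- setNames(rep("na", length(gene_sets)), names(gene_sets))
  lines <- vapply(names(gene_sets), function(id) {
    paste(c(id, desc[[id]], gene_sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
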