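#' Quantile normalization between arrays
#'
#' Forces every array (column) to share one empirical intensity
#' distribution — the between-array step of the RMA workflow. After
#' normalization the sorted value vector of each column is identical;
#' tied values within a column receive the mean of the reference values
#' over their rank span, which makes the result deterministic and
#' independent of input row order. The heavy lifting is delegated to
#' [limma::normalizeQuantiles()].
#'
#' @param matrix Numeric genes x samples matrix (log2 scale), at least two
#'   columns, no missing values.
#' @return Matrix of the same shape and dimnames with attribute
#'   `"normalized"` set to `TRUE`.
#' @examples
#' m <- cbind(a = c(1, 3), b = c(2, 4))
#' rownames(m) <- c("g1", "g2")
#' quantile_normalize(m)  # both columns become (1.5, 3.5)
#' @export
quantile_normalize <- function(matrix) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (ncol(matrix) < 2)
    stop("quantile normalization needs at least 2 samples", call. = FALSE)
  if (anyNA(matrix) || any(!is.finite(matrix)))
    stop("expression matrix contains missing or non-finite values", call. = FALSE)
  out <- limma::normalizeQuantiles(matrix, ties = TRUE)
  dimnames(out) <- dimnames(matrix)
  attr(out, "normalized") <- TRUE
  lp_log("quantile_normalize: ", nrow(out), " genes x ", ncol(out), " samples")
  out
}

#' Median-polish summarization of probe blocks
#'
#' Summarizes a probe x sample intensity matrix into one value per gene and
#' sample, the way RMA condenses the 16-19 probes of a probe set: a
#' two-way additive decomposition (overall + probe effect + sample effect
#' + residual) fitted by median polish on each gene's probe block. The
#' reported gene value is overall effect + column (sample) effect, which is
#' robust to a single outlying probe cell.
#'
#' @param probe_matrix Numeric probes x samples matrix with probe ids as
#'   rownames.
#' @param probe_to_gene Named character vector mapping every probe id to
#'   exactly one gene id.
#' @param tol Convergence tolerance on the median polish (default 1e-6).
#' @param max_iter Maximum polish iterations (default 20).
#' @return Numeric genes x samples matrix (one row per distinct gene, in
#'   first-appearance order) with attribute `"normalized"` preserved as
#'   `FALSE`.
#' @export
median_polish_summarize <- function(probe_matrix, probe_to_gene,
                                    tol = 1e-6, max_iter = 20) {
  stopifnot(is.matrix(probe_matrix), !is.null(rownames(probe_matrix)))
  unmapped <- setdiff(rownames(probe_matrix), names(probe_to_gene))
  if (length(unmapped))
    stop("probes without gene mapping: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  genes <- probe_to_gene[rownames(probe_matrix)]
  gene_order <- unique(genes)
  out <- matrix(NA_real_, length(gene_order), ncol(probe_matrix),
                dimnames = list(gene_order, colnames(probe_matrix)))
  for (g in gene_order) {
    block <- probe_matrix[genes == g, , drop = FALSE]
    if (nrow(block) == 1) {
      # degenerate one-probe block: overall = row median, col effects are
      # the centred values, so overall + col reproduces the probe row
      med <- median(block[1, ])
      out[g, ] <- med + (block[1, ] - med)
    } else {
      fit <- suppressWarnings(
        medpolish(block, eps = tol, maxiter = max_iter, trace.iter = FALSE))
      out[g, ] <- fit$overall + fit$col
    }
  }
  attr(out, "normalized") <- FALSE
  lp_log("median_polish_summarize: ", nrow(probe_matrix), " probes -> ",
         nrow(out), " genes")
  out
}
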