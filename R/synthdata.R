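#' Canonical contrast table of the 2x2x2 design
#'
#' Twelve two-group contrasts, each comparing two design cells:
#' four treatment contrasts (low P over normal P within each accession x
#' tissue cell), four material contrasts (tolerant over sensitive within
#' each tissue, separately under each treatment) and four tissue contrasts
#' (root over leaf within each accession, under each treatment). Material
#' and tissue contrasts come in low-P/normal-P pairs that feed the pattern
#' classification; the `comparison` column names the pair.
#'
#' @return Data frame with columns `name`, `family`, `comparison`,
#'   `treatment_arm` and the six cell selectors
#'   (`exp_accession`, ..., `ctl_treatment`).
#' @export
contrast_table <- function() {
  rows <- list()
  for (a in ACCESSIONS) for (t in TISSUES) {
    rows[[length(rows) + 1]] <- data.frame(
      name = paste("treatment", a, t, sep = "_"), family = "treatment",
      comparison = NA_character_, treatment_arm = NA_character_,
      exp_accession = a, exp_tissue = t, exp_treatment = "lowP",
      ctl_accession = a, ctl_tissue = t, ctl_treatment = "normalP",
      stringsAsFactors = FALSE)
  }
  for (t in TISSUES) for (tr in TREATMENTS) {
    rows[[length(rows) + 1]] <- data.frame(
      name = paste("material", t, tr, sep = "_"), family = "material",
      comparison = paste0("material_", t), treatment_arm = tr,
      exp_accession = "tolerant", exp_tissue = t, exp_treatment = tr,
      ctl_accession = "sensitive", ctl_tissue = t, ctl_treatment = tr,
      stringsAsFactors = FALSE)
  }
  for (a in ACCESSIONS) for (tr in TREATMENTS) {
    rows[[length(rows) + 1]] <- data.frame(
      name = paste("tissue", a, tr, sep = "_"), family = "tissue",
      comparison = paste0("tissue_", a), treatment_arm = tr,
      exp_accession = a, exp_tissue = "root", exp_treatment = tr,
      ctl_accession = a, ctl_tissue = "leaf", ctl_treatment = tr,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

cell_name <- function(accession, tissue, treatment) {
  paste(accession, tissue, treatment, sep = "_")
}

design_cells <- function() {
  cells <- expand.grid(accession = ACCESSIONS, tissue = TISSUES,
                       treatment = TREATMENTS, stringsAsFactors = FALSE)
  cells$cell <- cell_name(cells$accession, cells$tissue, cells$treatment)
  cells
}

#' Build the canonical 24-array sample sheet
#'
#' @param replicates Replicates per design cell (default 3).
#' @return A validated sample sheet data frame (24 rows for the default).
#' @export
canonical_sample_sheet <- function(replicates = 3) {
  cells <- design_cells()
  sheet <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(
      sample_id = paste(cells$cell[i], paste0("rep", seq_len(replicates)),
                        sep = "_"),
      accession = cells$accession[i], tissue = cells$tissue[i],
      treatment = cells$treatment[i], replicate = seq_len(replicates),
      stringsAsFactors = FALSE)
  }))
  rownames(sheet) <- NULL
  validate_sample_sheet(sheet)
}

#' Define a planted effect block
#'
#' A block is a group of genes sharing one planted shift pattern. Each
#' component draws, per gene, a single log2 effect uniformly from `range`
#' and adds it to every listed design cell, so one component models one
#' coherent response (e.g. "induced by low P in all cells"). Effect ranges
#' must stay outside `(-1, 1)` so planted genes clear the two-fold DEG
#' criterion in expectation.
#'
#' @param label Block label recorded in the planted truth.
#' @param n Number of genes.
#' @param components List of `list(cells = <cell names>, range = c(lo, hi))`.
#' @return A validated block definition.
#' @export
effect_block <- function(label, n, components) {
  cells <- design_cells()$cell
  for (cp in components) {
    if (!all(cp$cells %in% cells))
      stop("unknown design cell in block '", label, "'", call. = FALSE)
    if (cp$range[1] > cp$range[2])
      stop("effect range must be ordered (lo, hi)", call. = FALSE)
    if (!(cp$range[1] >= 1 || cp$range[2] <= -1))
      stop("effect range of block '", label,
           "' must exclude (-1, 1) on the log2 scale", call. = FALSE)
  }
  list(label = label, n = as.integer(n), components = components)
}

#' Scenario specification for the synthetic-data generator
#'
#' @param n_genes Total genes on the synthetic array (default 6000, which
#'   puts the 151 default planted genes at ~2.5% of the array — a DEG
#'   fraction small enough for between-array normalization to be valid, as
#'   on a real chip).
#' @param blocks List of [effect_block()] definitions; genes not covered by
#'   any block are nulls. Defaults to [default_blocks()].
#' @param noise_sd Per-replicate additive Gaussian noise on the log2 scale
#'   (default 0.25, a typical post-normalization replicate scatter).
#' @param baseline_mean,baseline_sd Gaussian parameters of per-gene
#'   baseline log2 intensity (defaults 8 and 2, a typical chip dynamic
#'   range).
#' @param array_offset_sd Standard deviation of a per-array additive log2
#'   offset (default 0.3), emulating the between-array "abiologic"
#'   variation that quantile normalization removes.
#' @param rng_seed Integer seed.
#' @return An object of class `"lp_scenario"`.
#' @export
scenario_spec <- function(n_genes = 6000, blocks = default_blocks(),
                          noise_sd = 0.25, baseline_mean = 8,
                          baseline_sd = 2, array_offset_sd = 0.3,
                          rng_seed = 1L) {
  stopifnot(n_genes >= 1, noise_sd > 0, baseline_sd >= 0,
            array_offset_sd >= 0)
  total <- sum(vapply(blocks, function(b) b$n, 0L))
  if (total > n_genes)
    stop("block gene counts (", total, ") exceed n_genes (", n_genes, ")",
         call. = FALSE)
  structure(list(n_genes = as.integer(n_genes), blocks = blocks,
                 noise_sd = noise_sd, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd,
                 array_offset_sd = array_offset_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "lp_scenario")
}

#' Default planted blocks of the study-design scenario
#'
#' Emulates the qualitative structure of a low-phosphate experiment:
#' a global low-P response (both directions), root-specific and
#' tolerant-accession-specific responses at rescued (> 4-fold) and dropped
#' (2-4-fold) magnitudes, accession differences present under both
#' treatments (concordant), treatment-flipped accession/tissue differences
#' (opposite), and a block of "active" genes induced only in the tolerant
#' root under low P — the genes every comparison family should converge on.
#' Up-regulation magnitudes stay within log2 2-5.08 (linear 4-33.8).
#'
#' @return List of [effect_block()]s (151 planted genes).
#' @export
default_blocks <- function() {
  lowP <- cell_name(rep(ACCESSIONS, each = 2), rep(TISSUES, 2), "lowP")
  root_lowP <- cell_name(ACCESSIONS, "root", "lowP")
  tol_lowP <- cell_name("tolerant", TISSUES, "lowP")
  list(
    effect_block("global_up", 40,
      list(list(cells = lowP, range = c(2, 5.078)))),
    effect_block("global_down", 20,
      list(list(cells = lowP, range = c(-3.18, -2)))),
    effect_block("root_up", 20,
      list(list(cells = root_lowP, range = c(2.6, 3.8)))),
    effect_block("root_up_weak", 10,
      list(list(cells = root_lowP, range = c(1.3, 1.7)))),
    effect_block("tolerant_up", 16,
      list(list(cells = tol_lowP, range = c(2.6, 3.8)))),
    effect_block("tolerant_up_weak", 10,
      list(list(cells = tol_lowP, range = c(1.3, 1.7)))),
    effect_block("active_root_tolerant", 12,
      list(list(cells = "tolerant_root_lowP", range = c(2.6, 3.8)))),
    effect_block("active_root_tolerant_down", 6,
      list(list(cells = "tolerant_root_lowP", range = c(-3.8, -2.6)))),
    effect_block("material_concordant_root", 10,
      list(list(cells = cell_name("tolerant", "root", TREATMENTS),
                range = c(2.2, 3.4)))),
    effect_block("material_opposite_root", 4,
      list(list(cells = "tolerant_root_lowP", range = c(2.6, 3.4)),
           list(cells = "tolerant_root_normalP", range = c(-2.5, -1.5)))),
    effect_block("tissue_opposite_tolerant", 3,
      list(list(cells = "tolerant_root_lowP", range = c(2.6, 3.4)),
           list(cells = "tolerant_leaf_normalP", range = c(1.5, 2.5))))
  )
}

#' A scenario with no planted effects
#'
#' @inheritParams scenario_spec
#' @return An `lp_scenario` with an empty block list.
#' @export
scenario_null <- function(n_genes = 6000, noise_sd = 0.25, rng_seed = 1L) {
  scenario_spec(n_genes = n_genes, blocks = list(), noise_sd = noise_sd,
                rng_seed = rng_seed)
}

#' Simulate a full synthetic dataset with planted truth
#'
#' Draws per-gene baselines, adds the planted cell shifts of the scenario
#' blocks, overlays independent per-replicate Gaussian noise on the log2
#' scale, and finally adds one additive offset per array (the "abiologic"
#' between-array variation removed by quantile normalization).
#' The planted truth records, per gene, the block label, the
#' shift applied to each design cell, and the exact (noise-free) log2
#' ratio of all twelve canonical contrasts.
#'
#' @param spec An [scenario_spec()] object.
#' @return List with `matrix` (genes x 24 samples, log2), `sheet`
#'   (canonical sample sheet), and `truth` (class `"lp_truth"`).
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "lp_scenario"))
  old <- local_seed(spec$rng_seed)
  on.exit(restore_seed(old), add = TRUE)
  sheet <- canonical_sample_sheet()
  cells <- design_cells()
  g <- spec$n_genes
  gene_ids <- sprintf("SYN%06d", seq_len(g))
  delta <- matrix(0, g, nrow(cells), dimnames = list(gene_ids, cells$cell))
  block_lab <- rep("null", g)
  cursor <- 0L
  for (b in spec$blocks) {
    idx <- cursor + seq_len(b$n)
    block_lab[idx] <- b$label
    for (cp in b$components) {
      e <- runif(b$n, cp$range[1], cp$range[2])
      for (cl in cp$cells) delta[idx, cl] <- delta[idx, cl] + e
    }
    cursor <- cursor + b$n
  }
  baseline <- rnorm(g, spec$baseline_mean, spec$baseline_sd)
  mat <- matrix(NA_real_, g, nrow(sheet),
                dimnames = list(gene_ids, sheet$sample_id))
  sample_cell <- cell_name(sheet$accession, sheet$tissue, sheet$treatment)
  offsets <- rnorm(nrow(sheet), 0, spec$array_offset_sd)
  for (j in seq_len(nrow(sheet))) {
    mat[, j] <- baseline + delta[, sample_cell[j]] +
      rnorm(g, 0, spec$noise_sd) + offsets[j]
  }
  attr(mat, "normalized") <- FALSE
  ct <- contrast_table()
  ratios <- vapply(seq_len(nrow(ct)), function(i) {
    delta[, cell_name(ct$exp_accession[i], ct$exp_tissue[i],
                      ct$exp_treatment[i])] -
      delta[, cell_name(ct$ctl_accession[i], ct$ctl_tissue[i],
                        ct$ctl_treatment[i])]
  }, numeric(g))
  colnames(ratios) <- ct$name
  truth <- structure(list(gene_id = gene_ids, block = block_lab,
                          delta = delta, ratios = ratios, spec = spec),
                     class = "lp_truth")
  lp_log("simulate_dataset: ", g, " genes x ", nrow(sheet), " samples, ",
         sum(block_lab != "null"), " planted genes")
  list(matrix = mat, sheet = sheet, truth = truth)
}

#' Planted DEG status of a contrast
#'
#' @param truth An `lp_truth` object.
#' @param contrast A contrast name from [contrast_table()].
#' @param threshold Log2 ratio threshold (default 1).
#' @return Character vector (`"up"`, `"down"`, `"none"`) named by gene id.
#' @export
truth_status <- function(truth, contrast, threshold = 1) {
  r <- truth$ratios[, contrast]
  setNames(ifelse(r >= threshold, "up",
                  ifelse(r <= -threshold, "down", "none")),
           truth$gene_id)
}

# Noise-free pattern rules, kept deliberately separate from
# classify_patterns(): status from exact ratios, category from the
# concordant/opposite/rescued/dropped convention.
truth_patterns_one <- function(truth, comparison, config = pipeline_config()) {
  ct <- contrast_table()
  lowc <- ct$name[!is.na(ct$comparison) & ct$comparison == comparison &
                    ct$treatment_arm == "lowP"]
  norc <- ct$name[!is.na(ct$comparison) & ct$comparison == comparison &
                    ct$treatment_arm == "normalP"]
  r1 <- truth$ratios[, lowc]
  r0 <- truth$ratios[, norc]
  thr <- config$log2_ratio_threshold
  in_cmp <- abs(r1) >= thr
  dir1 <- ifelse(r1 > 0, "up", "down")
  status <- ifelse(abs(r0) < thr, "no_difference",
                   ifelse(sign(r0) == sign(r1), "same_direction",
                          "opposite_direction"))
  category <- ifelse(status == "same_direction", "concordant",
                     ifelse(status == "opposite_direction", "opposite",
                            ifelse(abs(r1) > log2(config$rescue_fold_threshold),
                                   "rescued", "dropped")))
  data.frame(gene_id = truth$gene_id[in_cmp], comparison = comparison,
             lowP_direction = dir1[in_cmp],
             normalP_status = status[in_cmp],
             lowP_fold_change = 2^r1[in_cmp],
             category = category[in_cmp],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Planted pattern records of the four comparisons
#'
#' Applies the category rules to the exact planted ratios — the noise-free
#' reference against which [classify_patterns()] output is checked.
#'
#' @param truth An `lp_truth` object.
#' @param config A [pipeline_config()] object.
#' @return Pattern-record data frame over the four comparisons
#'   (material_root, material_leaf, tissue_tolerant, tissue_sensitive).
#' @export
truth_patterns <- function(truth, config = pipeline_config()) {
  comps <- unique(stats::na.omit(contrast_table()$comparison))
  do.call(rbind, lapply(comps, truth_patterns_one, truth = truth,
                        config = config))
}

#' Planted set-accounting summary
#'
#' The exact cardinalities the pipeline should report on noise-free data:
#' per-treatment-contrast DEG counts, the non-redundant treatment DEG
#' union, marked-set counts per family, and the overlap/common-gene
#' cardinalities.
#'
#' @inheritParams truth_patterns
#' @return Nested list mirroring the `summary` element of [run_pipeline()].
#' @export
truth_summary <- function(truth, config = pipeline_config()) {
  ct <- contrast_table()
  tnames <- ct$name[ct$family == "treatment"]
  status <- lapply(tnames, truth_status, truth = truth,
                   threshold = config$log2_ratio_threshold)
  names(status) <- tnames
  treat_sets <- list()
  for (cn in tnames) for (dir in c("up", "down")) {
    treat_sets[[paste(cn, dir, sep = "_")]] <-
      truth$gene_id[status[[cn]] == dir]
  }
  acc <- nonredundant_union(treat_sets)
  pats <- truth_patterns(truth, config)
  mk_mat <- marked_degs(pats[grepl("^material", pats$comparison), ])
  mk_tis <- marked_degs(pats[grepl("^tissue", pats$comparison), ])
  treat_union <- acc$union
  ov_mat <- overlap_genes(treat_union, mk_mat$sets$marked_all)
  ov_tis <- overlap_genes(treat_union, mk_tis$sets$marked_all)
  common <- overlap_genes(treat_union, mk_mat$sets$marked_all,
                          mk_tis$sets$marked_all)
  list(
    treatment = list(
      per_contrast = lapply(status, function(s)
        list(n_up = sum(s == "up"), n_down = sum(s == "down"))),
      raw_total = acc$raw_total, nonredundant = acc$distinct_count),
    material = list(raw_marked = mk_mat$raw_total,
                    nonredundant_marked = mk_mat$nonredundant),
    tissue = list(raw_marked = mk_tis$raw_total,
                  nonredundant_marked = mk_tis$nonredundant),
    overlaps = list(treatment_material = ov_mat$cardinality,
                    treatment_tissue = ov_tis$cardinality,
                    common = common$cardinality)
  )
}

#' Synthetic annotation terms with planted over-representation
#'
#' Samples term gene sets from a universe, weighting genes of a designated
#' target subset by per-term odds: odds 1 gives null terms, odds above 1
#' plants over-representation of the target among that term's genes.
#'
#' @param universe Character vector of gene ids (non-empty).
#' @param n_terms Number of terms (>= 1).
#' @param target Designated gene subset (default empty: all terms null).
#' @param odds Scalar or per-term vector (recycled) of sampling odds for
#'   target genes.
#' @param term_size Integer range of term sizes, drawn uniformly.
#' @param rng_seed Integer seed.
#' @return Named list of gene-id vectors (`T001`, `T002`, ...) with a
#'   `"description"` attribute, writable via [write_gene_sets()].
#' @export
simulate_annotation <- function(universe, n_terms, target = character(0),
                                odds = 1, term_size = c(10, 40),
                                rng_seed = 1L) {
  if (!length(universe)) stop("empty gene universe", call. = FALSE)
  if (n_terms < 1) stop("n_terms must be >= 1", call. = FALSE)
  universe <- unique(universe)
  odds <- rep_len(odds, n_terms)
  old <- local_seed(rng_seed)
  on.exit(restore_seed(old), add = TRUE)
  w_base <- rep(1, length(universe))
  in_target <- universe %in% target
  sets <- lapply(seq_len(n_terms), function(j) {
    w <- w_base
    w[in_target] <- odds[j]
    size <- if (term_size[1] == term_size[2]) term_size[1] else
      sample(seq(term_size[1], term_size[2]), 1)
    size <- min(size, length(universe))
    sample(universe, size, prob = w)
  })
  names(sets) <- sprintf("T%03d", seq_len(n_terms))
  attr(sets, "description") <- setNames(
    ifelse(odds > 1, sprintf("planted term (odds %.3g)", odds),
           "null term"), names(sets))
  sets
}

# --- fixtures engineered to the printed multiplicities -----------------

#' Synthetic DEG sets with the printed treatment-contrast multiplicities
#'
#' Deterministic gene sets for the five non-empty treatment-contrast DEG
#' lists (257 and 41 up/down in the tolerant root, 11 up in the tolerant
#' leaf, 3 and 7 down in the sensitive root and leaf), with exactly two
#' cross-set shared transcripts: one down-regulated transcript common to
#' the root sets of both accessions, and one up-regulated transcript
#' common to the root and leaf sets of the tolerant accession. Gene ids
#' are synthetic (`SYN...`) and transcript-suffixed.
#'
#' @return List with `sets` (named list of gene-id vectors), and
#'   `shared` (the two shared ids).
#' @export
simulate_table1_fixture <- function() {
  mk <- function(prefix, n) sprintf("%s%04d.1", prefix, seq_len(n))
  shared_up <- "SYNT1SHAREDUP.1"     # up in tolerant root and tolerant leaf
  shared_down <- "SYNT1SHAREDDN.2"   # down in roots of both accessions
  sets <- list(
    treatment_tolerant_root_up   = c(mk("SYNT1TRU", 256), shared_up),
    treatment_tolerant_root_down = c(mk("SYNT1TRD", 40), shared_down),
    treatment_tolerant_leaf_up   = c(mk("SYNT1TLU", 10), shared_up),
    treatment_sensitive_root_down = c(mk("SYNT1SRD", 2), shared_down),
    treatment_sensitive_leaf_down = mk("SYNT1SLD", 7)
  )
  list(sets = sets, shared = c(shared_up, shared_down))
}

# per-comparison/direction category multiplicities of the cross-accession
# and cross-tissue fixture; concordant counts are only filled where the
# running text corroborates them, otherwise 0 (synthetic convention).
table2_layout <- function() {
  rbind(
    data.frame(comparison = "material_root", direction = "up",
               concordant = 941, opposite = 10, rescued = 93, dropped = 733),
    data.frame(comparison = "material_leaf", direction = "up",
               concordant = 0, opposite = 1, rescued = 40, dropped = 935),
    data.frame(comparison = "material_root", direction = "down",
               concordant = 0, opposite = 0, rescued = 14, dropped = 310),
    data.frame(comparison = "material_leaf", direction = "down",
               concordant = 0, opposite = 0, rescued = 38, dropped = 488),
    data.frame(comparison = "tissue_tolerant", direction = "up",
               concordant = 5137, opposite = 1, rescued = 97, dropped = 1135),
    data.frame(comparison = "tissue_sensitive", direction = "up",
               concordant = 0, opposite = 0, rescued = 63, dropped = 1144),
    data.frame(comparison = "tissue_tolerant", direction = "down",
               concordant = 0, opposite = 0, rescued = 19, dropped = 874),
    data.frame(comparison = "tissue_sensitive", direction = "down",
               concordant = 0, opposite = 0, rescued = 73, dropped = 1002)
  )
}

#' Synthetic pattern fixture with the printed category multiplicities
#'
#' Builds, for each of the four inter-accession/inter-tissue comparisons,
#' paired low-P and normal-P contrast-result tables whose pattern
#' classification reproduces the reference category multiplicities
#' exactly: e.g. 941 concordant / 10 opposite / 826 unchanged (93 of them
#' above four-fold, hence rescued) for up-regulation in the root material
#' comparison, 40-14-38 rescued in the remaining material blocks, and
#' 97-63-19-73 rescued in the tissue blocks, with exactly one rescued
#' transcript shared between the root and leaf material comparisons.
#' Concordant counts without a corroborated reference value are set to 0.
#'
#' Fold changes are placed deterministically: 2.5 on the log2 scale for
#' rescued genes (5.7-fold), 1.5 for dropped (2.8-fold, below the 4-fold
#' rescue bar) and concordant/opposite genes.
#'
#' @return List with `contrasts` (per comparison, `lowP` and `normalP`
#'   contrast-result data frames), `truth` (the intended pattern-record
#'   table), `layout` (the multiplicity table) and `shared` (the shared
#'   gene id).
#' @export
simulate_table2_fixture <- function() {
  layout <- table2_layout()
  shared <- "SYNT2SHARED.1"
  comps <- unique(layout$comparison)
  truth_rows <- list()
  contrasts <- list()
  for (cm in comps) {
    lay <- layout[layout$comparison == cm, ]
    gene_id <- character(0); direction <- character(0); category <- character(0)
    for (i in seq_len(nrow(lay))) {
      for (cat in c("concordant", "opposite", "rescued", "dropped")) {
        n <- lay[[cat]][i]
        if (!n) next
        ids <- sprintf("SYNT2.%s.%s%s%05d.1", cm,
                       toupper(substr(lay$direction[i], 1, 1)),
                       toupper(substr(cat, 1, 3)), seq_len(n))
        # plant the one shared rescued-up transcript across the two
        # material comparisons
        if (cat == "rescued" && lay$direction[i] == "up" &&
            cm %in% c("material_root", "material_leaf")) ids[1] <- shared
        gene_id <- c(gene_id, ids)
        direction <- c(direction, rep(lay$direction[i], n))
        category <- c(category, rep(cat, n))
      }
    }
    sgn <- ifelse(direction == "up", 1, -1)
    low_ratio <- sgn * ifelse(category == "rescued", 2.5, 1.5)
    norm_ratio <- ifelse(category == "concordant", sgn * 1.5,
                         ifelse(category == "opposite", -sgn * 1.5, 0.2))
    norm_sig <- category %in% c("concordant", "opposite")
    mk_tbl <- function(ratio, sig) {
      df <- data.frame(
        gene_id = gene_id, contrast = cm,
        mean_experimental = 8 + ratio, mean_control = 8,
        log2_ratio = ratio, fold_change = 2^ratio,
        d_statistic = ifelse(sig, sign(ratio) * 10, ratio),
        p_value = ifelse(sig, 1e-4, 0.6),
        q_sam = ifelse(sig, 1e-3, 0.8), q_bh = ifelse(sig, 1e-3, 0.8),
        q_value = ifelse(sig, 1e-3, 0.8),
        n_complete_replicates = 3L, stringsAsFactors = FALSE)
      call_degs(df)
    }
    contrasts[[cm]] <- list(lowP = mk_tbl(low_ratio, TRUE),
                            normalP = mk_tbl(norm_ratio, norm_sig))
    truth_rows[[cm]] <- data.frame(
      gene_id = gene_id, comparison = cm, lowP_direction = direction,
      normalP_status = ifelse(category == "concordant", "same_direction",
                              ifelse(category == "opposite",
                                     "opposite_direction", "no_difference")),
      lowP_fold_change = 2^low_ratio, category = category,
      stringsAsFactors = FALSE)
  }
  list(contrasts = contrasts, truth = do.call(rbind, truth_rows),
       layout = layout, shared = shared)
}
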