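---
title: "Methods: comparative expression profiling under low-phosphate stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative expression profiling under low-phosphate stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lowpdeg)
```

## The design and the questions

The package targets a 2 × 2 × 2 factorial microarray design: two soybean
accessions with contrasting phosphate-starvation tolerance, two tissues
(root, leaf), two phosphate treatments (normal, low), three biological
replicates per cell — 24 arrays. Three families of two-group contrasts
are informative:

* **treatment** contrasts (low P / normal P within one accession ×
  tissue cell) isolate the starvation response of each material;
* **material** contrasts (tolerant / sensitive within a tissue, under
  each treatment) isolate accession differences;
* **tissue** contrasts (root / leaf within an accession, under each
  treatment) isolate organ differences.

All ratios are oriented experimental over control: low P over normal P,
tolerant over sensitive, root over leaf. The analysis narrows these
twelve contrasts down to a single list of *common active genes*: genes
that respond to low phosphate *and* distinguish the accessions *and*
distinguish the tissues under starvation.

## Differential expression

Each contrast is tested with a SAM-style moderated statistic
`d = (mean_exp − mean_ctl) / (s + s0)`, where `s` is the pooled standard
error of the mean difference and `s0` is the exchangeability constant
that keeps near-zero-variance genes from dominating. `s0` is chosen by
the classical rule: among candidates (the 5%-step percentiles of `s`,
plus 0), take the value minimizing the coefficient of variation of the
median absolute deviation of `d` across ten `s`-quantile bins
(`choose_s0()`).

The null distribution comes from balanced relabelings of the six pooled
samples. At the canonical 3 vs 3 size there are `choose(6, 3) = 20`
relabelings and all are used, removing Monte-Carlo noise; larger designs
are subsampled with the configured seed. Permutation p-values pool the
null across genes: `p = (1 + #{|d*| ≥ |d_obs|}) / (1 + total)`.

A gene is called a DEG only when all three criteria hold:

1. `|log2 ratio| ≥ 1` (at least two-fold change);
2. FDR-adjusted significance below `fdr_alpha = 0.05`;
3. complete biological triplicates in both groups.

### Why SAM q-values are the default FDR route

Two FDR routes are implemented: Benjamini–Hochberg on the pooled
permutation p-values (`q_method = "bh"`) and the SAM
median-false-positive estimate (`q_method = "sam"`, the default). The
default is not a matter of taste but of arithmetic. With exhaustive
relabelings, every gene's own observed labeling *and its complement* are
members of the null set, each reproducing `|d_obs|` exactly. A gene at
rank *r* (by `|d|`) therefore has at least `2r` pooled null values at or
above its threshold, so its pooled p-value is at least
`(1 + 2r) / (1 + 20G)`, and the BH-adjusted value is bounded below by
roughly `2rG / (20G·r) = 0.10` — for *every* gene, at *any* effect size.
At triplicate design sizes, BH on pooled permutation p-values can never
reach `q < 0.05`; we verified this numerically (minimum BH q = 0.100 on
data with 150 planted 4-to-32-fold genes, zero calls).

The SAM estimate is immune to this artifact because it compares, at each
threshold `t`, the *median* across relabelings of the null exceedance
count against the observed count: the two degenerate relabelings
(identity and complement) cannot move a median over twenty values. The
estimated FDR is scaled by the usual null-proportion estimate `pi0`
(fraction of observed `d` inside the interquartile range of the pooled
null, divided by one half) and made monotone so each gene reports the
best FDR of any threshold that still includes it. On the default planted
scenario this route recovers ~100% of planted genes at `q < 0.05` with
empirical FDR under 1%. BH remains available and is the sensible choice
for designs with many more replicates, where the granularity floor
`~3G/(total + 1)` is far below 0.05.

## Normalization

`quantile_normalize()` (delegating to limma) forces all arrays to share
one empirical intensity distribution — the between-array step of the RMA
workflow — with ties receiving the mean reference value over their rank
span, so the result is deterministic and row-order independent.
`median_polish_summarize()` provides the RMA summarization step for
probe-level input: a two-way additive fit per gene block (tolerance 1e-6,
at most 20 iterations — conventional defaults), reporting overall + column
effects. Probe-level background correction is intentionally out of scope:
the pipeline accepts matrices already summarized to one row per
transcript, and the synthetic generator produces gene-level data.

Quantile normalization assumes the arrays are distributionally
equivalent up to technical artifacts. This fails visibly when a large
fraction of a *small* synthetic array is planted with strong one-sided
effects: the planted genes crowd the top ranks of the treated arrays and
every remaining gene is remapped slightly downward, by roughly
(planted count)/(local rank density) log2 units. At the default scenario
(2.5% planted of 6000 genes) this distortion stays below ~0.15 log2 and
is immaterial; at 20% of an 800-gene toy it reaches a full log2 unit and
manufactures false calls. Extreme-rank null genes are the most exposed.
This is a property of the method, not of the implementation, and it is
why the generator defaults keep the planted fraction realistic.

## Pattern classification and the 4-fold rescue

For each material/tissue comparison the low-P DEG list is classified by
normal-P behavior:

| category     | normal-P behavior            | retained as marked? |
|--------------|------------------------------|---------------------|
| `concordant` | DEG, same direction          | no                  |
| `opposite`   | DEG, inverted direction      | yes                 |
| `rescued`    | no difference; low-P change strictly > 4-fold (or < 1/4) | yes |
| `dropped`    | no difference; below 4-fold  | no                  |

The rescue rule exists because a gene with, say, a 3-fold accession
difference under low P and no difference under normal P cannot be
attributed a starvation-specific accession effect larger than two-fold;
requiring strictly more than 4-fold under low P guarantees the
*treatment-dependent* part of the difference exceeds the two-fold DEG
bar. Two conventions are declared and configurable:

* the threshold is **strict** (`> 4.0` on the linear scale);
* "no difference under normal P" means **failing any of the three DEG
  criteria** (`normal_diff_rule = "deg_criteria"`); a fold-change-only
  rule is available (`"fold_only"`).

Marked DEGs are `opposite ∪ rescued`. All set accounting treats the full
transcript-level identifier as the unit of identity (suffixes `.1`/`.2`
are distinct transcripts) and reports both raw totals (with multiplicity
across lists) and non-redundant counts.

## Enrichment

`enrich_sets()` computes the upper-tail hypergeometric probability
`P(X ≥ k)` for each term, with the **measured array as background** — the
universe a chip experiment can actually speak about — rather than all
annotated genes. Terms are intersected with the background first; terms
left empty are dropped with a log line. The significance flag uses the
raw `p < 0.05` by default, with BH adjustment exposed
(`enrichment_adjust = TRUE`); with tens of terms and a single query the
raw rule mirrors the conventional reporting practice for this kind of
screen, and both numbers are always in the output table.

## Clustering

Two-way agglomerative clustering with average linkage: correlation
distance (`1 − r`) over gene profiles (shape matters, not level) and
Euclidean distance over samples (level differences are the signal).
Ties are broken deterministically by pre-ordering items
lexicographically, which also makes the output invariant to input row
order. Row z-scoring is display-only by default and never applied before
distance computation unless requested. Dendrograms serialize to Newick.

## The synthetic-data generator

`simulate_dataset()` draws per-gene baseline log2 intensities from
N(8, 2) (a typical chip dynamic range; arbitrary and configurable), adds
planted cell-wise shifts, overlays per-replicate N(0, 0.25) noise (a
typical post-normalization replicate scatter), and finally adds one
N(0, 0.3) offset per array — the "abiologic" between-array variation
that quantile normalization is there to remove.

Planted structure is declared as **blocks** (`effect_block()`): a block
assigns each of its genes one uniformly drawn log2 effect per component,
added to the listed design cells. Effects are uniform over a stated log2
range — the truthful reading of a situation where only the range of
realized fold changes is known, not their distribution; this choice is a
stand-in and is flagged as such. Ranges must exclude (−1, 1) so planted
genes clear the two-fold criterion in expectation. The default blocks
(151 genes of 6000) emulate the qualitative biology of a starvation
screen: a global low-P response in both directions (4-to-33.8-fold), root-
and tolerant-specific responses at rescued (>4-fold) and dropped (2.8-fold)
magnitudes, accession differences present under both treatments
(concordant), treatment-inverted differences (opposite), and an
"active" block induced only in the tolerant root under low P — the genes
all three comparison families converge on. The planted truth stores the
exact per-contrast log2 ratios, and `truth_patterns()` /
`truth_summary()` derive the expected categories and cardinalities with
an independent, deliberately separate implementation of the category
rules, so the pipeline and the truth can disagree.

Two deterministic fixtures complement the stochastic generator:
`simulate_table1_fixture()` (treatment DEG lists with engineered
cross-list sharing: 319 raw entries, 317 distinct transcripts) and
`simulate_table2_fixture()` (paired low-P/normal-P contrast tables whose
classification reproduces a reference set of category multiplicities,
e.g. the 941/10/826-with-93-rescued root partition and the 196-raw /
195-non-redundant and 253 marked totals, with exactly one transcript
shared between the two material comparisons). Concordant counts without
a corroborated reference value are set to 0 by convention; they do not
enter any marked-set arithmetic. `simulate_annotation()` samples toy GMT
terms with configurable odds of drawing from a designated target subset
(odds 1 = null term).

**What the generator does not emulate:** probe-level effects and
background, intensity-dependent variance, correlated noise between
genes, batch structure beyond a scalar array offset, and real annotation
topology. Passing tests therefore demonstrate the correctness of the
statistics and the set algebra under the stated noise model — not
robustness to every artifact of real chips.

## Numerical and degenerate-input conventions

* `d = 0` whenever the numerator is exactly 0, regardless of `s + s0`;
  a group with fewer than two finite replicates yields NA statistics and
  can never be a DEG (criterion c).
* All-zero standard errors make `choose_s0()` return 0 with a warning.
* Permutation p-values live in (0, 1] by the add-one convention.
* Hypergeometric tails are computed in log space (stable to
  backgrounds of 1e5).
* Pipeline stages attach their name to propagated errors; every stage
  logs input/output cardinalities when `options(lowpdeg.verbose = TRUE)`.

## Problem sizes used by the test suite

The suite exercises the statistics at the sizes where their guarantees
are checkable by enumeration or simulation: exhaustive 20-relabeling
oracles on 3 vs 3 toys; hypergeometric tails against direct summation
for all backgrounds up to N = 60; planted-truth recovery and empirical
FDR over 20 simulated datasets of 6000 genes; exact category recovery in
the noise-free limit (noise sd 1e-3, no array offsets, normalization
bypassed so that boundary-category genes are not moved across the 2-fold
and 4-fold thresholds by the renormalization of a planted array); and
null control over 20 zero-planted datasets. At replicate noise sd 0.25 a
dropped-category gene placed mid-window (2.8-fold) sits only ~2.5 noise
standard deviations from both the 2-fold and 4-fold boundaries, so exact
category equality is only asserted noise-free; at realistic noise the
statistical guarantees (≥95% recovery, FDR ≤ 2× nominal) are asserted
instead.

## Known limitations

* The pooled-permutation + BH route is structurally unable to call genes
  at triplicate sizes (see above); it is provided for larger designs.
* Quantile normalization distorts extreme-rank genes when planted
  (or real) differential expression is strongly one-sided and a large
  fraction of the array; the effect scales inversely with array size.
* The uniform-on-log2-range effect model is a declared stand-in.
* With only 20 distinct relabelings, permutation p-values are coarse;
  the SAM q-value, not the raw p, carries the inference.
* Real GO/KEGG databases are out of scope; enrichment is exercised on
  generated annotation.
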