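---
title: "Methods: context-dependent neutrophil states, windowed CNV malignancy calling, and their synthetic validation"
author: "ctxneu"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: context-dependent neutrophil states and windowed CNV malignancy calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctxneu)
```

`ctxneu` implements the bespoke computations of a multi-tissue tumor
scRNA-seq analysis — cell QC with consensus doublet voting, expression-based
malignancy calling by genomic sliding windows, a bimodal likelihood-ratio
differential-expression test, cross-tissue context scores for neutrophils,
Ro/e tissue-preference statistics, and data-driven anchored signatures —
together with a negative-binomial simulator that plants the truth each of
these computations is supposed to recover. This vignette is the package's
account of those methods: the models, the parameters that matter, the
numerical choices, and what the synthetic validation does and does not
demonstrate about real data.

## The data model

All functions accept a `SingleCellExperiment` with a sparse `counts`
assay, per-cell metadata (patient, tissue, and — for simulated data —
the planted truth) and per-gene annotation (chromosome, start position,
mitochondrial flag). Unless stated otherwise, expression means
log-normalized values: counts scaled to a fixed library size of 10,000
followed by `log(x + 1)`, the droplet-data convention
(`log_normalize()`).

## Quality control and doublet consensus

`compute_cell_qc()` drops a cell when it has **fewer than 250 detected
genes** or **more than 30% mitochondrial counts**. Both are strict
inequalities, so a cell with exactly 250 genes or exactly 30%
mitochondrial content is kept. The mitochondrial fraction is a *count*
fraction on raw counts (mitochondrial counts over total counts): the rule
could also be read as a fraction of detected genes, but the count
fraction is the universal convention of the field's QC tooling, and the
package adopts it as the single implemented reading. A cell with zero
counts fails as `low_genes` rather than producing a division error.

Doublets are removed by consensus: a cell is discarded when **at least
two detectors** call it (`consensus_doublet_call()`, vote threshold and
count overridable). Published doublet detectors are deliberately not
re-implemented; instead one simulation-based scorer of the same family is
provided (`score_doublets_simulated()`) and external detectors' scores or
0/1 calls enter the same consensus interface. The native scorer:

1. simulates artificial doublets by summing two random cells of the same
   sample and multinomially downsampling to the sample's mean singlet
   library size — exactly the construction the simulator uses for its
   planted doublets;
2. embeds observed cells and simulated doublets jointly by PCA (10
   components over the 1,000 most variable genes of the log-normalized
   pooled matrix);
3. scores each observed cell by the fraction of its k = 20 nearest
   pooled neighbors that are simulated, averaging over distance ties at
   the k-th neighbor so the score is invariant to point order.

The number of simulated doublets defaults to one third of the observed
cells, making the simulated points 25% of the pool — the common detector
parameterization. In a homogeneous region the expected neighbor fraction
is then well below the 0.5 call threshold, while cells in the
heterotypic-doublet region see mostly simulated neighbors. The default
threshold of 0.5 per detector is a package choice (no threshold is
prescribed by the rules above); the demo workflow runs the native scorer
three times with distinct seeds and neighborhood sizes (15, 20, 25) as
its three voters. Two limits are worth stating plainly: doublets formed
by two cells of the same type are close to indistinguishable from
singlets by construction (they are downscaled sums of
identically-distributed cells), so recall on datasets dominated by one
cell type per sample is low — the two-type validation design measures
recall only over detectable (heterotypic) doublets; and when all cells
are identical the scorer has no signal at all and returns uniform
at-chance-or-below scores, flagging nothing.

## Malignancy calling from expression

Tumor cells carry far more copy-number variation than normal cells, so
malignancy can be called from smoothed relative expression along the
genome without genotype data. `call_malignant()` chains four steps, each
exported separately:

1. **`relative_expression()`** — drop mitochondrial-contig genes, drop
   genes with mean normalized expression below **0.1** across all cells,
   log-normalize, center each gene on its mean over a set of **reference
   normal epithelial cells**, and clip to ±3. Centering and clipping
   follow the established expression-CNV convention; the reference may
   overlap the query cells.
2. **`sliding_windows()`** — per chromosome, sort genes by start
   position and take every contiguous run of **100 genes at stride 1**
   (n − 99 windows); a chromosome with fewer than 100 retained genes
   contributes a single window holding all its genes, so no chromosome
   silently disappears.
3. **`cnv_profile()`** — CNV~i~(cell, window) is the arithmetic mean of
   the cell's relative expression over the window's genes.
4. **`cnv_score_and_call()`** — the per-cell score is the **mean of
   squared CNV~i~ over all windows**; cells strictly above **0.04** are
   called malignant.

An HMM-based segmentation stage is intentionally absent: the windowed
score above *is* the malignancy definition implemented here, and the
score/threshold pair is the complete decision rule.

The score's magnitude matters for interpreting the threshold. Squared
window values average over *all* windows, so the score of a malignant
cell scales roughly with (fraction of windows inside altered regions) x
(squared log-shift of the alteration). The 0.04 cut corresponds to the
extensive aneuploidy of real tumor genomes, where altered segments cover
a substantial fraction of windows. The package's malignancy-recovery
benchmark (`benchmark_malignancy()`) therefore plants its single
copy-ratio-2.0, 330-gene gain on a compact three-autosome, 1,200-gene
genome — about a third of windows altered, comparable to a real
aneuploid fraction — with 200 tumor epithelial cells (half malignant)
and 200 normal peritumor epithelial cells as reference. Under default
negative-binomial noise this yields sensitivity and specificity at or
near 1.0 at the default threshold across seeds. The same segment planted
in a large, otherwise quiet genome dilutes the score toward the
threshold (the 2,000-gene demo genome gives malignant scores of ~0.05
against a normal baseline of ~0.01, and sensitivity around 0.6–0.7 at
0.04, visible in the demo report's confusion matrix) — a property of the
mean-of-squares definition worth knowing before applying the fixed 0.04
cut to data whose CNV burden is small.

## Differential expression: the bimodal likelihood-ratio test

Single-cell log-expression is zero-inflated, so `bimod_lrt()` models each
group as a mixture of a point mass at zero (weight 1 − α) and a normal
component on the positive values. With per-group and pooled fits at
their maximum-likelihood estimates, the statistic is

    LRT = 2 (l_A + l_B − l_pooled),  p = P(chi²_3 > LRT)

(3 degrees of freedom: α, μ, σ re-estimated per group). Numerical
choices: α is clamped to [1e-5, 1 − 1e-5] so all-zero or all-detected
groups stay finite; the normal variance is the exact ML estimate (1/n
denominator) floored at 1e-6 so constant groups cannot degenerate; the
statistic is floored at 0. Using the exact ML variance keeps the
statistic equal (to 1e-6) to a direct numerical maximization of both
likelihoods, which the test suite checks; implementations that plug in
the n−1 sample sd differ by O(1/n) in log-likelihood. Calibration is
verified by simulation: over 10,000 null genes (both groups of 50 cells
drawn from one mixture with 70% detection), the empirical type-I error
at α = 0.001 falls inside the 95% binomial interval around 0.001.

`find_degs()` applies the test gene-wise on log-normalized expression.
The fold change is the ratio of de-logged group means,
`(mean(expm1(x_A)) + 1e-9) / (mean(expm1(x_B)) + 1e-9)`, the convention
of the ecosystem this rule comes from. A gene is significant iff **fold
change > 1.2 and p < 0.001**, both strict, on the raw p-value — no
multiple-testing correction enters the call, though a BH-adjusted column
is emitted for transparency. Tables are sorted by descending fold
change, then ascending p. A Wilcoxon rank-sum alternative is available
(`test = "wilcoxon"`) and agrees with the bimod test on effect direction
for ≥95% of planted DEGs in the validation suite.

## Context-dependent neutrophil scores

`build_context_scores()` condenses the blood → peritumor → tumor
transition into three gene sets built from three bimod contrasts over
neutrophils (peritumor vs tumor, blood vs tumor, peritumor vs blood; the
reverse directions are read off the same tables by symmetry):

| score | up in | and up in | ranked by |
|---|---|---|---|
| Nontumor-Activating | peritumor vs tumor | blood vs tumor | peritumor-vs-tumor FC |
| Tissue-Residing | peritumor vs blood | tumor vs blood | peritumor-vs-blood FC |
| Tumor-Modifying | tumor vs peritumor | tumor vs blood | tumor-vs-peritumor FC |

Each set is the intersection of its two full significant directional
lists, then truncated to the **top 21** genes by the primary contrast's
fold change. A top-N-with-intersection rule leaves open whether
truncation precedes intersection; intersecting first
guarantees both criteria hold for every retained gene and makes the
result a prefix of the ranking (smaller `top_n` always yields a subset),
so that reading is implemented, with `rank_by = "p"` available since the
ranking criterion is likewise unstated. Tissues named otherwise (e.g.
separate liver and gallbladder peritumoral samples) are pooled into the
three classes via `tissue_map`. Per-cell scores are plain means of
log-normalized expression over each set (`score_gene_set()`), with a
z-scored variant by flag; the plain mean is the implemented reading of
"average expression".

## Tissue preference: Ro/e

`roe()` cross-tabulates cluster by tissue and divides observed counts by
the expected counts of the chi-square independence model
(`expected_ij = n_i. n_.j / N`). Values above 1 mark enrichment; a
cluster absent from a tissue scores 0 there. The ratio is invariant to
duplicating every cell, and for each cluster the column-share-weighted
ratios average to exactly 1. Banding cutoffs for display glyphs are left
to the reporting layer.

## Anchored signatures

`build_signature()` rebuilds subtype signatures of the KRT17 kind: the
union of (i) significant DEGs up in subtype A vs B, (ii) genes whose
Pearson correlation with an anchor gene across the supplied cells, on
log-normalized expression, strictly exceeds `corr_threshold` (default
0.3 — a package choice; the resulting signature size is data-dependent
rather than contractual), and (iii) the
anchor itself. A constant anchor disables the correlation arm with a
warning rather than failing.

## The simulator and what it validates

`generate_dataset()` draws counts gene-wise from a negative binomial
with log-normal baseline means (default meanlog = log 0.5, sdlog = 1,
dispersion 0.3 — variance = μ + 0.3 μ²), a standard and sufficient noise
model for every downstream test. The synthetic genome places
mitochondrial genes on their own contig (excluded from CNV windows, per
convention) and spreads the rest in contiguous blocks over a configurable
number of chromosomes with evenly spaced positions — CNV windowing needs
ordering, not realistic coordinates. Planted structure:

- **programs** (`gene_program()`): disjoint gene sets whose NB means are
  multiplied by `2^log2_effect` in the program's active tissues,
  optionally restricted to a cell type;
- **copy-number segments** (`cnv_segment()`): contiguous gene runs whose
  means are multiplied by `copy_ratio` in malignant cells (a configurable
  fraction of tumor epithelium);
- **doublets**: same-sample pairs summed and downsampled to the mean
  singlet library, flagged in the metadata;
- **damaged cells**: a fraction of cells whose mitochondrial means are
  inflated to an expected 50% mitochondrial fraction, safely past the
  30% QC cut.

The standard design (`default_design()`) is 3 patients x
{blood, peritumor, tumor} x 300 cells, 2,000 genes on 5 autosomes plus
chrM, three disjoint 30-gene neutrophil programs at log2 effect 2
(blood+peritumor, peritumor+tumor, tumor-only), one 300-gene
copy-ratio-2 gain in half the tumor epithelium, 5% doublets and 5%
damaged cells — small enough that the full demo pipeline (simulate, QC,
cluster, CNV, DEG + context scores, Ro/e) runs in well under five
minutes on one CPU, which is also the problem scale the test suite and
the acceptance script use throughout (up to ~2,800 cells and 10,000
simulated null genes). All randomness flows from the design seed (and,
in the pipeline, fixed per-stage offsets of one global seed), so
identical configuration yields bit-identical files.

What passing the synthetic validation shows: the implemented rules
recover exactly the structure they are defined to recover, at the
default parameter values, under NB noise. What it does not show: realism
of batch effects, ambient RNA, UMI saturation, graded biological
transitions, or transferability of the fixed thresholds (0.04; 1.2 /
0.001) to datasets whose noise or CNV burden differ from the planted
conditions.

### A composition caveat for the score orderings

On real multi-tissue data the three context scores order the tissues cleanly
(Tumor-Modifying: tumor > peritumor > blood; Nontumor-Activating:
blood ≥ peritumor > tumor). The synthetic validation reproduces the
tumor-vs-rest separations robustly, but the *within-nontumor* ordering
of a score whose genes are planted at baseline in both compartments is
decided by a small systematic artifact, not biology: planted programs
only add expression (`log2_effect > 0`), peritumor neutrophils carry two
active programs against blood's one, and under fixed-library
normalization (equally under any compositional count model) the extra
program load deflates all neutral genes in peritumor by a few percent.
Tumor-Modifying genes are neutral in both compartments, so their
peritumor mean sits ~2–5% *below* blood — the real data's intermediate
peritumor elevation of tumor genes is a graded effect that disjoint
binary programs cannot represent. The validation therefore treats
tumor-vs-nontumor orderings as the robust property; the
peritumor-vs-blood comparison of the Tumor-Modifying score is reported
but is a noise-level quantity on this design, and the acceptance report
includes its indicator honestly per seed.

## Defaults at a glance

| parameter | default | where |
|---|---|---|
| min detected genes | 250 (strict) | `compute_cell_qc()` |
| max mito fraction | 0.30 (strict, counts) | `compute_cell_qc()` |
| doublet votes | ≥ 2 of 3 detectors | `consensus_doublet_call()` |
| doublet score threshold | 0.5 per detector | package choice |
| expression cutoff | 0.1 (mean normalized) | `relative_expression()` |
| clip | ±3 | `relative_expression()` |
| window size / stride | 100 genes / 1 | `sliding_windows()` |
| malignancy threshold | 0.04 (strict) | `cnv_score_and_call()` |
| fold-change gate | > 1.2 | `find_degs()` |
| p gate | < 0.001 (raw) | `find_degs()` |
| context set size | top 21 by FC | `build_context_scores()` |
| signature correlation | > 0.3 | `build_signature()` |
| normalization | 10,000 counts, log1p | `log_normalize()` |

## Known limitations

- Doublet recall is bounded by the homotypic fraction; the consensus
  preserves specificity (≥ 0.99 in the two-type validation), not recall.
- The fixed 0.04 malignancy threshold presumes a realistic aneuploid
  fraction of the genome; low-burden tumors dilute the mean-of-squares
  score (see above).
- The bimod test's chi-square reference is asymptotic; calibration is
  verified at n = 50 per group and α = 0.001 but very small groups rely
  on the variance floor and clamping.
- Clustering is a thin delegating stage (scran SNN graph + igraph
  Louvain); the package asserts only planted-truth recovery, not any
  particular cluster count or naming.
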