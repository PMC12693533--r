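---
title: "Calling epispliced genes and episplicing RBPs: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling epispliced genes and episplicing RBPs: models and choices}
  %\VignetteEncoding{UTF-8}
---

## The question and the model

Histone modifications are enriched over exons, and several adaptor
mechanisms (PTBP1--MRG15, Psip1--SRSF1, ZMYND11--EFTUD2) physically couple
chromatin readers to the splicing machinery. `episplicer` implements a
pipeline that asks, genome-wide and per histone mark, whether differential
inclusion of an exon between two conditions co-varies with differential
histone-mark signal in the exon's immediate neighbourhood, and which
RNA-binding proteins (RBPs) could mediate that coupling.

The units of analysis are the two 200 bp flanks of each candidate exon.
Each flank carries two scores:

* **DEU score** — the exon's change in percent-spliced-in between the two
  conditions (ΔPSI, in [-1, 1], from an rMATS-style table), extrapolated
  unchanged onto both flanks. Exons with |ΔPSI| ≥ 0.2 at FDR < 0.05 are
  *alternative*; all other candidate exons of the same genes score 0.
* **DHM score** — the M-value (log2 fold change of ChIP-seq read density,
  from a MAnorm-style table) of the strongest overlapping differential
  peak, or 0 when no eligible peak overlaps the flank.

For every gene with at least three flanks, Pearson correlation between the
**absolute** DEU and DHM scores over its flanks is computed. Genes with
r ≥ 0.5 at Benjamini–Hochberg FDR < 0.05, whose histone-mark peaks are
confined to alternative-exon flanks, are **epispliced**; genes with
alternative exons but no differential peak on any flank for any of the
five marks (H3K27ac, H3K27me3, H3K36me3, H3K9me3, H3K4me3) are
**non-epispliced**. Everything else stays unclassified.

Flanks of epispliced and non-epispliced exons, consolidated across all
pairwise comparisons, become the positive and control classes of a per-mark
random-forest classifier whose features are thresholded RBP motif-scan
Z-scores. Held-out Shapley attributions rank the RBPs; the top attributions
split, by direction, into *episplicing* and *non-episplicing* seed sets,
each expanded with RBPs whose binding profiles correlate with a seed member
at r ≥ 0.7 (FDR < 0.05). Welch's t-tests then compare mean set binding
across the three exon classes (DEU & DHM, DEU & ¬DHM, ¬DEU & DHM), and a
uniform-placement model scores eCLIP peak evidence near epispliced exons.

## Candidate exons and flanks

Exons come from a GFF3 annotation restricted to transcripts with support
level (TSL) 1–3; the TSS set uses transcripts of any TSL 1–5 because
initiation-associated chromatin must be masked regardless of transcript
quality. An exon with any base within 200 bp (inclusive) of any TSS is
excluded. The window is symmetric: nothing in the biology of initiation
marks distinguishes upstream from downstream at this scale, and the
filter's purpose is conservative masking.

Coordinates are handled in one internal convention — 0-based, half-open —
with GFF3 (1-based closed) and MAnorm tables converted on ingest and
BED-style files passing through unchanged. "Overlap" always means ≥ 1 bp of
intersection under half-open arithmetic. Flanks are computed in genomic
orientation; strand only relabels which flank is 5′ or 3′ of the
transcript. Flanks clipped at a contig edge are dropped rather than padded,
since a short flank would distort both the correlation unit and the
binding-score normalization.

## Peak filtering

Three filters keep spurious chromatin signal away from the flanks:

1. **Common peaks** (present in both conditions) and peaks at FDR ≥ 0.05
   are removed on ingest.
2. **Transcription-initiation leak**: a peak overlapping any exon that lies
   within 200 bp of a TSS is removed globally — the conservative reading,
   since such a peak is plausibly initiation-associated wherever else it
   reaches.
3. **Coverage**: a peak may annotate an exon's flanks only if it covers at
   least half of that exon (inclusive at exactly 50%, "at least half"),
   which suppresses marginal spill-over from neighbouring features.

When several eligible peaks overlap one flank, the one with the largest
|M| wins; exact ties break by smaller FDR, then leftmost start — an
arbitrary but deterministic rule, needed because input order must not
influence results.

## The correlation unit and zero imputation

The per-gene correlation runs over *all* non-clipped flanks of the gene's
candidate exons whenever the gene has at least one qualifying usage event,
with zero-imputed DEU and DHM values included. This is the only reading
under which zero imputation matters: the (0, 0) flanks anchor the
regression and reward genes whose peaks sit exactly where the usage changes
are. Genes with fewer than three flanks, or with a constant score vector on
either axis, are excluded with a recorded reason instead of propagating
NaN. BH adjustment is applied per mark and per pairwise comparison — the
batch in which the hypotheses are actually exchangeable.

The control ("non-epispliced in ≥ 70% of analyses") consolidation counts,
for each flank, the comparisons in which the flank's gene was testable at
all, and applies a ceiling to the fractional cutoff; flanks ever labelled
epispliced are removed from the control side so the classes never overlap.

## Classifier, baseline and attribution

The classifier is a 200-tree probability forest (Gini splits), with class
weights inversely proportional to training-class frequency, evaluated by
stratified 5-fold cross-validation repeated 10 times. The headline metric
is PR-AUC in its average-precision form, evaluated at every distinct score
threshold so tied scores are handled without interpolation optimism.

The baseline is a stratified-random predictor. Its *expected* PR-AUC equals
the positive prevalence asymptotically, but at realistic fold sizes (a few
dozen rows, a handful of positives) the average precision of any
uninformed ranking is biased a few points above prevalence. All null
comparisons in the tests therefore use the *measured* baseline from the
same folds, not the prevalence constant, and the reported
`baseline_pr_auc` per fold is a measured quantity.

Shapley attributions are computed with an interventional Monte-Carlo
permutation-chain estimator: per iteration, one background row (sampled
from the fold's training data) and one feature permutation are drawn, and
the full chain of hybrid rows from background to target is predicted in
one batch. Because each chain telescopes, per-row attributions sum exactly
to `f(x) - base` — local accuracy holds to float precision, not merely in
expectation — while the per-feature variance shrinks as 1/`n_perm`
(default 8 chains). Attributions for every flank come from the fold model
under which the flank was held out, avoiding training-set optimism.

An RBP counts as episplicing-directed when the correlation between its
binding score and its attribution, among flanks where it binds, is
positive; with fewer than three bound flanks the sign of the mean bound
attribution is used instead. Seed sets are the top 10 RBPs by mean |SHAP|
in each direction; 10 is a declared knob (`top_k`), as no principled
cutoff exists for attribution magnitudes. Expansion candidates pulled
toward both sets are ambiguous and dropped from both, with the conflict
logged.

## eCLIP enrichment model

Under a uniform placement of `n` peaks on a genome of length `G`, the
probability that at least one lands in a fixed window of `w` bases is
`1 - (1 - w/G)^n`. The genome length defaults to 3.0 × 10⁹ bp, which
reproduces the reference TIA1 value (5885 peaks → 3.923 × 10⁻⁴) to four
significant figures; the U2AF2 value (10732 peaks → 7.154 × 10⁻⁴) is
matched to about 0.01% but not in the fourth digit under either the exact
complement or the rare-event linearization `n·w/G`, so both forms are
exposed (`method = "exact"` is the default) and the residual is attributed
to the unstated genome length behind the reference values. Concordance
between the condition in which usage, mark and eCLIP binding are each
elevated is categorized into three named cases (all agree; mark+eCLIP vs
usage; usage+mark vs eCLIP); the fourth pattern maps to `other`.

## The synthetic scene

The generator emits every upstream file class — GFF3, rMATS-style event
tables, MAnorm-style peak tables, RBPmap-style hit tables, eCLIP BED —
with planted truth. The default scene has 300 genes with 4–7 exons on two
contigs, 10 pairwise comparisons, 5 marks and a 160-RBP panel, yielding
roughly 1200 candidate exons and 2400 flanks; it runs through the full
pipeline in a few minutes on one CPU. Planted classes per eligible gene:
25% epispliced (two alternative exons with |ΔPSI| ~ U(0.25, 0.8) and peaks
whose |M| = 3·|ΔPSI| + N(0, 0.35)), 25% non-epispliced, and 12% each of
sub-threshold, common-peak-only and peak-leak distractors, the remainder
constitutive-marked. Binding background is Z ~ N(1.5, 0.8) truncated at 0
with a 0.7 site rate, so roughly a quarter of background sites clear the
Z ≥ 2 threshold; ten planted RBPs gain +2 on true epispliced flanks (+1 on
constitutive-marked flanks, making the three-class Welch contrasts
non-trivial), and the tenth planted RBP carries no independent signal —
its scores copy the ninth's with jitter, exercising the correlation
expansion.

What the scene does **not** emulate: read-level noise and junction-count
uncertainty (events carry exact ΔPSI values), overlapping genes and shared
exons, peak-width heterogeneity, correlated mark co-occurrence, and the
motif-driven covariance structure of real RBP panels. Passing recovery
tests therefore demonstrates correctness of the pipeline's logic and its
statistical machinery under the stated noise model — not performance on
ENCODE-scale data, whose published per-mark gene counts and classifier
metrics depend on the real assays and are out of reach at this scale.

## Numerical and degenerate-input conventions

* Pearson p-values use the exact t transform; perfectly collinear columns
  get p = 0 rather than NaN; constant columns yield NA correlations that
  are flagged non-significant.
* Welch's test delegates to `t.test(var.equal = FALSE)`
  (Welch–Satterthwaite df), with the degenerate identical-constant case
  pinned to t = 0, p = 1.
* All stochastic stages take explicit seeds; cross-validation repeat `r`
  uses `seed + r - 1`, and fold-level fits reseed deterministically.
* Empty tables propagate as empty data frames with the documented columns,
  never as errors, except where the input is unusable (unknown histone
  mark, malformed intervals, single-class training data).

## Problem sizes used by the tests

Unit tests run on constructed fixtures of tens of rows. The end-to-end
checks use the default 300-gene scene for caller and selection recovery, a
150-flank × 40-RBP configuration over 10 seeds for the null-behaviour
bands, and 2 repeats of cross-validation where the full 10 add nothing to
the property under test; the acceptance script runs the study
configuration (K = 5, 200 trees, 10 repeats) on the default scene.
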