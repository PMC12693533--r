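# episplicer

Connecting alternative splicing to the local chromatin state. `episplicer`
implements an analysis pipeline that scores the ±200 bp flanks of candidate
exons with **differential exon usage** (ΔPSI from rMATS-style tables) and
**differential histone-mark signal** (M-values from MAnorm-style tables),
calls **epispliced genes** — genes where |ΔPSI| and |M| co-vary across exon
flanks (Pearson r ≥ 0.5, BH-FDR < 0.05, with peaks confined to
alternative-exon flanks) — and then asks which RNA-binding proteins (RBPs)
could mediate the coupling: a random-forest classifier separates
chromatin-marked from unmarked alternative-exon flanks by RBP motif-scan
Z-scores, held-out Shapley attributions plus correlation expansion
(r ≥ 0.7, FDR < 0.05) nominate *episplicing* and *non-episplicing* RBP
sets, and eCLIP peak overlap with a uniform-placement enrichment model
validates them. It is aimed at regulatory genomicists studying
chromatin-coupled splicing from rMATS/MAnorm/RBPmap/eCLIP-shaped inputs.

At its core, for each gene *g* with flank score vectors over its candidate
exons,

    r_g = cor(|ΔPSI|, |M|),   epispliced ⇔ r_g ≥ 0.5 ∧ p_FDR < 0.05
                                ∧ peaks only at alternative-exon flanks

and for eCLIP validation, the probability of seeing at least one of *n*
uniformly placed peaks in a *w* bp window of a genome of *G* bp is

    P = 1 − (1 − w/G)^n .

A synthetic-data module generates every upstream file class (GFF3,
rMATS/MAnorm/RBPmap dialects, eCLIP BED) with planted ground truth, so the
entire pipeline is testable without downloads.

## Worked example

The numbered scripts under `analysis/` run the whole study on the default
synthetic scene and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_scene.R     # scene files + truth manifest
Rscript analysis/02_candidate_exons.R    # TSL + TSS filters, flanks
Rscript analysis/03_call_episplicing.R   # per-comparison/mark gene calls
Rscript analysis/04_classify_rbps.R      # RF + SHAP + Welch, one mark
Rscript analysis/05_validate_eclip.R     # enrichment + concordance cases
```

Representative output (seed 1):

```
After TSS-proximity exclusion: 1197 candidate exons ( 314 removed )
Flanks: 2394 (clipped flanks dropped)
...
Recovery of planted epispliced genes: sensitivity 0.998, specificity 1.000
Feature matrix: 428 flanks x 160 RBPs; 52 positive
PR-AUC 0.980 +/- 0.027 (baseline prevalence 0.121)
Planted RBPs recovered: 10 of 10
```

Sensitivity/specificity compare the caller's per-comparison labels against
the planted epispliced genes; the PR-AUC line summarizes 5-fold × 10-repeat
cross-validation of the H3K36me3 flank classifier against its
stratified-random baseline. The eCLIP step prints the uniform-placement
probabilities for the reference peak counts shipped in `inst/extdata/`
(TIA1, 5885 peaks in K562 → 3.92 × 10⁻⁴; U2AF2, 10732 peaks in HepG2 →
7.15 × 10⁻⁴) and the three-way DEU/DHM/eCLIP concordance case for each row
of the reference HepG2–K562 table.

In code, the same pipeline is three calls:

```r
library(episplicer)
scene <- simulate_scene(seed = 1)
res   <- run_scene_calls(scene)                      # gene-level calls
caller_performance(scene, res$calls)                 # sens/spec vs truth
fm    <- scene_feature_matrix(scene, res$classes, "H3K36me3", seed = 101)
fit   <- train_evaluate(fm$matrix$x, fm$matrix$y, seed = 1)
sel   <- select_rbps(shap_attribution(fit, seed = 1)$summary, fm$matrix$x)
```

See `vignettes/episplicing-methods.Rmd` for the model, parameter defaults,
numerical conventions and the limits of what the synthetic scene shows.

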