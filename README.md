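# zgaenhancers

Chromatin-based classification of regulatory elements in the early embryo,
centered on the two-class enhancer call that separates **H3K4me1-only
enhancers** from **H3K4me2-marked enhancers** at zygotic genome activation
(ZGA).

## The problem

During the maternal-to-zygotic transition, the zebrafish embryo activates
its genome. Much of that activation depends on the maternal pluripotency
factors Nanog, Pou5f3 and Sox19b (NPS) pioneering closed chromatin at
enhancers — but a subset of genes activates without them. Multi-mark
histone-modification profiling (CUT&RUN) over an ATAC-defined open-chromatin
region universe reveals the chromatin correlate: most active enhancers carry
H3K4me1 only, while a distinct subclass additionally carries H3K4me2, is
DNA-hypomethylated in a pattern shared with both gametes, is depleted for
NPS binding motifs, and sits nearer to NPS-independent genes.

This package implements that analysis end to end, for computational
biologists who want a tested, reusable version of the pipeline:

* region universe construction (two merged sources, `atac_L#####` /
  `atac_P#####` ids) and the promoter / proximal / distal taxonomy
  (CAGE-supported TSS selection, 2-kb distal boundary);
* fragment filtering (140–250 bp spans, tag-centered 73-bp trim, duplicate
  removal), subinterval coverage counting, `log2(RPKM/2 + 1)` ("RPK500")
  normalization, replicate pooling, spike-in scaling, and per-region
  fold-enrichment over an IgG control,
  `fold = (RPK500_mark + 0.1) / (RPK500_IgG + 0.1)`;
* the core classifier: centered PCA on the coverage features, a
  radial-basis SVM (γ = 1, C = 1) trained on promoter vs distal taxonomy
  labels, and threshold-based element calls driven by SVM *discordance* —
  distal regions the SVM places with the promoters become H3K4me2
  enhancers (H3K27ac ≥ 1.5-fold, H3K4me2 ≥ 2-fold), with a coverage-gated
  rescue rule (top quartile of first-pass H3K4me2 coverage), H3K4me1
  enhancers (H3K4me1 ≥ 2-fold, H3K4me2 < 1.25-fold, H3K27ac ≥ 1.5-fold),
  poised enhancers (H3K27ac ≤ 1.5-fold) and proximal potential enhancers
  (H3K4me3 < 1.25-fold);
* a directional-transcription filter removing putative enhancers that
  behave like unannotated gene TSSs (≥ 1 RPKM strand-specific flank
  coverage, ≥ 2-fold directional, in ≥ 2 stages, with exon exemption);
* stage-wise analyses (stacked-stage H3K4 PCA trajectories; expression
  trajectories `log2(x_t + 0.1) − log2(x_0 + 0.1)` with t-interval
  confidence bounds; maternal-zygotic stratification at > 0.5 RPKM);
* association statistics (PWM motif-density scanning, presence chi-squared
  tests, methylation strata <20% / 20–80% / >80%, gamete-shared
  hypomethylation, CpG and C+G content, nearest-gene distances with
  Wilcoxon rank-sum comparisons, proximity fractions, Fisher + BH term
  enrichment);
* crispant qRT-PCR analysis (technical-replicate averaging, ΔCt, 2^−ΔCt,
  control normalization, fold decrease with an exact rank-sum test);
* a synthetic-data generator (`simulate_study()`) that plants all of the
  above structure — six chromatin classes, an IgG baseline, spike-ins,
  cryptic-TSS contaminants, methylation, motifs, RNA-seq and Ct tables —
  so the whole pipeline runs and is validated with no external data.

## Worked example

```r
library(zgaenhancers)

sim <- simulate_study()          # default study conditions, fixed seed
res <- classify_study(sim)       # taxonomy -> coverage -> PCA -> SVM ->
                                 # calls -> transcription filter

table(res$final_calls$call)
#>     H3K4me1-enhancer     H3K4me2-enhancer high-K4me23-promoter
#>                  200                  194                  396
#>  low-K4me23-promoter      poised-enhancer         unclassified
#>                    4                  181                  226

res$txfilter$report
#>               call n_input n_removed fraction_removed
#> 1 H3K4me1-enhancer     200         0       0.00000000
#> 2 H3K4me2-enhancer     207        13       0.06280193
```

The generator planted 200 regions per class plus 14 cryptic-TSS
contaminants carrying H3K4me2-enhancer chromatin. The classifier calls 207
H3K4me2 enhancers (including most of the contaminants, which pass every
chromatin gate by construction); the transcription filter then removes the
13 of them showing directional stable transcripts — about 6% of the class
— and the final calls recover the planted classes with high sensitivity
and precision. Poised enhancers and the promoter split come along for free
from the same thresholds and SVM concordance.

The crispant analysis on a synthetic Ct table:

```r
ct <- simulate_ct_table(sim_config(), planted_fold = 1.7, noise = 0.5)
analyze_ct_table(ct)$test[c("fold", "p.value")]
#> $fold
#> [1] 1.723374
#>
#> $p.value
#> [1] 1.082509e-05
```

a 1.7-fold planted knockdown recovered as a 1.72-fold decrease of the
control-normalized 2^−ΔCt values, with an exact two-sided rank-sum
p-value.

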