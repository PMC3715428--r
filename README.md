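# peakstate

Integrative expression-array × ChIP-Seq classification of
transcription-factor target genes, for regulatory genomicists who have (a)
a replicated three-genotype expression contrast (control, factor
overexpression, and a tumourigenic combination) and (b) ChIP-Seq of the
factor in both conditions plus an input control, and want to separate
*direct* targets (bound **and** deregulated) from downstream responses.

The core of the package is the joint classification: a probe set is
deregulated when |log2FC| > 1 and BH-adjusted p < 0.05 (Welch *t* per
contrast, BH across all probe sets per contrast); a gene is a ChIP target of
a condition when a significant peak overlaps the 500 bp upstream of a TSS or
an intron; and every gene deregulated in the tumour contrast falls into one
of six classes by its (deregulation pattern) × (peak pattern):

| class | deregulated in | peaks in |
|---|---|---|
| 1 | both contrasts | both conditions |
| 2 | tumour only | both conditions |
| 3 | both contrasts | tumour only |
| 4 | tumour only | tumour only |
| 5 | tumour-deregulated | none |
| 6 | tumour-deregulated | overexpression only |

Around that sit: a simplified input-normalised binomial peak caller carrying
the published parameters (read extension 40 bp, merge gap 40 bp, p < 1e-4,
FDR < 0.01, peak height = max extended-read depth); PWM log-odds scanning
with normalised-density rank-shift overrepresentation (selection: genome→peak
rank improvement ≥ 200 positions, positive fold change); hypergeometric term
enrichment; 2^(−ΔΔCt) qPCR arithmetic; and a synthetic-data generator that
plants ground-truth deregulation, binding loci, motif instances and fold
changes so the whole pipeline is testable end to end.

## Worked example

```r
library(peakstate)

cfg <- sim_config(seed = 7, n_genes = 120, noise_sd = 0.25,
                  class_plan = c("1" = 12, "2" = 9, "3" = 6,
                                 "4" = 6, "5" = 24, "6" = 6))
study <- simulate_study(cfg)   # annotation, truth, expression, reads
res <- run_pipeline(study)     # DE -> peaks -> targets -> classes -> venn
res
```

```
de_result: 126 probe sets, 120 genes
  deregulated probe sets: ab 31, tumour 66 (|log2FC| > 1, adj p < 0.05)
assignment
       both        none tumour_only
         30          57          33
peaks: ab 27, tumour 33
Probe sets: 126 total; 0 ab-unique, 31 shared, 35 tumour-unique
Gene assignments: both=30 ab_only=0 tumour_only=33 none=57
ChIP target genes: unique_ab=6 unique_tumour=12 shared=21 total_ab=27 total_tumour=33
Classes: class1=12 class2=9 class3=5 class4=7 class5=24 class6=6 unclassified=57
Deregulated genes with peaks: ab 47%, tumour 52%
```

Reading the output: 63 genes are deregulated in the tumour contrast (30 in
both contrasts + 33 tumour-only) and the six class sizes sum to exactly
that; 12 + 9 = 21 genes bound in both conditions and tumour-deregulated are
the strongest direct-target candidates. Against the planted truth this run
recovers 119/120 class labels (99.2%); the one miss is a class-3 gene whose
overexpression-contrast shift lands just under the strict thresholds at
noise s.d. 0.25, moving it to class 4. At `noise_sd = 0` recovery is exact.

Per-stage entry points (`de_analysis`, `call_peaks`, `assign_targets`,
`classify_genes`, `venn_report`, `rank_matrices`, `select_overrepresented`,
`ddct_fold_change`, `chip_fold_enrichment`) accept standard formats —
expression TSV, BED6 reads/peaks, GFF3 gene models, JASPAR count matrices,
FASTA — via the `read_*`/`write_*` helpers.

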