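# bsaskit

Targeted bisulfite amplicon sequencing (BSAS) analysis for sex-gene
methylation studies in fish, built around the barramundi
(*Lates calcarifer*) gonad panel: seven sex-determination genes (*dmrt1*,
*cyp19a1*, *foxl2*, *nr5a2*, *amh*, *sox8*, *sox9*) covered by 11 amplicons
and 146 CpG sites over 3,430 bp of promoter/first-exon sequence.

The package is for researchers who run targeted bisulfite panels on
non-model species and want a reproducible, testable path from reads to
group statistics — including a seeded simulator so every stage can be
validated without access to the original sequencing data.

## What it computes

**Methylation.** After bisulfite conversion, an unmethylated cytosine reads
as T and a methylated CpG cytosine stays C, so per sample *s* and CpG *j*

> m̂ₛⱼ = 100 · n_C / (n_C + n_T) %

over the bisulfite-aware alignments of that sample's reads. The pipeline:
3' quality trim (base accuracy < 95%, i.e. Q < 13.01, trimmed from the
end), length filter (reads < 100 bp removed), primer-prefix assignment to
amplicons (≤ 2 mismatches, unique best match), ungapped bisulfite-aware
alignment (read T opposite reference C is conversion, not mismatch), per-CpG
C/T tallies with coverage flagging, and conversion-efficiency QC at non-CpG
cytosines.

**Statistics.** Amplicon group summaries (group mean ± SD; overall =
unweighted mean of the four group means), per-CpG Kruskal–Wallis tests with
Dunn/Holm post-hoc compact letter displays, testes-minus-ovaries
differences per gene, and an exponential fit of methylation against CpG
density (m = a·e^(−b·d)).

**Expression.** Standard-curve efficiencies (E = 10^(−1/slope) − 1),
2^−ΔCt relative expression against a reference gene (*ubq*), and
log-scale t-tests with fold-change reporting.

**Splice assays.** Exon-chain comparison of transcript variants against a
gene model (skipping, 5'/3' shortening, intron retention, novel exons) and
virtual RT-PCR with a 3'-anchored primer rule, operationalising the
male-specific *dmrt1* DM-domain assay (575 bp) and female-specific
*cyp19a1a* assay (207 bp) as a sex-typing readout.

**Simulator.** Seeded, deterministic generation of directional bisulfite
amplicon read pairs (Beta-distributed between-individual methylation,
per-CpG jitter, incomplete conversion, sequencing error), qPCR Ct tables
and toy splice-variant transcripts, with ground-truth tables for
parameter-recovery testing.

## Worked example

Simulate a reduced cohort over two differentially methylated amplicons and
run the full pipeline:

```r
library(bsaskit)

panel <- lates_panel()
panel$amplicons <- panel$amplicons[c("cyp19a1", "nr5a2 (2)")]
design <- cohort_design(6L, 4L, 6L, 4L)   # testes/ovaries, captive/wild
cfg <- run_config(panel = panel, design = design,
                  sim = simulation_config(coverage_per_amplicon = 300L),
                  min_coverage = 100L, seed = 42L)
report <- run_pipeline(cfg)
print(report)
```

```
BSAS pipeline report (seed 42 )
Methylation matrix: 20 samples x 16 CpG sites (min coverage 100)
  mean methylation 53.4%, conversion efficiency 99.45%
Amplicon group summary (mean % +/- SD):
 amplicon_id overall_mean overall_sd
     cyp19a1     66.70886   22.97194
   nr5a2 (2)     40.70950   29.81075
Sex differences (testes - ovaries, %):
    gene  diff_pct            p
 cyp19a1  40.71856 0.0001826718
   nr5a2 -54.87456 0.0001826718
Relative expression: fold change (testes/ovaries) 2.05, t = 11.15, p = 2.31e-09
  group means 2^-dCt: testis 0.00766 (n=10), ovary 0.00374 (n=10)
Sex-typing calls: testis = male-pattern, ovary = female-pattern
```

Reading the output: the recovered *cyp19a1* overall mean (66.7%) sits near
the unweighted average of its configured group truths (69.6%), and the
sex differences carry the expected directions — *cyp19a1*
testis-hypermethylated (+40.7 points), *nr5a2* ovary-hypermethylated
(−54.9 with this reduced design) — while conversion efficiency (99.45%)
reflects the simulated 0.5% incomplete-conversion rate. The *dmrt1* qPCR
fold change (2.05 here, truth 1.9) and the two virtual RT-PCR assays
complete the sex-typing picture.

Individual stages are available as plain functions
(`simulate_cohort()`, `quantify_cohort()`, `amplicon_group_summary()`,
`kruskal_wallis_per_cpg()`, `relative_expression()`, `virtual_pcr()`, ...)
and the vignette in `vignettes/bsas-methods.Rmd` documents the model and
every default.

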