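---
title: "Methods: targeted bisulfite amplicon methylation analysis with bsaskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted bisulfite amplicon methylation analysis with bsaskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement model

Bisulfite amplicon sequencing (BSAS) measures DNA methylation at single-CpG
resolution in a targeted panel. Sodium bisulfite deaminates unmethylated
cytosine to uracil, read as T after PCR; 5-methylcytosine resists
deamination and stays C. After PCR of the converted template with
conversion-specific primers and deep paired-end sequencing, the methylation
level of a CpG site in a sample is the fraction of aligned reads showing C
rather than T at that cytosine:

$$\hat m_{s,j} = 100 \cdot \frac{n_C}{n_C + n_T}\ \%.$$

At coverage $n$ this is a binomial estimate with standard error
$\sqrt{m(1-m)/n}$; at the panel's working depth (the study this package
emulates reported a mean of roughly 7,000 reads per amplicon; the simulator
defaults to 2,000 pairs) the sampling error per cell is a fraction of a
percentage point, so between-individual biological spread dominates group
summaries.

`bsaskit` implements the full path from panel definition to group
statistics for a panel of seven fish sex-determination genes (dmrt1,
cyp19a1, foxl2, nr5a2, amh, sox8, sox9; 11 amplicons, 146 CpG sites,
3,430 bp) in the protandrous barramundi, plus a seeded synthetic-data
generator so every stage is testable without sequence downloads.

## Coordinates and panel bookkeeping

Panel coordinates are TSS-relative integers with no position zero
(..., -2, -1, +1, +2, ...). Amplicon sizes quoted with such coordinates are
reproduced by plain signed subtraction `end - start`; an inclusive base
count would disagree with the published sizes for amplicons that do not
cross the TSS (e.g. a (-575, -305) amplicon is 270 bp by subtraction but
271 by inclusive count). The subtraction convention is the only one
consistent with all eleven published sizes, so it is the package's
definition (`amplicon_length()`).

The mapping reference is built by bisulfite-converting each amplicon's top
strand with all CpGs unmethylated and concatenating the amplicons with
100-N spacers (`build_reference()`). For the default panel this yields
3,430 + 10 x 100 = 4,430 bp. The study reports a 4,717 bp reference; the
difference is not derivable from the published table (most plausibly
primer-inclusive region lengths), so the builder always reports its own
computed length and never hard-codes the published figure.

## Primer validation

Bisulfite PCR primers anneal to converted template, which has no cytosine
outside methylated CpGs. `validate_bisulfite_primers()` therefore checks,
after stripping the Illumina overhang constants: (i) the forward core
contains no C; (ii) the reverse core contains no G; (iv) neither core
covers a CpG (whose state is unknown a priori). With a template sequence it
additionally requires (iii) both primers to match the converted top strand
(forward on the sense, reverse on its reverse complement) within a
2-substitution budget with no indels — amplicon primers are short and
anchored, so gapped matching is unnecessary — and at least one primer to
fail on unconverted genomic DNA, mirroring the wet-lab no-genomic-product
control. All 22 bundled locus-specific primers pass (i), (ii) and (iv).

## The synthetic cohort

The generator emulates the study conditions:

* **Design.** Four sex-by-origin groups: captive testes n = 14, wild testes
  n = 10, captive ovaries n = 14, wild ovaries n = 4 (42 samples;
  `cohort_design()`).
* **Group truth.** Per amplicon and group, the published mean ± SD percent
  methylation (`lates_methylation_truth()`). Only the first two moments are
  published, so per-sample amplicon-level methylation is drawn from a Beta
  distribution moment-matched to (mean, SD) — the natural bounded-support
  choice — with a point-mass fallback (and warning) when the SD exceeds the
  Beta variance bound. Per-CpG values add Gaussian jitter (default SD 2
  percentage points, clipped to [0, 1]) to reproduce the site-to-site
  variability visible in per-CpG profiles.
* **Reads.** Directional bisulfite PCR pairs: R1 reads the converted top
  strand from the forward primer, R2 its reverse complement from the
  reverse primer, truncated to 300 bp (MiSeq V3 paired-end geometry).
  Coverage defaults to 2,000 pairs per sample and amplicon — an order of
  magnitude below the study's ~7,000 mean, keeping desk-scale runs fast
  while leaving binomial noise negligible next to biological spread. Each
  unmethylated cytosine (CpG or not) escapes conversion with probability
  0.005 and each base suffers a substitution error with probability 0.001;
  both rates are plumbing defaults of realistic magnitude for a
  kit-converted MiSeq library, not published values. Base qualities are
  constant at the Phred equivalent of the error rate (capped at Q40), with
  an optional 3' decay to exercise trimming.
* **Sequences.** Published panels carry no amplicon sequence, so the
  simulator synthesizes one per amplicon honouring the declared length and
  CpG count, beginning/ending with the primer footprints. Footprints carry
  convertible non-CpG cytosines so that primers match converted but not
  genomic template, as real bisulfite primers do.

Reads carry their sample and amplicon in the read name for truth tracking;
the quantifier never uses names — assignment is sequence-based.

What the simulator does **not** model: PCR duplicates and amplification
bias, indels, non-directional libraries, non-uniform coverage across
amplicons, bisulfite degradation, SNPs under primers. Passing recovery
tests therefore demonstrates correctness of the quantification and
statistics machinery under the stated noise model, not robustness to every
artefact of real libraries.

## Quantification

Per read: (1) 3' quality trimming removes bases while call accuracy is
below 95%, i.e. Phred < -10·log10(0.05) ≈ 13.01 — a suffix-only rule,
stopping at the first passing base; (2) reads shorter than 100 bp are
discarded (a 100 bp read is kept); (3) the read's 5' end is compared
against every amplicon's expected converted primer (forward core for R1,
reverse core for R2) with a ≤2-mismatch budget — the unique best match
wins, ties and no-matches are unassigned; (4) an ungapped bisulfite-aware
alignment anchored at the primer scores read-T opposite reference-C as a
legal conversion, rejects alignments with plain mismatches above
ceil(5% of aligned length), and records a C/T/other call at every covered
reference cytosine.

Calls are tallied per sample and CpG; "other" (sequencing-error) calls are
excluded from both numerator and denominator rather than counted as
unmethylated. Cells with fewer than `min_coverage` (default 100)
informative calls are reported missing. R1 and R2 are processed
independently without overlap merging: both mates re-read the same
molecule's conversion events, so overlapping CpGs are counted twice with
identical outcomes — this leaves point estimates unbiased and only
overstates nominal coverage, which the deep-coverage setting makes
inconsequential.

Conversion efficiency QC is the percentage of non-CpG reference cytosines
read as T per sample (expected 100 minus the failure rate in percent), with
a warning below 98%.

## Group statistics

* **Amplicon summaries.** The per-sample amplicon value is the mean over
  its CpGs. Group mean/SD are taken over samples. The *overall* mean is the
  unweighted average of the four group means — the only definition that
  reproduces the published overall column (e.g. (92.5+88.0+44.1+54.0)/4 =
  69.65 → 69.6) — while the overall SD pools all samples, the only
  definition compatible with the large published spreads.
* **Per-CpG tests.** Kruskal–Wallis with tie correction across the four
  groups at every CpG (`stats::kruskal.test`), chi-square reference with
  k-1 df. No cross-CpG multiple-testing correction by default, mirroring
  the per-site reporting of the study; a Benjamini–Hochberg column is
  available by flag. With the study's unbalanced design (wild ovaries
  n = 4) the chi-square approximation is slightly conservative (empirical
  type-I ≈ 0.040 at α = 0.05 under a Beta null); at balanced n = 14 per
  group it is calibrated (≈ 0.048), which is the regime the package's
  calibration test checks.
* **Letters.** The study reports only "different letters denote significant
  differences"; the post-hoc procedure is unstated. The package's
  interpretation is pairwise Dunn tests (rank-based z with tie correction
  on the joint ranking) with Holm adjustment, summarised as a compact
  letter display whose letter sets are the maximal cliques of the
  not-significantly-different graph — with four groups these are enumerated
  exhaustively. Defaults: α = 0.01 at amplicon level, 0.05 per CpG,
  matching the published captions.
* **Sex differences.** Per gene, testes minus ovaries in percentage points.
  Whether the study pooled samples or averaged group means is unstated;
  both are implemented (`mode = "pooled"` default, `"group_means"`
  alternative) and neither is asserted to equal the published values, which
  derive from the unreleased reads.
* **Density relationship.** Least-squares fit of
  $m = a\,e^{-b\,d}$ (methylation vs CpG per 100 bp) via `stats::nls`
  seeded from a log-linear regression, with `scaleOffset` so exact
  (zero-residual) data converge. On the published panel summaries the decay
  is positive: CpG-dense, island-like amplicons (sox8, foxl2) are
  hypomethylated.

## Expression analysis

Standard curves: OLS of mean Ct on log10 dilution, efficiency
$E = 10^{-1/\text{slope}} - 1$, flagged outside [0.9, 1.1] or R² ≤ 0.99.
Relative expression uses the 2^-ΔCt method: replicate Ct values are
averaged per gene before ΔCt (the usual Livak practice; the aggregation
order is not stated in the study), then compared between sexes by t-test on
log values — Welch by default for robustness, Student's t available to
mirror the study exactly. The fold change is the ratio of arithmetic group
means of 2^-ΔCt, matching "on average x times higher"; the geometric
alternative is also reported. Kolmogorov–Smirnov normality (with estimated
moments, hence approximate) and Levene checks are reported, never gating.

## Splice assays

Transcript variants are compared to a gene model by coordinate intervals
(`exon_diff()`): missing exon → skipped; boundary truncation → 5'/3'
shortening with its bp delta (partial intronization); segments extending
past a boundary → intron retention (exonization); segments with no
overlapping model exon → novel exon. `virtual_pcr()` predicts end-point
RT-PCR products with full-length primer matching (default 0 mismatches,
always an exact 3'-terminal base — the polymerase extension rule, standard
PCR behaviour the study does not state) and reports gel-convention product
sizes inclusive of both primer footprints; multiple products are flagged
non-specific. The toy isoform generator reproduces the published structure
— a testis-only first exon carrying the DM domain with a 59 bp alternative
first exon in ovaries, and a testis cyp19a1 variant with exon 1 shortened
196→163 and exon 2 151→101 — and assay primers cut so the male-specific
assay yields 575 bp on testis dmrt1 only and the female-specific assay
207 bp on ovary cyp19a1 only (its reverse primer spans the full-length
exon1/exon2 junction, which the testis variant destroys).

## Numerical and design choices

* Quality threshold 13.0103 is derived, not tuned, from the 95% accuracy
  quote; the length filter keeps exactly-100 bp reads per the "< 100 bp
  removed" wording.
* Primer assignment and annealing budgets are 2 substitutions, no indels.
* Alignment rejection at ceil(5% of aligned length) plain mismatches.
* Degenerate inputs: all-tied groups give H = 0, p = 1 and a shared letter;
  a zero-SD truth is a point mass; an SD beyond the Beta bound falls back
  with a warning; empty reference coverage makes conversion efficiency NA
  with a warning.
* All randomness flows from one root seed through named substreams
  (`simulate_cohort`, `simulate_qpcr`, `simulate_isoforms` are individually
  reseeded), so every artefact is reproducible from (config, seed).

## Problem sizes used in the checks

The bundled recovery experiments run one amplicon at a time with the
published group parameters (n = 14 samples, 2,000 read pairs per sample,
conversion failure 0.005, error 0.001) and recover the group mean within
three standard errors of the configured truth; the qPCR recovery averages
100 simulated cohorts of n = 10 per sex. The cohort-level demonstration
uses all four differentially methylated genes at 150 pairs per amplicon —
enough for sub-point sampling error per cell — and checks the sign and
ordering of the sex differences. These sizes were chosen so the full suite
reruns in minutes on a laptop while keeping Monte-Carlo error well inside
every asserted tolerance.

## Limitations

Real-data quantities that depend on the study's unreleased MiSeq reads
(per-CpG group percentages, mapped-read counts, sex differences on real
fish, products on real accession transcripts) are out of reach at desk
scale; the package covers them through parameter-recovery and
property-based tests on its own simulator instead. The bespoke aligner is
amplicon-anchored and ungapped by design — it is not a general bisulfite
mapper, and indel-containing reads are rejected rather than realigned.
Non-CpG (CHG/CHH) methylation is not reported beyond the
conversion-efficiency QC.
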