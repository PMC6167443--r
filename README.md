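# lncsig

Calling and characterizing a regulatory T cell (Treg) lncRNA signature
from bulk RNA-seq counts, and testing whether that signature is shaped by
a master transcription factor (Foxp3).

## Who this is for

Immunogenomics analysts who have: a count table of naive CD4+ T cells vs
Tregs (and optionally Foxp3-deficient Tregs), a gene annotation
(GTF), a Foxp3 ChIP-seq peak set (BED), pairwise alignments of candidate
loci (aligned FASTA), and qPCR CT plates (TSV) — and who want the full
signature-characterization chain as small, testable, scriptable pieces.
A synthetic-data module plants every structure the analysis assumes, so
the whole pipeline also runs with no input data at all.

## What it computes

* **Differential expression** (`size_factors`, `estimate_dispersion`,
  `nb_wald_test`, `bh_adjust`): counts are modeled as negative binomial,
  `Var(K) = mu + alpha * mu^2`, with DESeq-style median-of-ratios size
  factors `s_j = median_i(k_ij / (prod_j k_ij)^(1/n))`, method-of-moments
  dispersion with an empirical-Bayes squeeze, and a Wald test on
  `log2FC = log2((mB + 0.5) / (mA + 0.5))` with BH-adjusted p-values.
  Plus `fpkm` and an expressed-feature filter.
* **Signature calling** (`call_signature`, `summarize_signature`): the
  core up/down sets at `padj < alpha`, partitioning the expressed lncRNA
  universe.
* **Positional classification** (`classify_positions`,
  `positional_enrichment`): sense / antisense / lincRNA by strand-aware
  span overlap with coding genes, an intronic flag, and Fisher-exact
  category enrichment of the core sets.
* **Peak colocalization** (`peak_flags`, `peak_enrichment`): ChIP-peak
  presence in promoter (default -2000/+500 bp of the TSS) or gene body,
  core-vs-background enrichment with frequency ratio and Fisher p.
* **Knockout reversal** (`reversal_report`, `mann_whitney`): does the
  signature collapse when the factor is lost — reversed fractions,
  one-sided Fisher enrichment, Mann-Whitney rank shift, and cross-dataset
  log2FC concordance (`cross_dataset_concordance`).
* **Conservation** (`find_ecrs`): conserved regions in a pairwise
  alignment — runs longer than 100 columns at > 70% identity.
* **qPCR** (`delta_ct`, `ddct_fold`, `knockout_check`): Livak 2^-ddCt
  with two reference genes and explicit handling of undetected wells.
* **Simulation** (`sim_config`, `simulate_annotation`, `simulate_peaks`,
  `simulate_counts`, `simulate_alignment`, `simulate_qpcr`): a seeded
  synthetic world with planted signature (190 up / 55 down of 2000
  lncRNA), doubled peak rate at core loci, 80% knockout reversal, and a
  lincRNA-heavy core placement — the ground truth travels alongside for
  recovery testing.

## Worked example

```r
library(lncsig)
cfg <- validate_config(list(seed = 1, out_dir = file.path(tempdir(), "demo")))
report <- run_pipeline(cfg)
print(report)
```

```
== lncRNA signature analysis ==
signature: 166 up, 56 down of 1998 expressed (11.1%)
peak colocalization: core 0.44 vs nondiff 0.25 (ratio 1.79, p = 2.91e-09)
KO reversal: up-set fraction 0.86 (Fisher p = 1.77e-72)
concordance: r = 0.745, rho = 0.300, sign = 0.56 (n = 1998)
```

Reading it: the pipeline calls 222 lncRNA differential at BH < 0.05
(11.1% of the expressed universe), drawn almost entirely from the 245
planted core features (the acceptance suite checks recall >= 85% and
false-discovery proportion <= 10% across 20 seeds); core
loci carry a ChIP peak 1.79x as often as the non-differential background
(planted: 2x); 86% of the called up-set drops by more than the reversal
threshold in the knockout; and log2 fold changes correlate r = 0.75 with
an independently re-simulated replicate dataset. Every stage writes its
table under `out_dir` (`de_naive_vs_treg.tsv`, `signature.tsv`,
`peak_flags.tsv`, `report.json`, ...), and re-running the same config
reproduces them byte-for-byte.

The reference-scale arithmetic check (190 up, 55 down, 1765 expressed):

```r
sig <- structure(list(up = sprintf("u%d", 1:190), down = sprintf("d%d", 1:55),
                      nondiff = sprintf("n%d", 1:1520), alpha = 0.05,
                      universe_size = 1765L), class = "signature_set")
summarize_signature(sig)$pct_differential
#> [1] 13.8
```

## Command line

```sh
Rscript inst/cli/lncsig.R simulate --seed 2 --out simdir
Rscript inst/cli/lncsig.R de --counts simdir/counts.tsv \
    --conditions simdir/conditions.tsv --lengths simdir/feature_lengths.tsv --out simdir
Rscript inst/cli/lncsig.R ecr --aln pair.afa --min-len 100 --min-id 0.70 --out .
```

Subcommands: `run | simulate | de | signature | classify | coloc |
reversal | concord | ecr | qpcr`. Exit codes: 0 ok, 2 validation error,
3 stage failure.

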