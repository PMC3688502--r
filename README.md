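# mirisc

Analysis of tissue-restricted **miRISC immunoprecipitation** experiments:
which miRNAs, and which target mRNAs, are loaded on the miRNA-induced
silencing complex in a tissue of interest?

The experimental design the package models is an AGO/GW182 pull-down (e.g. a
GFP-tagged GW182 protein expressed from a tissue-specific promoter) with
paired **IP** and **Total** (whole-lysate input) fractions across biological
replicates, assayed two ways:

* **small-RNA sequencing** of the IP and Total fractions, to find the
  miRNAs enriched in (or depleted from) the tissue's miRISC;
* **two-colour microarrays** of the co-immunoprecipitated mRNAs, to find the
  transcripts associated with the complex — the candidate miRNA targets.

It is written for computational biologists re-analysing such RIP-seq /
RIP-chip experiments, and ships a synthetic-data generator with planted
ground truth so the whole pipeline is testable offline.

## The statistics

**miRNA enrichment.** For each library, a miRNA's *relative concentration*
is its read fraction, `(reads of miRNA) / (total reads)` (with a 0.5
pseudocount). All relative concentrations are normalised to the lowest one
observed in the analysis and expressed in log2 (*relative abundance*), so
the global minimum maps to 0. Per miRNA, IP vs Total replicates are compared
with a two-sample Student's t-test (pooled variance, two-sided); calls at
p&nbsp;<&nbsp;0.01 are `enriched` or `depleted` by the sign of
Δ&nbsp;=&nbsp;mean(IP)&nbsp;−&nbsp;mean(Total), and folds are reported as
2^Δ (a Δ of −log2(19) prints as "19-fold depleted").

**Target enrichment.** Within each array replicate, the IP/Total signal
ratios of that replicate's reliably detected probes are converted to
*percent ranks*, `(rank − 0.5)/n` with average ties. Probes with reliable
signal in ≥ 2 replicates are *testable*. Each probe's ranks are tested
one-tailed (Welch t, probe&nbsp;>&nbsp;background) against the pooled ranks
of all testable probes; a gene keeps its minimum-p probe ("multiple probes
per gene removed, lowest p wins"; percent ranks are never altered by the
filtering). A fifth replicate from a second platform with a single probe per
gene is then merged in — its percent rank is appended to each gene's vector
and significance recomputed — and genes at p&nbsp;<&nbsp;0.001 (strict) are
called miRISC-associated.

**Seed-site statistics.** A miRNA's *perfect 7-mer site* is the reverse
complement of its nucleotides 2–8; the *control* is the reverse complement
of the site. Seed density is `matches / 1000 nt` of 3'UTR (overlapping
matches counted), reported relative to a reference set. UTR-length
distributions are compared with Mood's median test on a 400-point quantile
grid (every 0.25th percentile, chi-square on the 2×2 above/below table).

**Set statistics.** Gene-set overlaps use the upper-tail hypergeometric
probability `P(X ≥ k)` with expectation `|A||B|/|U|`; percent-rank shifts of
gene sets against all testable genes use a two-sided Student's t-test.

## Worked example

```r
library(mirisc)
study <- simulate_study(sim_config(seed = 1, n_mirnas = 120, n_genes = 2000))

fit <- mirna_enrichment(study$counts)
fit
#> miRNA IP-vs-Total enrichment (120 miRNAs, 4 replicates/fraction)
#>   Student's t (pooled variance), alpha = 0.01, pseudocount = 0.5
#>   enriched: 8   depleted: 15   neither: 97

summary(fit)   # the top of the call table:
#>        mirna delta_log2               fold         p   bh_fdr     call
#>  sim-miR-046     -2.713 6.56-fold depleted 3.801e-05 0.002972 depleted
#>  sim-miR-089      2.394 5.25-fold enriched 6.192e-05 0.002972 enriched
#>  ...

gfit <- target_enrichment(study$signals)
gfit
#> IP/Total percent-rank target enrichment
#>   1997 testable genes (4020 testable probes), background mean rank 0.500
#>   92 genes enriched at p < 0.001 (one-tailed Welch t vs pooled background)

enriched <- gene_set("enriched", gfit$genes$gene[gfit$genes$enriched])
sites <- seed_site(study$mirnas$seq)
density_report(enriched, study$utrs, sites, reference = gfit$genes$gene)
#>   n_genes total_matches density_per_kb frac_with_site relative_density ...
#>        92           283          16.56          0.957            2.185
```

Reading the output: 8 miRNAs are called IP-enriched and 15 depleted at
p < 0.01; 92 of 1997 testable genes associate with the complex at p < 0.001;
and the 3'UTRs of those genes carry miRNA seed sites at 2.19× the density of
all testable genes (their reverse-complement control density stays at
0.93×) — exactly the signature expected if the co-purified mRNAs are genuine
miRNA targets. With ground truth in hand,
`hypergeom_overlap(enriched, gene_set("planted", study$truth$target_genes),
gene_set("testable", gfit$genes$gene))` shows 83 of the 92 called genes are
planted targets (90.2% of the called set, expected overlap 3.9,
p ≈ 1.9e-135).

A shell entry point wrapping the same functions is provided:

```sh
Rscript scripts/pipeline.R report --out-dir out --seed 9
```

writes the simulated inputs, both enrichment tables, the seed-site report,
the truth overlap, summary histograms and a run manifest into `out/`.

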