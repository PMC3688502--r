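---
title: "Methods: miRISC IP enrichment, percent-rank target calling, and seed-site statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRISC IP enrichment, percent-rank target calling, and seed-site statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirisc)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, the numerical conventions chosen
where several were defensible, and what the synthetic-data tests do and do
not establish about real data.

## The experiment being modelled

A GW182/AGO-tagged miRISC is immunoprecipitated from a tissue of interest,
with the whole-lysate input ("Total") retained as the paired reference.
Small RNAs from IP and Total are sequenced across four biological
replicates; co-immunoprecipitated mRNAs are profiled on two-colour arrays
(IP vs Total) in four same-platform replicates plus one replicate from a
second platform that carries a single probe per gene. The contrast of
interest throughout is IP versus Total: material bound by the complex in
that tissue versus its overall abundance.

## miRNA enrichment

For one library with counts $c_i$, the relative concentration of miRNA $i$
is $(c_i + q) / \sum_j (c_j + q)$ with pseudocount $q$. All entries of the
miRNA × library matrix are then divided by the global minimum entry and
log2-transformed ("relative abundance"), so every value shares one scale
and the minimum maps to exactly 0. Per miRNA, the IP replicates' log2
abundances are compared with the Total replicates' by a two-sample t-test;
$\Delta = \bar{x}_{IP} - \bar{x}_{Total}$ is the log2 fold, $2^\Delta$ the
linear fold, and calls at $p < \alpha$ follow the sign of $\Delta$.

Parameter choices:

* **Pseudocount $q = 0.5$** (configurable). Zeros are routine in IP
  fractions of depleted miRNAs and the log transform requires positivity;
  0.5 is the usual half-count convention. Because the pseudocount enters
  both fractions symmetrically it does not bias $\Delta$ appreciably except
  at very low counts, where it shrinks folds toward 1 (conservative).
* **Pooled-variance Student's t, two-sided** (Welch available via
  `var_equal = FALSE`). With $n = 4$ per fraction and the same generative
  noise in both fractions, the pooled form is the natural reading of a
  "Student's t-test"; the Welch alternative is slightly conservative here.
* **The normaliser is the global minimum across all libraries**, not a
  per-library minimum: one shared reference keeps log2 values comparable
  between libraries, and it cancels in $\Delta$, so the test is invariant
  to this choice; it only fixes the scale of reported abundances.
* **$\alpha = 0.01$ on raw p-values**, the conventional screen threshold
  for this design; a Benjamini–Hochberg FDR column is emitted for
  information but plays no part in the calls.
* Degenerate inputs: identical constant groups give $p = 1$ (call
  `neither`); zero variance with unequal means is the limit $|t| \to
  \infty$ and gives $p = 0$.

## Target enrichment from arrays

Order of operations, which matters:

1. Per replicate, the reliably detected probes' IP/Total ratios are
   converted to percent ranks $(r - 0.5)/n$ (average ties). The transform
   is symmetric with mean exactly 0.5, avoids the 0/1 endpoints that break
   t-statistics, and makes replicates comparable regardless of their
   dynamic range. "Reliable" is a boolean per probe × replicate × channel
   supplied with the data (the generator emits it; real-data users derive
   it from their platform's detection calls — the package deliberately does
   not guess a detection rule).
2. Probes reliable (both channels) in ≥ `min_reliable = 2` replicates are
   *testable*.
3. Each testable probe's rank vector is tested one-tailed (probe >
   background) against the pooled ranks of all testable probes. The Welch
   form is used because the two "samples" (4–5 values vs tens of
   thousands) have wildly unequal sizes and variances; the pooled form
   would let the probe's own variance be swamped.
4. Genes keep their minimum-p probe across transcripts; ties break by
   larger mean rank, then lexicographic probe id (deterministic). Ranks
   are never recomputed after filtering.
5. The second platform's single-probe percent ranks are appended per gene
   and significance recomputed over the extended vector; its ranks also
   join the background pool (disable with `p2_in_background = FALSE`).
   Second-platform genes absent from the primary platform would carry a
   single value and are dropped, logged.
6. Genes at $p < 0.001$ (strict inequality) are called miRISC-associated.

The probe-level test is used as a ranking device, exactly as in the
original screen design: the min-p collapse is a selection step without a
multiplicity correction, so gene-level p-values are anti-conservative in a
known, documented way, and the null mean percent rank after collapse sits
slightly above 0.5 (about 0.53 under the generator's defaults) rather than
at 0.5.

## Seed-site statistics

The perfect 7-mer site of a miRNA is the reverse complement of its
nucleotides 2–8 (1-based, 5'→3'); the control sequence is the reverse
complement of the site — identical base composition, no targeting meaning.
Matches are counted overlapping, independently per site (a position
matching two distinct sites counts twice); `N` never matches. These
conventions are oracle-checked against a naive per-position counter and are
switch-free by design: density comparisons are ratios, so any consistent
convention cancels.

Density is matches per 1000 nt over a gene set's UTRs (one UTR per gene:
the longest annotated, ties broken lexicographically), reported relative to
a reference set — typically all testable genes. UTR-length distributions
are compared with Mood's median test after reducing each set to 400
quantile points (probabilities $i/400$): counts above/not-above the grand
median of the 800 points form a 2×2 table tested by chi-square with 1 df,
no continuity correction. Quantile type 4 (linear interpolation of the
ECDF) is used because it is the convention under which a 400-point vector
is returned unchanged by its own grid — the natural fixed point of the
procedure. Constant inputs, or tables with an empty margin, return $p = 1$
with a warning rather than `NaN`.

## Set statistics

Overlap p-values are upper-tail hypergeometric including the observed
count, $P(X \ge k)$ — the standard over-representation convention — with
expectation $|A||B|/|U|$. Set members outside the universe are dropped with
a logged count (published gene lists routinely exceed a given array's
universe) rather than raised as errors. Mean-percent-rank comparisons of a
set against all testable genes use a two-sided pooled t-test.

## The synthetic-data generator

The generator exists so that every stage is testable, with known truth,
offline. Its defaults are the study conditions the pipeline targets:

* **Small RNA**: 250 miRNA species (the scale of the *C. elegans* mature
  complement), baselines log-uniform over 4 orders of magnitude, 4 paired
  IP/Total libraries at a nominal depth of 5×10^6 miRNA-mapped reads
  (typical of Illumina small-RNA libraries; per-library depths jittered
  within 2× so enrichment is never confounded with depth), negative
  binomial counts with dispersion 0.1, 6.5% planted enriched and 13%
  planted depleted miRNAs at |log2 fold| = 2.
* **Arrays**: 17,673 genes, 1–3 probes per gene on the primary platform
  plus one single-probe replicate from a second platform; log-normal
  baseline intensities; 4.2% planted target genes at log2 fold 2 on the IP
  channel; detection flags dropped out independently at 5%. Ratio noise is
  decomposed into a gene × replicate biological component (sd 0.2 on the
  log scale per channel) shared by all probes of a gene — a gene's probes
  measure the same mRNA in the same replicate — plus a smaller probe-level
  technical component (sd 0.12). This correlation structure is what makes
  min-p probe collapsing behave realistically; fully independent probe
  noise would overstate within-gene spread and inflate the collapse bias.
* **UTRs**: lengths log-normal with median 140 nt (worm 3'UTRs are short),
  uniform ACGT background, and `planted_sites_per_target = 2` seed sites
  of the planted-enriched miRNAs written at non-overlapping positions in
  each target gene's longest UTR. Background UTRs are untouched, so their
  matches arise by chance only (expected ≈ length/4^7 per site).

All randomness flows from one seed; each generator draws from a fixed
derived stream, so any stage's output is reproducible in isolation.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: mapping and annotation error in read
counting; isomiRs; cross-hybridisation and sequence-dependent probe biases
(probe affinity is modelled, but independent of sequence); intensity-
dependent detection dropout (dropout is uniform); correlated biological
replicates from shared culture batches; realistic base composition and
dinucleotide structure of UTRs (so chance seed-match rates are those of a
uniform alphabet); and genuine miRNA::target network structure. Recovery
rates measured on the generator are best-case values under a correctly
specified noise model.

## Problem sizes used in validation

The test suite validates calibration and recovery at sizes chosen to keep
estimator noise well below the tolerances being checked: null calibration
on 10,000 simulated miRNAs (binomial SE ≈ 0.1 pp on a 1% rate) and 5,000
genes; recovery on 10 seeds of 300 miRNAs / 3,000 genes; seed-density
separation on 20 seeds of 1,000 genes with 100 miRNAs (so chance-match
counts are large enough that the control ratio concentrates within ±20%).
The same computations, re-seeded, are what `scripts/acceptance.R` reports.

## Known limitations

* The probe-level one-tailed test inherits the anti-conservativeness of
  min-p probe selection, as discussed; treat gene p-values as a ranking.
* `relative_abundance` depends on the smallest observed fraction, which is
  itself noisy; this affects only the reported scale, never $\Delta$ or p.
* The Mood's-median quantile grid deliberately compresses large samples to
  400 points; for very unequal set sizes the test is approximate by
  construction.
* File formats are strict (TSV without quoting, FASTA through Biostrings);
  the parsers fail loudly rather than guessing.
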