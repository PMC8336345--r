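---
title: "Methods: synthetic SNP-array cohorts, multi-caller CNV consensus, and case-control CNVR association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic SNP-array cohorts, multi-caller CNV consensus, and case-control CNVR association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope

`cnvrassoc` implements a genome-wide case-control analysis of copy number
variation (CNV) called from SNP-array intensity data, of the kind used in
glaucoma and other common-disease CNV studies: three independent callers are
run per sample, calls are subjected to stringent sample- and call-level
quality control, multi-caller consensus calls are pooled into CNV regions
(CNVRs) defined by innermost boundaries, and the CNVR catalogue is tested
for case-control differences (burden, per-CNVR Fisher exact with FDR,
cross-cohort meta-analysis), followed by gene-set overrepresentation and
expression-percentile interpretation stages. Because raw genotype data of
such studies is typically restricted-access, the package ships a
synthetic-cohort generator as its canonical input source; every analysis
stage is equally usable on real final-report-style signal files.

## The signal model

Each sample is a pair of per-marker tracks over an ordered autosomal SNP
map:

* **LRR** (LogR ratio), a log-scale normalized total intensity, with mean 0
  in the diploid state, negative under deletion, positive under duplication.
* **BAF** (B-allele frequency), the fraction of signal attributable to the B
  allele: near 0, 0.5 or 1 for diploid genotypes, and at the allelic ratios
  implied by the carried copy number otherwise (e.g. copy number 1 yields
  {0, 1}; copy number 3 yields {0, 1/3, 2/3, 1}).

The simulator and all three callers share one emission model:

* LRR \(\sim \mathcal N(\mu_{CN}, \sigma)\) with per-state means
  \(\mu = (-3.5, -0.66, 0, +0.40, +0.68)\) for CN 0–4. Only the sign
  semantics of LRR are fixed by the assay; the numeric means follow the
  widely used SNP-array convention (the homozygous-deletion mean is far
  below the single-copy band because the log of a near-zero intensity
  diverges). Sharing one emission model across simulator and callers is a
  deliberate design choice: it makes multi-caller *consensus* meaningful as
  a comparison of decision structures (hidden-Markov path decoding vs Bayes
  factors vs maximal-scoring Gaussian segments) rather than a comparison of
  incompatible signal models.
* BAF is a mixture over B-allele counts \(b = 0..CN\) with
  \(\mathrm{Binomial}(CN, p)\) weights, where \(p\) is the marker's
  population B-allele frequency; each component is a truncated normal on
  \([0,1]\) centred at \(b/CN\). Homozygous bands get one quarter of the
  heterozygous-band SD (arrays compress the tails). CN 0 has no allelic
  signal and emits uniform BAF.

The map generator draws exponential inter-marker gaps (the real spacing
distribution of any particular array is not modelled; exponential gaps are a
stand-in with the right mean), a sinusoid-plus-noise GC profile so GC-wave
artifacts can be injected and corrected, and uniform population B-allele
frequencies on (0.05, 0.95). Carriers of each implanted locus are drawn
independently per sample at the phenotype-specific design frequency — a
frequency-level model, adequate for carrier-count statistics, not a diploid
two-allele model.

## The three callers

All callers operate per sample and emit calls whose boundaries are marker
positions (1-based inclusive):

* **HMM caller** (PennCNV-style): Viterbi decoding over states CN 0–4 with
  distance-dependent self-transition
  \(1 - (1 - p_{stay})(1 - e^{-d/D})\) (defaults \(p_{stay} = 0.999\),
  \(D = 100\) kb), initial mass 0.999 on the diploid state and the rest
  uniform over non-diploid states. Contiguous non-diploid runs become
  calls; confidence is the segment's log10 likelihood ratio against
  diploid.
* **Bayes-factor caller** (QuantiSNP-style): GC-corrects LRR first, then
  the same segmentation; confidence is `MaxLogBF`, the maximum log10 Bayes
  factor of any non-diploid state against diploid over the segment.
  Downstream QC keeps only `MaxLogBF` strictly greater than 10.
* **Gaussian-partition caller** (cnvPartition-style): no chain; each marker
  is scored with the log-likelihood advantage of its best non-diploid state
  over diploid, all maximal-scoring segments of that advantage are
  extracted (Ruzzo–Tompa), and segments reaching the confidence threshold
  (35, log10 scale) become calls.

The equivalence of these callers to the programs that inspired them is
structural, not numerical: those tools' internal parameters are not public,
and re-creating their decision shapes over one shared emission model is
exactly what makes the downstream two-of-three consensus rule a meaningful
filter in simulation studies.

Numerical choices: the per-track emission SD is estimated robustly
(1.4826 × MAD, floored at 0.01) so that implanted segments do not inflate
the noise estimate; Viterbi and the maximal-segment extraction are exact
dynamic programming/linear-time algorithms implemented in C++ and are
checked in the test suite against exhaustive path enumeration and
brute-force segment enumeration.

## Quality control

Sample-level exclusion rules (a sample violating any limit of a caller is
excluded; the pipeline removes it from the cohort entirely and logs the
reason codes):

| caller | limits |
|---|---|
| HMM | SD(LRR) > 0.35, BAF drift > 0.01, |GC-wave factor| > 0.05, > 50 calls |
| Bayes | SD(LRR) > 0.25, SD(BAF) > 0.3, outlier rate > 0.01, > 50 calls |
| Gaussian | > 50 calls (its stringency is the call confidence threshold) |

BAF drift is the fraction of markers with BAF in (0.2, 0.25) ∪ (0.75, 0.8)
(the customary off-cluster bands; the metric is named but not defined by the
programs that report it), the GC-wave factor is the slope of LRR regressed
on standardized local GC, SD(BAF) is the SD of the distance from BAF to its
nearest canonical band {0, 0.5, 1}, and the outlier rate is the fraction of
|LRR| > 1.

Call-level rules: at least 5 probes, at least 5 kb (lengths are
`end − start + 1`, 1-based inclusive), confidence at least 10 for the HMM
caller, strictly above 10 for the Bayes caller, at least 35 for the Gaussian
caller. Calls whose overlap with the union of exclusion regions (telomeres,
centromeres, immunoglobulin loci, segmental duplications; supplied as BED)
reaches 50% of the call length are removed. Neighbouring same-type calls of
one sample merge when the gap is strictly less than half their combined
length, iterated to a fixpoint.

## Consensus calls and CNVRs

A consensus call needs the same event from at least two distinct callers
with consistent copy-change type and pairwise reciprocal overlap ≥ 0.5 (the
overlap must cover half of *both* intervals; the threshold is configurable —
the originating studies say "reciprocally overlapping" without a number, and
0.5 is the field's convention). Groups form greedily from the
leftmost-starting unused call, each caller's call supports at most one
consensus call, and the consensus interval is the common intersection.

CNVRs are built per chromosome and copy type by a deterministic sweep:
consensus calls are pooled across samples and accumulated while the running
intersection (max start, min end) stays non-empty; when a call starts past
the running intersection the accumulated intersection is emitted as a CNVR
and the sweep restarts from that call, retaining still-overlapping members.
This resolves the ambiguity of "innermost boundaries" for overlap chains
whose common intersection is empty, guarantees that every contributing call
fully covers its CNVR, and makes same-type CNVRs on a chromosome pairwise
disjoint. Loss and gain are tracked separately, so one locus can yield two
CNVRs. CNVRs carried by fewer than 1% of the cohort are dropped.

## Association statistics

* **Burden**: per-sample load metrics (number of CNVs, any-CNV indicator,
  total kb; with a gene list also genes spanned, any-gene indicator, genes
  per kb) are compared as case mean − control mean with a one-sided
  (cases > controls) phenotype-label permutation test, default
  n = 10,000 permutations, p = (1 + #{perm ≥ obs}) / (1 + n) so p never
  reaches 0.
* **Per-CNVR association**: the two-tailed Fisher exact test evaluated by
  the probability-mass rule — the sum of hypergeometric probabilities of
  all tables (margins fixed) no more probable than the observed one, with a
  1 + 1e-7 relative slack against floating-point ties (the dominant
  software convention; the tail rule is not specified by the name of the
  test alone). Benjamini–Hochberg FDR is applied over *all* tested CNVRs —
  published tables print only significant rows, so printed adjusted
  p-values are not comparable across family sizes and are not asserted.
* **Meta-analysis**: for genes annotated to significant CNVRs in both
  cohorts, Fisher's combined probability test
  \(X = -2\sum\ln p_i \sim \chi^2_{2k}\), with degrees of freedom twice the
  number of p-values combined (all type-rows listed for the gene enter),
  BH-adjusted over the shared genes.
* **Pathway enrichment**: per sample, the fraction of CNV-overlapped genes
  belonging to the pathway; the case mean − control mean of that ratio is
  tested by two-sided label permutation. The per-sample normalisation is
  what absorbs case-control differences in CNV size and rate distribution.
  Samples whose CNVs overlap no gene contribute a ratio of 0.
* **Power**: the noncentral chi-squared goodness-of-fit power at Cohen's
  effect size w, \(\lambda = n w^2\), upper tail at the central
  1 − α critical value.

## Annotation and expression stages

Genes are assigned to intervals on ≥ 1 bp of overlap (GenomicRanges).
Overrepresentation of a query gene set against term→gene annotation (GMT)
uses fold enrichment \((q/Q)/(m/N)\), a one-sided hypergeometric tail in the
direction of the deviation, and Bonferroni correction over the tested terms;
fold-enrichment values computed against a live annotation database are
version-dependent and are not asserted against published values.

Expression-percentile selection ranks each query gene within a tissue
column of a PLIER-normalized expression table: a gene is *high* if more
than 90% of the column's genes lie strictly below it and *low* if fewer
than 10% lie at or below it. With this tie-handling an all-equal column
selects nothing in either direction. Percentiles are computed within-tissue
across **all** genes of the supplied table (the plausible reading of
ranking a gene list against a reference expression database; the
alternative — ranking within the query only — would make membership depend
on the query's size). The bundled
`inst/extdata/otdb_plier_subset.tsv` reproduces a published ocular-tissue
expression excerpt for the genes selected there.

## Synthetic study conditions

The standing recovery experiment (`recovery_study()`, also used by the
acceptance script) fixes:

* one chromosome, 2000 markers, mean spacing 3 kb (≈ 6 Mb);
* a 50-probe deletion at 20% case / 2% control carrier frequency (the
  association signal) and a 50-probe duplication at 10% / 10% (a
  frequency-matched null measuring the association stage's false-positive
  rate);
* 300 cases + 300 controls per cohort, LRR noise SD 0.2, heterozygous BAF
  noise SD 0.03.

Both loci span ~2.5% of the map. This proportion matters: sample-level QC
metrics (SD of LRR, GC-wave factor) are whole-track statistics, and on a
real genome-wide array a CNV is a negligible fraction of the markers. On a
desk-scale map a proportionally huge implant would inflate those metrics
and QC would (correctly, by its own rules) drop exactly the carrier
samples. Keeping implants at a few percent of the map preserves the
regime the QC thresholds were designed for.

What the generator does *not* emulate: raw two-channel intensities and
genotype clustering, linkage between markers, relatedness and ancestry
structure, batch/plate effects, waviness beyond a single GC covariate, sex
chromosomes and mitochondria. Passing recovery tests therefore show that
the pipeline's decision rules recover frequency contrasts under the stated
noise model — not that any particular real dataset would yield the same
catalogue.

Problem sizes used by the test suite and the acceptance script (50 and 20
replicates of the 600-sample study, 500 null-calibration replicates with
199 permutations each, 10,000 permutations for single burden runs) were
chosen once as the smallest sizes at which the binomial/KS acceptance
margins are meaningful.

The burden-test null calibration simulates exchangeable per-sample CNV
counts with a vanishing continuous jitter: permutation p-values are uniform
only for (effectively) continuous statistics, and heavily tied integer
statistics make the +1-corrected p conservative by construction.

## Determinism and degenerate inputs

Every stochastic operation takes an explicit integer seed, restores the
caller's RNG state, and is bit-reproducible; `run_pipeline()` derives all
stage seeds from the single configured seed, so reruns are byte-identical.
Degenerate inputs fail fast with a classed `invalid-argument` condition:
empty tracks and cohorts, loci outside the map, inverted intervals,
single-class phenotype vectors, p-values outside (0, 1], zero cohort sizes,
unknown callers and unknown configuration keys. Filters never return
silently-modified data: every dropped sample or call carries
machine-readable reason codes.

## Known limitations

* The callers share one emission model by design; consensus rates between
  *real* PennCNV/QuantiSNP/cnvPartition runs will be lower than in
  simulation.
* The carrier model is frequency-level (no diploid two-allele model, no
  de-novo events, no mosaicism).
* The CNVR copy-type is binary (loss/gain); a CN0 and CN1 call of one locus
  fall into the same loss CNVR.
* Meta-analysis matches cohorts by gene symbol, not by coordinates; CNVR
  harmonisation across cohorts beyond shared genes is out of scope.
* Printed length conventions differ across published CNV tables (some print
  `end − start + 2`); this package stores and prints 1-based inclusive
  lengths (`end − start + 1`) throughout.
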