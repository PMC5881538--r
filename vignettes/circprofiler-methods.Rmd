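---
title: "Methods: backsplice detection and expression profiling at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: backsplice detection and expression profiling at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circprofiler)
```

## What the package computes

circprofiler profiles circular RNA alongside mRNA and lncRNA from
single-end, rRNA-depleted RNA-seq reads. The chain is: quality filtering of
raw reads; full-length linear alignment to the genome; discovery of
head-to-tail (backsplice) junctions among the reads that fail to align
linearly; quantification of every called junction by realignment to a
pseudo-circular reference; negative-binomial differential expression applied
uniformly to mRNA, lncRNA and circRNA count tables; Fisher-exact functional
enrichment with GO-tree and pathway-relation networks; and condition-specific
Pearson co-expression networks analysed through degree centrality, W-cores
and differential hubs.

A circRNA arises when a splice donor joins an *upstream* acceptor, producing
a covalently closed transcript. The only sequence evidence unique to the
circle is the head-to-tail junction: reads that cross it align in two pieces
whose genomic order is reversed relative to their order on the read. All
detection logic in this package follows from that observation.

## The backsplice detection model

**Linear pass.** A read is linearly mapped iff it has a full-length
alignment — contiguous, or split across exactly one annotated intron — with
at most `max_mismatches` substitutions. The aligner is a k-mer
seed-and-extend search (default k = 15) over both genome strands plus
exon–exon junction constructs of width `read_length − 1` per side.
`max_mismatches + 1` non-overlapping seeds per read make the search complete
by pigeonhole: if every seed misses, the read has more than `max_mismatches`
substitutions. The mismatch tolerance should mirror the error model of the
library; for error-free simulated reads the natural operating point is 0.

**Segment discovery.** Unmapped reads are decomposed into maximal local
matches (segments) by dense k-mer seeding and extension, with one tolerated
mismatch per `mismatch_per` aligned bases (set `Inf` for exact extension
when the error rate is zero) and a minimum segment score of 18, a floor in
the spirit of the minimum-seed/minimum-score settings of local aligners
used for this task. When two segments of one read overlap in read
coordinates — the signature of sequence homology across the junction — the
later segment's head is trimmed, so the retention rules below can assume
disjoint read intervals; the resulting joint coordinate shift is undone by
the score-based refinement.

**Retention rules.** For each read, an ordered segment pair (A earlier on
the read, B later) is kept as a junction candidate iff both segments are on
(a) the same chromosome, (b) the same strand, and (c) in reversed genomic
order — B upstream of A on the plus strand, mirrored on the minus strand —
with a genomic span of at most 1 Mb. The candidate acceptor is B's genomic
start and the donor is A's genomic end (mirrored on the minus strand).

**Short-arm rescue.** A junction read whose breakpoint lies near one end
has one arm below any honest local-alignment floor (an 18-nt minimum
segment cannot anchor a 6-nt arm). Such reads still carry one long,
unambiguous segment. Guided by that anchor, the unexplained remainder of
the read is searched *exactly* within the 1-Mb window on the same chromosome
and strand, in the orientation a head-to-tail junction requires, and every
placement becomes a raw candidate. This mirrors the two-step logic of
realignment-based quantification, applied at discovery time. Remainders
down to 4 nt are searched (micro-homology can shave the arm below the
nominal 6-nt overhang floor; refinement restores the coordinates). Spurious
placements are eliminated downstream: each read supports at most one
junction (its best-scoring one), junctions need at least two distinct
supporting reads, and the splice score threshold removes random placements,
whose expected score is far below zero.

**Junction refinement.** The junction coordinate is ambiguous exactly when
the genome repeats across it: junctions (a, d) and (a+1, d+1) produce the
same junction-spanning sequence iff `genome[a] == genome[d]`. The
sequence-consistent shifts therefore form a contiguous run around zero; all
shifts in that run (clipped to ±`shift_window`, default 10) are scored and
the shift with the highest donor + acceptor splice strength wins, ties going
to the smallest acceptor coordinate.

**Splice-site scoring.** The scorer is pluggable. The default is a
first-order position weight matrix with the classic window geometry — a 9-nt
donor window (3 exonic + 6 intronic bases) and a 23-nt acceptor window
(20 intronic + 3 exonic) — trained on the annotation's own splice sites with
add-one smoothing, scored as log2-odds against the genome's base
composition. The default reporting threshold is a summed donor + acceptor
score of 10; with a trained PWM this is a configurable operating point on
the package's own score scale, calibrated here so that canonical annotated
sites score well above it and random sequence far below (a random window
pays roughly −5 per non-consensus base at a near-invariant position). The
alternative `min(donor, acceptor)` aggregation is a one-line change in
`call_circrnas()` input preparation; the sum is the default because a
single-number threshold is applied to it.

**Calling.** Junction candidates are aggregated by (chromosome, strand,
acceptor, donor); a junction is reported iff it has at least 2 distinct
supporting reads and a splice score of at least 10 (both inclusive). Host
genes are same-strand genes whose span contains the junction; when several
overlap, all are listed and the first by coordinate is used for
per-gene multiplicity statistics.

**Quantification.** Each call receives a junction construct: the circle's
last `L − 6` bases concatenated with its first `L − 6` bases (L = read
length), assembled from the host gene's annotated exons inside the circle
(genomic span as fallback), wrapping for circles shorter than one arm. The
construct length is chosen so that *any* read fully contained in it
necessarily covers at least 6 nt on both sides of the midpoint — the
overhang rule becomes equivalent to containment, and counting reduces to
substring alignment (2 mismatches tolerated by default; exact matching is
the fast path). A read counts for at most one circle: fewest mismatches,
ties to the lexicographically smallest identifier.

## Differential expression

The DE machinery is the classic negative-binomial exact-test formulation:

* **Size factors** are median-of-ratios: the per-sample median, over
  features with nonzero counts in all samples, of the count divided by the
  feature's geometric mean.
* **Dispersion** is method-of-moments on normalized counts with variance
  pooled within conditions, `alpha = max(0, (s² − mu)/mu²)`, then taken
  conservatively as the maximum of the per-feature value and a least-squares
  mean–dispersion trend `a0 + a1/mu`. The maximum rule deliberately
  sacrifices a little power to protect the type-I error at n = 3 per
  condition, where per-feature moments are extremely noisy.
* **The exact test** conditions on the two condition sums. A group sum of n
  samples with per-sample dispersion alpha has dispersion alpha/n (NB size
  n/alpha); the two-sided p-value sums the probabilities of all splits of
  the total at most as probable as the observed one. As alpha → 0 the test
  converges to the conditional binomial exact test, which the test suite
  uses as a closed-form oracle.
* **Thresholds** follow the strict rule: up iff fold change > 2 and
  FDR < 0.05, down iff fold change < 0.5 and FDR < 0.05. Fold change is the
  tumor/normal ratio of normalized means; a zero reference mean yields an
  infinite fold change, which passes the fold-change criterion and stands or
  falls with the FDR. Benjamini–Hochberg adjustment is implemented directly
  (step-up with monotonicity, capped at 1) and cross-checked against both a
  brute-force evaluation of the definition and `p.adjust`.

The same machinery is applied unchanged to the circRNA junction-count
table, with samples quantified independently against a shared call set.

## Enrichment and networks

Enrichment is the one-sided hypergeometric upper tail of the query/term
overlap against a user-supplied background, BH-adjusted across terms; terms
with no background gene are skipped. The GO tree is the DAG induced by
terms with p < 0.01 plus all ancestors, annotated by the direction
(up/down-regulated query) in which each term is significant. The pathway
network links enriched pathways that share differentially expressed genes,
weighted by the Jaccard index of their DE-gene sets (curated pathway
relation maps are licensed data; a relation edge list can be supplied as an
optional input instead). Core pathways are the top-degree nodes.

Co-expression networks are built per condition from size-factor-normalized,
log2(x+1) counts — the log transform stabilises Pearson correlation at low
counts. Edges require |r| ≥ 0.9 and a BH-adjusted t-distribution p ≤ 0.05
(df = n − 2, hence the hard requirement of ≥ 3 samples); both cutoffs are
parameters, since "significant correlation" is a study choice. Degree
centrality is the raw incident-edge count. The W-core is the maximal
subgraph in which every node keeps at least W neighbours inside the
subgraph, computed by iterative pruning (it equals the classic k-core with
k = W; the suite verifies it against exhaustive subset enumeration and
`igraph::coreness`). Differential core regulators are ranked by the
absolute between-condition degree difference, ties broken by the larger
maximum degree and then lexicographically.

## The synthetic data generator

The generator is first-class, tested code; it defines the study conditions
under which the pipeline's properties are verified.

* **Genome**: uniform random DNA chromosomes (default 3 × 100 kb) with 40
  genes placed round-robin, 3–6 exons of 100–300 nt separated by introns of
  100–400 nt, 70% mRNA / 30% lncRNA, strands random. Terminal UTR stretches
  are annotated on mRNA genes so region tallies can distinguish UTRs.
* **Splice sites**: every intron carries GT…AG embedded in
  consensus-biased donor/acceptor motifs (pyrimidine tract, near-invariant
  positions modeled on the U2-type consensus). Sites are drawn from the
  motif matrices *conditional on a minimum log-odds strength* (donor ≥ 6,
  acceptor ≥ 7 against a uniform background) — functional splice sites are
  consensus-constrained, and an annotated site that a trained PWM cannot
  distinguish from background would not be spliced in the first place. This
  conditioning fixes the operating point at which the score threshold of 10
  separates true junctions from random placements.
* **Circles** are exon-bounded ranges of *internal* exons of ≥3-exon hosts
  — both circle boundaries must be genuine splice sites, which terminal
  exons lack on one side. One host always receives two distinct circles so
  per-gene multiplicity is exercised. Spans never exceed 1 Mb.
* **Reads**: linear reads are uniform substrings of spliced transcripts at
  Poisson depth; junction reads are drawn uniformly over the positions with
  at least 6 nt on each side of the backsplice, from the circular
  (wrap-around) sequence, so the expected counted reads equal the simulated
  reads and quantification can be tested for exact equality. Qualities are
  constant Q35 except deliberately degraded contaminants (which carry
  excess N and low-quality tails to exercise QC); substitution errors and
  N injection are optional. Read names carry an `origin:source:pos` suffix
  for per-read audit.
* **Counts**: log-normal base means, NB noise with a common dispersion,
  spiked fold changes applied to the tumor condition, spiked features drawn
  with base mean ≥ 100 so the spike is detectable at a 3-vs-3 design.

What the generator deliberately does *not* model: positional and GC bias,
indels and structured error profiles, rolling-circle amplification,
intron-retaining (lariat) circles, pooling variance of pooled tissue
samples, and genuinely overlapping gene loci. Passing tests therefore
demonstrate correctness of the algorithms under clean assumptions, not
robustness to every artefact of real libraries.

## Numerical and policy choices

* Coordinates are 0-based half-open internally; GTF is read/written 1-based
  inclusive; BED output is 0-based half-open.
* QC removal uses strict inequalities ("more than"): a 100-nt read with
  exactly 5 Ns or exactly 20 bases under Q13 is kept. Filters are evaluated
  after adaptor trimming; a 20-nt length floor removes degenerate survivors.
* Alignment ties are resolved to the lowest (chromosome, position),
  contiguous before spliced placements — counts stay deterministic.
* Junction-read assignment: one junction per read (highest splice score),
  one circle per read in quantification (fewest mismatches, then smallest
  id) — no read is double-counted.
* `-Inf` is the score sentinel for windows containing N; a candidate whose
  every consistent shift is unscorable keeps its coordinates with score
  `-Inf` and cannot pass the call threshold.
* Degenerate DE features (all-zero) get p = 1 and an undefined fold change.
* The exact-test enumeration is O(total count) per feature; at the
  simulated depths (totals of a few thousand) this is well under a second
  per thousand features.

## Problem sizes used by the test suite

The shipped tests and the acceptance script run entirely on generated data:
the detection study uses 3 × 100 kb chromosomes, 40 genes and 20 circles
(roughly 2,000 reads); the specificity study 50,000 linear and 1,000 noise
reads; DE calibration 20 null simulations of 1,000 features plus 5 spiked
ones; the statistical and graph oracles hundreds of randomized small
instances. These sizes were chosen so each property is exercised with
comfortable margins while a full run stays in the minutes range on one
core.

## Known limitations

* The built-in aligner handles substitutions only (no indels) and splits
  reads across at most one annotated intron; it is a desk-scale stand-in
  whose contract — full-length linear alignments plus local segments — is
  what the detection stage consumes. External alignments in SAM form can be
  ingested instead.
* The default splice scorer is a first-order PWM; its scores are not on the
  scale of maximum-entropy models, and the threshold of 10 is an operating
  point on the package's own scale.
* Detection support counts (`n_backspliced_reads`) can fall marginally
  below the realigned junction counts, because discovery requires an
  anchored long arm while quantification only requires the 6-nt overhang;
  expression analysis should always use the quantified counts.
* The exact test covers a two-condition design without covariates; the
  fold-change/FDR rule is the only filtering applied.
* A junction read whose short arm happens to match the linear genomic
  continuation of its long arm is absorbed by the linear pass — it is,
  genuinely, consistent with a linear transcript. At a 6-nt minimum
  overhang this affects about one read in four thousand; per-circle counts
  can therefore occasionally fall one read short of the simulated truth at
  unlucky seeds. This is an identifiability limit of junction evidence, not
  a counting defect.
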