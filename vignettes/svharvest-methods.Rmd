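---
title: "Detecting large structural variants in mutagenized strains: methods and design"
author: "svharvest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting large structural variants in mutagenized strains: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Random mutagenesis screens in small-genome animals (the motivating system
is *C. elegans*, ~100 Mb, mutagenized with trimethylpsoralen/UV-A, inbred
to homozygosity over ~10 generations and resequenced at 15–20x with
single-end ~120 bp reads) produce strains carrying a handful of large
(>= 50 bp) structural variants each: mostly deletions, with tandem
duplications/multiplications, insertions, complex deletion-insertions,
inversions and rare translocations.  Harvesting these variants from
whole-genome resequencing requires (i) base-resolution breakpoint
detection, (ii) an orthogonal copy-number signal to corroborate losses
and gains, (iii) a zygosity call, (iv) removal of background variants
shared across sibling strains, (v) functional annotation, and (vi) a
triage step that separates true variants from alignment artifacts, for
which classical machine-learning classifiers trained on PCR-confirmed
calls work well.  `svharvest` implements this whole stack, plus a
deterministic simulator so every step is testable at desk scale.

# Detection model

## Split reads

A read crossing a structural-variant junction aligns in two pieces: a
primary alignment ending (or starting) at the breakpoint, and a
soft-clipped tail.  `extractClipped()` collects every soft clip of at
least `min_clip_len` bases (default 15 bp: shorter clips realign
non-uniquely on genomes of this size); the clip boundary on the primary
alignment is the breakpoint anchor.  Hard clips carry no sequence and
are ignored.

`realignClip()` maps the clip (or its reverse complement) back to the
reference, requiring full-length identity of at least `min_identity`
(default 0.95).  Matching is exact-first, then mismatch-tolerant, using
the `Biostrings` pattern matcher over the whole genome — a deliberate
choice over a seed-and-extend heuristic: at desk scale the exhaustive
matcher is fast, bit-deterministic, and trivially comparable against a
brute-force oracle (the test suite does exactly that).  Clips with more
than one equally good locus are discarded as ambiguous rather than
assigned; this conservatism is what keeps the false-positive count at
zero on clean data.  When the full clip has no locus, an
anchor-and-extend pass strips a novel (inserted) prefix: the terminal
bases away from the junction are matched exactly and extended toward
the junction; the unmatched remainder is the inserted sequence.

## Break-site patterns

Classification happens in reference geometry of the stored (SEQ-space)
alignment, which is always reference-forward, so the primary alignment
strand never enters the rules: a collinear hit downstream of a
right-side anchor is a deletion (the gap is the deleted length); a hit
back upstream is a tandem duplication; a zero gap with a novel segment
is an insertion, a positive gap with a novel segment a
deletion-insertion; an opposite-strand hit is an inversion breakend; a
cross-contig hit a translocation.  One subtlety: when inserted bases
coincide with the reference bases adjacent to the junction, the same
mutated sequence has several equivalent (start, end, inserted-sequence)
descriptions, and the realignment naturally finds the
maximally-extended one.  The classifier recognises these shifted
insertions (they would otherwise masquerade as 1–3 bp tandem
duplications) and rotates the inserted sequence into a consistent
description; the benchmark matcher judges insertion exactness by
reconstructing the local alternate sequence, not by comparing raw
coordinates.

Both clip orientations of an inversion junction, and both junctions of
an inversion, canonicalise to the same (min, max) coordinate pair, so
clustering pairs the reciprocal breakends implicitly; an evidence field
records whether one or both edges contributed reads.  A reciprocal
translocation's two junctions likewise share one canonical breakend
pair.

## Clustering and support

Per-read breakpoints of the same pattern within `tolerance` (default
5 bp) on both anchors merge; cluster coordinates are modal values with
ties broken toward the smaller coordinate, and support counts distinct
read identifiers, never alignments.  Evidence below `min_support`
(default 3 reads; at 15–20x roughly a fifth of the expected
junction-crossing reads) is dropped.  The inserted sequence of a
cluster is taken only from reads that agree with the modal coordinate
pair, so the reported (start, end, insert) triple is always one
self-consistent description of the junction.

## Copy-number ratio

Read starts are binned (default 500 bp so that a 1 kb deletion spans
at least two bins), normalized to genome-wide mean 1 per strain, and
divided: sample over control, with a pseudo-floor (0.05) on the
denominator and masking of bins whose control depth is below 0.25 —
unreliable denominators, not evidence.  The expected ratio is ~0 over
homozygous deletions, ~0.5 heterozygous, ~2 over homozygous tandem
duplications, ~3 over triplications.  Thresholded runs of at least
`min_bins` (default 2, suppressing single-bin noise) of ratio
<= 0.25 / in [1.5, 2.5) / >= 2.5 become DEL/DUP/MULT segments — the
thresholds sit at midpoints between integer copy states.  No HMM or
CBS segmentation: thresholding matches the simplicity of the indicator
and keeps every decision inspectable.

## Integration, frequency, zygosity

Deletion evidence reciprocally overlapping a DEL segment by >= 0.5
(the community convention for SV/CNV matching) is marked `split+cn`;
duplication evidence pairing with a MULT segment is promoted to a
multiplication.  Independently of segment matching, every precise call
gets `cn_ratio_mean` computed over its own interval (full bins
preferred), because thresholded runs can fragment on one noisy bin
while the interval mean remains informative.  Copy-number-only
segments of >= 2 kb with no split support are emitted as imprecise,
bin-resolution calls and excluded from size statistics.

Variant frequency is the fraction of breakpoint-informative reads
supporting the junction: junction reads divided by junction plus
reference-spanning reads, where spanning requires >= `min_clip_len`
aligned bases on both sides of the breakpoint.  Two refinements
matter.  First, both clip orientations of a deletion describe the same
physical junction, so the full cluster support is the junction count;
inversions and translocations have two physical junctions, and only
reads clipped at the interrogated breakpoint are comparable with the
spanning count there.  Second, junction frequency is uninformative for
tandem duplications — the variant haplotype itself carries
reference-spanning reads across the duplicated interval — so zygosity
for DUP/MULT comes from the copy-number ratio (hom >= 1.75 for DUP,
>= 2.75 for MULT) instead of the frequency bands.  For the remaining
types, frequency >= 0.8 is homozygous and [0.25, 0.8) heterozygous,
with a copy-number fallback for deletions whose junction coverage is
too thin to be informative (ratio <= 0.25 hom, <= 0.75 het).  All
cutoffs are exposed in `pipelineConfig()`.

## Background subtraction

Calls of identical type matching within tolerance across >= 2
independent strains are attributed to the shared ancestral genotype,
removed everywhere and reported once.  The operation is implemented on
the pooled call set, so it is idempotent and symmetric in strain
order.

# Machine-learning triage

Each candidate is summarised by eight features: genome-wide absolute
position (cumulative contig offsets in declared order), log10 deletion
and insertion lengths (+1), copy-number ratio, control-minus-sample
normalized depth difference, variant frequency, total split-read
support, and strand bias |fwd − rev| / (fwd + rev).  Missing values
are imputed with training-set medians and features are z-scored with
training statistics stored in the model — evaluation never touches
test-set statistics.  Seven classifiers are provided: logistic
regression, decision tree, k-nearest neighbours (k = 5), random forest
(100 trees), linear discriminant analysis, Gaussian naive Bayes and a
linear support vector machine (cost 1).  Hyperparameters are the
common defaults of the classic implementations; logistic regression is
fitted unpenalized — with z-scored features and hundreds of examples a
weak ridge penalty changes nothing measurable.  Training and
evaluation take explicit, disjoint inputs (train on confirmed calls,
test on new candidates) rather than an internal split.

The synthetic benchmark generator (`makeMlDataset()`) draws true
candidates as confirmed homozygous deletions look in practice — high
frequency (Beta(8,2)), ratio near zero (truncated N(0.05, 0.05)),
strong support (Pois(8)+3), balanced strands (Beta(2,2)) — and false
candidates as artifacts look — mirrored frequency, near-normal ratio
(N(0.9, 0.15)), weak skewed support.  Positions and lengths are
class-uninformative by construction.  These parameters are explicitly
fictional; under them the classes are almost perfectly separable (a
Bayes rule on the generating densities is essentially error-free), so
the held-out accuracies of the classical algorithms sit at or near
100%, comfortably above the 95% working bound.  Passing this benchmark
shows the harness (standardization, no leakage, determinism) is sound;
it says nothing about accuracy on real sequencing artifacts, which
depends on the confirmed training set one supplies.

# Mutation-count extrapolation

A forward-mutation rate measured on a reporter target scales to the
genome as rate × genome_size / target_size, with the genome at
100,272,607 bases and two canonical targets: the twitching-reporter
coding region (21,477 bases) and the total PCR-amplified screen region
(89,840 bases).  Rates are accepted in percent (the unit assay tables
print) with an explicit unit flag to remove the ×100 ambiguity.
Deletion size-class comparisons (< 50 vs >= 50 bp) use the two-sided
Fisher exact test.

# The simulator

The simulator is the package's stand-in for real mutagenized-strain
sequencing.  Genomes are i.i.d. with configurable A+T fraction
(default 0.645, nematode-like).  Variants are applied as haplotype
block chains — each haplotype contig is a chain of reference segments
(possibly reverse-complemented) and novel segments — which makes every
junction's reference coordinates exact by construction.  Homozygous
specs edit both haplotypes, heterozygous one.  Reads of 120 bases are
drawn uniformly from both haplotypes at the configured total depth
(default 20, the screen's working depth) with i.i.d. substitution
errors; reads crossing a junction are emitted as reference alignments
of their longest reference piece with exact soft clips (alignment
emulation — no external aligner, so truth stays exact and the stack
has no binary dependency); reads whose longest reference piece is
under 25 bases, or which lie inside novel sequence, are treated as
unmappable.  An optional file-based path (`cmdSimulate`/`cmdDetect`)
exercises the same pipeline through FASTA/SAM on disk.

The default engineered spectrum (30 DEL, 5 DUP, 2 MULT, 5 INS, 4
DELINS, 3 INV, 1 TRA = 50 variants) mirrors the deletion-dominated
spectrum such screens produce.  Deletion sizes are log-uniform on
60–5000 bp (median in the hundreds of bases, as observed);
duplications and inversions are sized to span multiple copy-number
bins; inserted sequences are 10–40 bases so a 120 bp read can bridge
the insert.  Heterozygosity is assigned with probability 0.3 to
copy-neutral and copy-loss variants; copy-gain variants are kept
homozygous in the default mix, both because the inbreeding design of
such screens yields homozygous harvests and because a heterozygous
triplication (ratio 2) is indistinguishable from a homozygous
duplication by ratio alone — a documented limitation of ratio-based
genotyping, not of the simulator.

What the simulator does not model: coverage bias (GC or mappability),
indel sequencing errors, homopolymer artifacts of semiconductor
sequencing, clipped-alignment jitter from a real aligner, and repeat
structure of real genomes.  Passing the simulated benchmarks therefore
demonstrates the correctness of the algorithmic chain — coordinates,
clustering, integration, genotyping, bookkeeping — not performance on
real libraries, where `min_support`, `min_clip_len` and the ratio
cutoffs would be tuned against confirmed calls.

# Benchmarks the package runs on itself

`benchmarkDetection()` simulates a 1 Mb two-contig genome (600 + 400
kb — large enough for 50 well-separated variants, small enough for
minutes-scale runtimes), all 50 default variants at depth 20 with
error-free reads, and scores recall, breakpoint exactness, zygosity
agreement and the call count on a variant-free strain.  The
copy-number study repeats a 60 kb genome with one homozygous and one
heterozygous 2.5 kb deletion 100 times at depth 20 and checks the
interval-mean ratios against the <0.1 and [0.35, 0.65] bands.  The
test suite runs both, plus exhaustive-oracle equivalences (brute-force
realignment scan, single-linkage clustering, interval overlap
counting, hypergeometric enumeration for the Fisher test) on toy
inputs.

# Numerical and degenerate-input conventions

All internal coordinates are 0-based half-open; emitted VCF positions
are 1-based with POS the base before the breakpoint (deleting
[1000, 1200) prints POS 1000, END 1200, SVLEN −200); annotation
intervals ride on `GRanges` (1-based closed) and are converted at the
overlap boundary.  Modal ties break toward the smaller coordinate.
All randomness flows through explicit seeds and the RNG state of the
caller is restored.  Degenerate cases are pinned by tests: all-zero
depth errors normalization; a constant-AT regressor defines R² = 0;
empty call sets produce header-only VCFs; translocations carry no
length and are conventionally counted in the large class; a
single-class training set is an error, not a warning.

# Known limitations

Breakpoints inside repeats are discarded with their ambiguous clips,
so recall in repetitive regions is limited by design.  Heterozygous
duplications without a clean copy-number segment genotype as
heterozygous only when the interval ratio is informative.  Insertions
longer than the read length cannot be fully assembled from single-end
120 bp reads and will surface as breakend-only evidence.  The
imprecise copy-number-only calls carry bin-resolution coordinates and
are deliberately excluded from size statistics.
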