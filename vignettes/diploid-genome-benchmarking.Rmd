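---
title: "Benchmarking sequences against a diploid truth genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking sequences against a diploid truth genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dibench)
```

# Scope and model

`dibench` evaluates three kinds of sequence data against a complete diploid
truth genome ("the benchmark"): test assemblies, aligned sequencing reads,
and phased variant call sets converted into genomes. The benchmark is two
haplotype sequence sets plus optional low-confidence regions; everything is
scored by direct sequence comparison in benchmark coordinates, which
sidesteps reference bias and the ambiguity of representing errors as
variants. This vignette explains the models, the tunable parameters, what
the simulators do and do not emulate, and the numerical choices that a user
of the results should know about.

# Haplotype markers and the phasing HMM

A *marker* is a canonical k-mer (lexicographic minimum of a k-mer and its
reverse complement; k odd so canonicalization is unambiguous) that occurs at
least once in one haplotype and zero times in the other. k defaults to 31 —
the conventional size at which human-scale genomes are close to k-mer
unique — and must lie in 15..31 (the 2-bit rolling encoder holds k ≤ 31 in
one 64-bit word). No within-haplotype copy-number filter is applied; the
occurrence count is kept so multi-copy markers can optionally be
down-weighted as 1/count (`weight_by_count`, off by default). This
permissive marker definition is deliberate: restricting markers to
single-copy k-mers is a stricter published alternative, and the choice is a
configuration, not a constant.

Scanning a contig yields an observation stream (position, source
haplotype). A two-state HMM is decoded by Viterbi: uniform initial
distribution, symmetric per-observation transition probability `p_switch`,
and emission probability `1 − p_error` when the marker source agrees with
the state. Defaults `p_switch = 1e-5`, `p_error = 0.02` make the break-even
run of discordant markers log((1−p)/p)-vs-log-odds arithmetic: one switch
costs ≈ 11.5 nats and each discordant marker explained as noise costs
≈ 3.9 nats, so ≈ 3–4 consecutive discordant markers flip a block and
isolated noisy markers are absorbed. Choices a user should know:

* transitions are **per observation**, not per base — marker spacing does
  not modulate switch probability (a distance-scaled transition is a
  straightforward extension but is not the default);
* Viterbi ties break toward the previous state, so switch counts are
  conservative and decoding is deterministic;
* block boundaries between distant markers are placed at the midpoint
  between the last marker footprint of one block and the first marker of
  the next — the true switch point is only localized to the inter-marker
  gap, and the midpoint is our documented convention;
* loci where markers are known to be unreliable (e.g. somatically
  rearranged immunoglobulin loci in cell lines) are handled by the generic
  BED exclusion mechanism, never hard-coded.

A practical consequence worth understanding: an isolated *phase-consistent*
base error (the other haplotype's allele at a het site) produces a short
cluster of up to k discordant markers, which the HMM reports as a
switch-and-return pair. That is the intended reading — the sequence locally
*is* the other haplotype — and it is why switch counts should be
interpreted together with block lengths.

# Assembly evaluation

Alignments of the assembly to the benchmark are consumed, not produced
(PAF with CIGARs or BAM/SAM; any aligner that emits base-level CIGARs
works). For NGAx, alignments are first broken at every single insertion or
deletion operation of length ≥ 10 kb (inclusive — exactly 10,000 splits);
blocks are then ordered by descending target span and the curve plots block
length against cumulative span divided by the total non-N diploid benchmark
length. The diploid denominator is the default even for single-haplotype
inputs (`reference_bp` overrides it).

Every mismatch and indel inside alignments becomes a discrepancy record in
benchmark coordinates. Substitutions at het SNV sites carrying the
alternate haplotype's allele are reclassified `phase_consistent` and
excluded from QV; het *indel* sites are recorded in the het catalog but not
reclassified (substitution-only phase consistency is the documented
default). QV is −10·log₁₀(#discrepancies / #aligned bases) with each indel
counted **once per event** regardless of length; a per-bp mode exists behind
a flag and the counting mode is stated in the summary output. Zero
discrepancies report the cap (default Q90) as a lower bound, never
infinity. Aligned bases are counted once per benchmark position (overlaps
deduplicated; conflicting records resolved in favor of the longer
alignment, ties by query name, for determinism). Benchmark N positions are
excluded from the denominator and can never host discrepancies.

Mononucleotide-run accuracy: a benchmark homopolymer is *aligned* when a
single alignment block spans it with at least one anchored base on each
side, and *erroneous* when the assembly bases between the anchors differ
from the run (wrong length or any substitution; an unaligned anchor is
conservatively erroneous). Runs touching an alignment end are excluded from
numerator and denominator.

Stratification recomputes every metric restricted to (∪ include) −
(∪ exclude). Point-anchored things — discrepancies, run observations (via
the run's start position) — are assigned to strata by position, so counts
over a partition of the genome sum exactly to the unstratified totals;
interval quantities (aligned bp, uncovered bp) are intersected. An empty
stratum reports "undefined", not zeros.

# Read evaluation

Primary, non-duplicate, non-QC-fail alignments only. The profiler
accumulates aligned and clipped bases, the 4×4-minus-diagonal substitution
matrix, indel events and bases, per-reported-quality tallies, per-base
coverage, and read starts, in one C++ pass per read. Reads from either
haplotype may map across homologous sequences, so by default a mismatch at
a het SNV where the read carries the other haplotype's allele is masked
(`het_mask = TRUE`); this is the read-level analogue of phase-consistent
classification. Conventions: indel events are attributed to the reported
quality of the read base immediately 5′ of the event; observed quality per
bin is −10·log₁₀((mismatches + indel events) / aligned), with zero-error
bins reported as bounds. Homopolymer observations require the run plus 5
flanking bases on each side to be spanned, demand the exact run length, and
fail on any substitution inside run or flanks.

Arrival dispersion bins read starts (default 1,000 bp bins; a warning fires
below 5 expected arrivals per bin and fewer than 100 bins is refused),
scales counts by the Poisson standard deviation √λ and centers at the
median, then reports D_below and D_above: the sup-norm distances between
the empirical and Poisson CDFs over count values below vs at-or-above the
median. These are diagnostics of over/under-dispersion on either tail, not
a hypothesis test. GC bias is summarized as mean coverage per integer %GC
over non-overlapping 100 bp windows; windows over 10% N are dropped and Ns
are excluded from the GC fraction.

# Variant constructed genomes

For each haplotype index of a phased genotype `a|b`, the selected allele
replaces the reference allele; unphased heterozygous records are *not*
applied — they are masked as `filtered` — while homozygous records apply
regardless of phasing (conservative handling of half-phased call sets;
masking rather than guessing is our documented choice). A coordinate map
tracks length changes. Masking at a GQ threshold (conventional set 10, 20,
30, 40) replaces with N: applied loci below threshold (`low_GQ`), unphased
hets (`filtered`), and — when a gVCF is supplied — reference blocks below
threshold plus positions absent from any block (`uncalled`). Masking is
unpadded by default (a pad flag exists); the mask covers the variant locus
span.

Scoring composes the applied-variant list with the truth-variant list over
the shared reference, which yields an exact constructed-vs-benchmark
alignment without running an aligner; masked intervals are projected into
benchmark coordinates and excluded via the generic stratification
mechanism. Reported per threshold: masked bp, aligned bp, covered fraction
of the diploid benchmark, and QV.

# What the simulators emulate — and what they do not

The fixtures module is first-class, tested code. `simulate_diploid_genome`
builds hap1 as uniform random sequence with seeded tandem runs (1–4 bp
units, configurable density and lengths) and derives hap2 by planting het
SNVs (default 1e-3/bp) and indels (1e-4/bp, lengths 1–10), plus optional
multi-kb SVs; truth tables, a phased truth VCF (hap1 as reference, GT 0|1),
and exact truth alignments are emitted from the construction, so no aligner
noise enters unit tests. Planted events keep a minimum spacing (default 2k)
so each event is an independent observable; consequently realized variant
counts run ~6% below rate × length (sampled positions within the guard of a
predecessor are thinned), which the bookkeeping tests account for.
`corrupt_assembly` plants substitutions, indels, large indels, phase
switches (splicing the homologous sequence at a mapped position), dropouts,
SNV-level collapses, and length-dependent homopolymer noise — each logged
in benchmark coordinates using the same classification the evaluator
reports, which is what makes exact-recovery tests possible. Per-haplotype
counts are split across that haplotype's chromosomes. `simulate_reads`
draws lognormal read lengths, uniform starts (optionally thinned by a
logistic GC-dropout curve evaluated on the read's own span), injects
substitution errors either at a fixed rate or from per-base qualities
(truthful model: P(error) = 10^(−q/10) exactly, enabling calibration
identities; a miscalibrated variant inflates reported q above a threshold),
indels at per-bp rates, and ±1 homopolymer length noise growing with run
length; reads are emitted as a sorted, indexed BAM whose records carry
truth CIGARs.

Not emulated: instrument-specific error signatures beyond rate parameters,
satellite/segmental-duplication evolution, chimeric reads, mapping
ambiguity (truth alignments are exact), and base-composition realism. A
green test therefore establishes that the *measurement machinery* is exact
on known inputs — not that any particular instrument behaves as simulated.

# Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; BED is 0-based half-open on
  disk; VCF is 1-based at the boundary.
* Phred caps: Q90 for assembly QV and run tables (beyond any desk-scale
  measurement), Q60 default for calibration bins; capped values carry a
  `capped` attribute and are bounds, not measurements.
* Viterbi runs in log space; enumeration-oracle agreement is asserted to
  1e-12 on ≤ 12 observations.
* Tandem runs are maximal non-extendable stretches with period u and a
  primitive unit; a partial trailing copy counts toward run length
  ("ACACA" is a 5 bp AC run). Runs never span N; a run of a degenerate unit
  is reported only at its smallest period.
* Empty inputs: contigs shorter than k scan to empty observation lists and
  are reported unphased; an empty stratum is undefined; zero aligned bases
  make QV undefined rather than infinite.
* Determinism: generators use one derived RNG substream per stage (naming,
  not order, determines the stream), Viterbi ties are fixed, overlap
  resolution is ordered, and serialized indexes are byte-stable.

# Known limitations

Whole-genome alignment is out of scope (alignments are inputs); trio-based
hap-mer phasing, k-mer-database QV (Merqury-style), structural-variant
calling, liftover of errors to a third reference, and browser-track output
are non-goals. The HMM does not scale switch probability with marker
distance, and block boundaries are only localized to inter-marker gaps.
Phase-consistency classification is SNV-only. The read simulator's
per-read construction is R-level and costs roughly 10 ms per 10 kb read —
fine for fixture scales, not for real datasets (the *profiler* is C++ and
handles real-scale BAMs).
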