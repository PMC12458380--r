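# dibench

Benchmarking genome assemblies, sequencing reads, and phased variant call
sets against a **complete diploid truth genome**.

## The problem

When a finished, haplotype-resolved genome of an individual exists, any
sequence derived from that same individual — a *de novo* assembly, a set of
sequencing reads, or a genome reconstructed from a phased VCF — can be
scored by direct comparison against the truth, with no reference bias and no
detour through variant representation. `dibench` implements that comparison
for a diploid truth genome supplied as two haplotype FASTA files:

* **Assemblies** — NGAx contiguity from alignments broken at indels ≥ 10 kb;
  a phase-aware discrepancy catalog (12 substitution types with Ti/Tv,
  insertions, deletions) in truth coordinates; an alignment-based quality
  value QV = −10·log₁₀(#discrepancies / #aligned bases); mononucleotide-run
  accuracy −10·log₁₀(#erroneous runs / #aligned runs) by run length;
  uncovered-base accounting; region-stratified reporting.
  A substitution at a heterozygous site that matches the *other* haplotype's
  allele is not an error: it is classified `phase_consistent` and excluded
  from QV, feeding the phase-switch analysis instead.
* **Phasing** — haplotype-specific canonical k-mers (default k = 31) are
  extracted from the two haplotypes; a two-state hidden Markov model over
  the marker stream segments each contig into haplotype blocks (Viterbi,
  symmetric per-observation switch probability, tie-break toward no switch)
  and yields switch counts and switches/Mb.
* **Reads** — aligned/clipped base totals, the twelve single-base error
  rates per Mb, indel event/bp rates, observed-vs-reported base-quality
  calibration, homopolymer accuracy by run length (correct length and no
  substitution within the run or its 5 flanking bases), read-start
  (arrival) dispersion against the Poisson ideal with D statistics below
  and above the median, and mean coverage per %GC in 100 bp windows.
* **Variant call sets** — "variant constructed genomes": phased calls are
  applied to a reference per haplotype, bases below GQ thresholds
  (10/20/30/40 by convention) or outside gVCF callable blocks are masked to
  N, and the constructed haplotypes are scored like assemblies, giving
  covered fraction and QV per threshold.
* **Fixtures** — a first-class simulation module generates diploid genomes
  with controlled heterozygosity and repeat content, corrupted assemblies
  with planted error catalogs, and reads with parameterized error/quality/
  coverage models — every test runs from synthetic data with exact truth.

## Worked example

```r
library(dibench)

fix <- simulate_diploid_genome(genome_spec(n_chroms = 1,
                                           chrom_len_bp = 500000, seed = 42))
fix$bench
#> DiploidBenchmark: 1 + 1 sequences, 1,000,004 non-N diploid bp,
#>   1 homologous pairs, 0 low-confidence intervals

hets    <- build_het_catalog(fix$bench, fix$alignments)
markers <- extract_markers(fix$bench, k = 21)
#> MarkerSet: k = 21 ; 11011 hap1 markers, 11015 hap2 markers
runs    <- annotate_runs(fix$bench)

asm <- corrupt_assembly(fix, error_spec(n_sub = 40, n_ins = 10, n_del = 10,
                                        n_phase_sub = 5, seed = 7))
ev <- evaluate_assembly(fix$bench, asm$alignments, asm$contigs,
                        hets = hets, runs = runs, markers = markers)
ev
#> AssemblyEval: 2 alignments; aligned_bp = 1,000,004
#>   QV:  39.21 ( 120 discrepancies )
#>   NGA50: 500,004 ; uncovered non-N bp: 0
#>   phase switches: 20
table(ev$catalog$klass)
#>         deletion        insertion phase_consistent     substitution
#>               20               20               10               80
```

Reading the numbers: 40 substitutions + 10 insertions + 10 deletions were
planted on *each* haplotype, so the catalog holds 80/20/20 records plus the
10 planted phase-consistent alleles. QV counts only the 120 true
discrepancies: −10·log₁₀(120 / 1,000,004) = 39.21. Each phase-consistent
site is locally a patch of the other haplotype, so the HMM reports a
switch-and-return pair there (2 × 10 = 20 switches). The identity case
(`error_spec()` with no errors) yields an empty catalog, 0 uncovered bases,
0 switches, and QV reported as the bound "≥ Q90".

## Command line

```sh
bench index --hap1 hap1.fa --hap2 hap2.fa --aln hap2_vs_hap1.paf --k 31 --out idx/
bench phase --index idx/ --assembly asm.fa --out phased/
bench eval-assembly --index idx/ --aln asm.paf --assembly asm.fa --out eval/
bench eval-reads --index idx/ --bam reads.bam --bin 1000 --window 100 --out reads/
bench build-vcg --ref ref.fa --vcf calls.vcf --gq 10,20,30,40 --out vcg/
bench simulate genome|assembly|reads --spec cfg --seed 1 --out sim/
bench report eval1/summary.json eval2/summary.json
```

`bench` is `inst/scripts/bench`; equivalently call
`dibench::bench_main(c("eval-assembly", ...))` from R. Alignments are
consumed, not produced: PAF (with `cg:Z:` tags, e.g. `minimap2 -c --eqx`) or
BAM/SAM.

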