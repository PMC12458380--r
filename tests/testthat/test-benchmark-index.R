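# benchmark_index: loading, het catalog, markers, run annotation

test_that("load_benchmark counts non-N diploid bases and validates inputs", {
  set.seed(1)
  s1 <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
              collapse = "")
  s2 <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
              collapse = "")
  b <- load_benchmark(c(chrA_hap1 = s1), c(chrA_hap2 = s2))
  expect_equal(b$total_diploid_bp, 2000)
  expect_equal(b$pairing$hap2[b$pairing$hap1 == "chrA_hap1"], "chrA_hap2")

  s1n <- paste0(substr(s1, 1, 490), strrep("N", 10), substr(s1, 501, 1000))
  bn <- load_benchmark(c(chrA_hap1 = s1n), c(chrA_hap2 = s2))
  expect_equal(bn$total_diploid_bp, 1990)

  expect_error(load_benchmark(c(chrA = s1), c(chrA = s2)), "duplicate")
  expect_error(
    load_benchmark(c(chrA_hap1 = s1), c(chrA_hap2 = s2),
                   lowconf_bed = data.frame(seq = "nope", start = 0, end = 10)),
    "unknown sequence")
  expect_error(
    load_benchmark(c(chrA_hap1 = s1), c(chrA_hap2 = s2),
                   lowconf_bed = data.frame(seq = "chrA_hap1", start = 0,
                                            end = 5000)),
    "bounds")
})

test_that("fixture benchmark matches the generator's own non-N tally", {
  fx <- fx_small()
  expect_equal(fx$bench$total_diploid_bp, fx$non_n_bp)
})

test_that("het catalog is empty for identical haplotypes and mirrors a toy SNV", {
  fx0 <- simulate_diploid_genome(genome_spec(n_chroms = 1L,
                                             chrom_len_bp = 20000L,
                                             het_snv_rate = 0,
                                             het_indel_rate = 0, seed = 5L))
  expect_identical(unname(fx0$bench$hap1[[1]]), unname(fx0$bench$hap2[[1]]))
  hets0 <- build_het_catalog(fx0$bench, fx0$alignments)
  expect_equal(nrow(hets0), 0)

  # single A<->G difference at position 500
  set.seed(7)
  base <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                collapse = "")
  substr(base, 501, 501) <- "A"
  other <- base
  substr(other, 501, 501) <- "G"
  b <- load_benchmark(c(c_hap1 = base), c(c_hap2 = other))
  aln <- data.frame(query = "c_hap2", query_len = 10000L, q_start = 0L,
                    q_end = 10000L, strand = "+", target_seq = "c_hap1",
                    t_start = 0L, t_end = 10000L, cigar = "10000M",
                    is_primary = TRUE, target_hap = "hap1")
  h <- build_het_catalog(b, aln)
  expect_equal(nrow(h), 2)
  expect_setequal(h$hap, c("hap1", "hap2"))
  expect_equal(h$pos, c(500L, 500L))
  expect_equal(h$allele_self[h$hap == "hap1"], "A")
  expect_equal(h$allele_other[h$hap == "hap1"], "G")
  expect_equal(h$allele_self[h$hap == "hap2"], "G")
  expect_equal(h$allele_other[h$hap == "hap2"], "A")
})

test_that("het catalog recovers every planted variant, mirrored", {
  fx <- fx_small()
  hets <- hets_small()
  tv <- fx$truth_variants
  expect_equal(nrow(hets), 2 * nrow(tv))
  h1 <- hets[hets$hap == "hap1", ]
  expect_setequal(h1$pos[h1$type == "snv"], tv$hap1_pos0[tv$type == "snv"])
  # mirror symmetry: every hap1 record has a partner with swapped alleles
  h2 <- hets[hets$hap == "hap2", ]
  m <- match(paste(h1$allele_self, h1$allele_other, h1$pos %in% tv$hap1_pos0),
             paste(h2$allele_other, h2$allele_self, TRUE))
  expect_false(any(is.na(m)))
  # hap2 SNV coordinates agree with the generator's derived coordinates
  expect_setequal(h2$pos[h2$type == "snv"], tv$hap2_pos0[tv$type == "snv"])
})

test_that("markers: empty for identical haplotypes, brute-force on a toy SNV pair", {
  set.seed(11)
  base <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                collapse = "")
  b0 <- load_benchmark(c(t_hap1 = base), c(t_hap2 = base))
  mk0 <- extract_markers(b0, k = 21)
  expect_length(mk0$hap1_markers, 0)
  expect_length(mk0$hap2_markers, 0)

  other <- base
  substr(other, 5001, 5001) <- setdiff(c("A", "C", "G", "T"),
                                       substr(base, 5001, 5001))[1]
  b1 <- load_benchmark(c(t_hap1 = base), c(t_hap2 = other))
  mk <- extract_markers(b1, k = 21)
  expect_lte(length(mk$hap1_markers), 21)
  expect_lte(length(mk$hap2_markers), 21)
  # brute-force canonical k-mer set difference
  s1 <- kmer_set_oracle(base, 21)
  s2 <- kmer_set_oracle(other, 21)
  expect_setequal(mk$hap1_markers, setdiff(s1, s2))
  expect_setequal(mk$hap2_markers, setdiff(s2, s1))
})

test_that("marker sets are disjoint and k is validated", {
  mk <- markers_small()
  expect_length(intersect(mk$hap1_markers, mk$hap2_markers), 0)
  expect_gt(length(mk$hap1_markers), 0)
  expect_error(extract_markers(fx_small()$bench, k = 22), "odd")
  expect_error(extract_markers(fx_small()$bench, k = 13), "between")
})

test_that("k-mers spanning N are excluded from markers", {
  set.seed(13)
  base <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                collapse = "")
  withn <- paste0(substr(base, 1, 1000), "N", substr(base, 1002, 2000))
  b <- load_benchmark(c(n_hap1 = withn), c(n_hap2 = base))
  mk <- extract_markers(b, k = 15)
  expect_false(any(grepl("N", c(mk$hap1_markers, mk$hap2_markers))))
  # hap2 has markers where hap1 has the N; hap1 must not gain N k-mers
  expect_gt(length(mk$hap2_markers), 0)
})

test_that("annotate_runs finds canonical toy cases with correct precedence", {
  seq <- paste0("GCTGC", "AAAAA", "GTCGT", "ACACACAC", "GTTGC")
  r <- annotate_runs(c(x = seq))
  mono <- r[r$unit_len == 1 & r$unit == "A", ]
  expect_equal(nrow(mono), 1)
  expect_equal(mono$run_len_bp, 5)
  expect_equal(c(mono$start, mono$end), c(5, 10))
  di <- r[r$unit_len == 2, ]
  expect_equal(nrow(di), 1)
  expect_equal(di$unit, "AC")
  expect_equal(di$run_len_bp, 8)
  # a homopolymer is never reported as a dinucleotide run
  r2 <- annotate_runs(c(x = "GCTAAAAAAGCT"))
  expect_false(any(r2$unit_len == 2))
})

test_that("run catalog equals the independent oracle on a random fixture", {
  seq <- substr(fx_small()$bench$hap1[[1]], 1, 50000)
  got <- annotate_runs(c(x = seq))
  want <- runs_oracle(seq)
  got <- got[order(got$start, got$unit_len), ]
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
  expect_equal(got$unit, want$unit)
  expect_equal(got$run_len_bp, got$end - got$start)
})

test_that("benchmark index round-trips through serialization deterministically", {
  fx <- fx_small()
  d1 <- tempfile(); d2 <- tempfile()
  mk <- markers_small()
  write_benchmark_index(d1, fx$bench, mk, hets_small(), runs_small())
  write_benchmark_index(d2, fx$bench, mk, hets_small(), runs_small())
  for (f in c("markers.tsv", "hets.tsv", "runs.bed")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  idx <- read_benchmark_index(d1)
  expect_equal(idx$bench$total_diploid_bp, fx$bench$total_diploid_bp)
  expect_equal(idx$markers$k, mk$k)
  expect_setequal(idx$markers$hap1_markers, mk$hap1_markers)
  expect_equal(nrow(idx$hets), nrow(hets_small()))
  expect_equal(nrow(idx$runs), nrow(runs_small()))
  unlink(c(d1, d2), recursive = TRUE)
})
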