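# assembly_eval: alignment ingestion, NGAx, discrepancies, QV, runs, strata

test_that("PAF parsing validates CIGARs and honors flags", {
  paf <- tempfile(fileext = ".paf")
  fx <- fx_small()
  writeLines(c(
    paste("ctg", 1000, 0, 1000, "+", "chr1_hap1", 200000, 100, 1100, 1000,
          1000, 60, "tp:A:P", "cg:Z:1000=", sep = "\t"),
    paste("ctg2", 500, 0, 500, "+", "chr1_hap1", 200000, 5000, 5500, 500,
          500, 60, "tp:A:S", "cg:Z:500=", sep = "\t")), paf)
  segs <- read_alignments(paf, fx$bench)
  expect_equal(nrow(segs), 1)   # secondary dropped by default
  expect_equal(segs$cigar, "1000=")
  expect_equal(segs$target_hap, "hap1")
  segs_all <- read_alignments(paf, fx$bench, primary_only = FALSE)
  expect_equal(nrow(segs_all), 2)
  expect_equal(nrow(read_alignments(paf, fx$bench, min_len = 600)), 1)

  bad <- tempfile(fileext = ".paf")
  writeLines(paste("ctg", 1000, 0, 1000, "+", "chr1_hap1", 200000, 100, 1100,
                   1000, 1000, 60, sep = "\t"), bad)
  expect_error(read_alignments(bad, fx$bench), "cg:Z")
  unknown <- tempfile(fileext = ".paf")
  writeLines(paste("ctg", 1000, 0, 1000, "+", "chrZ", 200000, 100, 1100,
                   1000, 1000, 60, "cg:Z:1000=", sep = "\t"), unknown)
  expect_error(read_alignments(unknown, fx$bench), "not in benchmark")
})

test_that("split_for_ngax applies the inclusive >= 10 kb threshold", {
  seg <- function(del_len) data.frame(
    query = "q", query_len = 1000000L + 0L, q_start = 0L,
    q_end = 1000000L - del_len, strand = "+", target_seq = "t",
    t_start = 0L, t_end = 1000000L,
    cigar = sprintf("500000=%dD%d=", del_len, 500000L - del_len),
    is_primary = TRUE, target_hap = "hap1", stringsAsFactors = FALSE)
  expect_equal(nrow(split_for_ngax(seg(10000L))), 2)
  expect_equal(nrow(split_for_ngax(seg(9999L))), 1)
  # planted 15 kb insertion + 12 kb deletion -> 3 blocks of known spans
  cigar <- "100000=15000I200000=12000D300000="
  s <- data.frame(query = "q", query_len = 615000L, q_start = 0L,
                  q_end = 615000L, strand = "+", target_seq = "t",
                  t_start = 0L, t_end = 612000L, cigar = cigar,
                  is_primary = TRUE, target_hap = "hap1",
                  stringsAsFactors = FALSE)
  blk <- split_for_ngax(s)
  expect_equal(nrow(blk), 3)
  expect_equal(blk$t_end - blk$t_start, c(100000L, 200000L, 300000L))
  expect_equal(blk$q_end - blk$q_start, c(100000L, 200000L, 300000L))
  expect_equal(blk$t_start, c(0L, 100000L, 312000L))
})

test_that("ngax implements the size-ordered cumulative curve", {
  blocks <- data.frame(t_start = c(0, 0, 0) * 1e6,
                       t_end = c(6, 3, 1) * 1e6)
  curve <- ngax(blocks, reference_bp = 10e6)
  expect_equal(curve$block_length, c(6e6, 3e6, 1e6))
  expect_equal(curve$cum_fraction, c(0.6, 0.9, 1.0))
  expect_equal(nga(curve, 50), 6e6)
  expect_equal(nga(curve, 90), 3e6)
  expect_true(is.na(nga(ngax(blocks, reference_bp = 20e6), 90)))
  expect_false(is.unsorted(rev(curve$block_length)))
})

test_that("identity evaluation is exactly clean", {
  fx <- fx_small()
  asm <- corrupt_assembly(fx, error_spec())
  ev <- evaluate_assembly(fx$bench, asm$alignments, asm$contigs,
                          hets = hets_small(), runs = runs_small())
  expect_equal(nrow(ev$catalog), 0)
  expect_equal(ev$uncovered$total, 0)
  expect_equal(ev$aligned_bp, fx$bench$total_diploid_bp)
  expect_true(attr(ev$qv, "capped"))
  expect_equal(sum(ev$run_quality$detail$erroneous), 0)
  # NGAx equals the NG curve of chromosome lengths
  lens <- sort(c(nchar(fx$bench$hap1), nchar(fx$bench$hap2)),
               decreasing = TRUE)
  expect_equal(ev$ngax$block_length, unname(as.numeric(lens)))
})

test_that("planted discrepancies are recovered exactly with classes and Ti/Tv", {
  fx <- fx_small()
  asm <- corrupt_assembly(fx, error_spec(n_sub = 20L, n_ins = 10L,
                                         n_del = 10L, n_phase_sub = 6L,
                                         seed = 9L))
  ev <- evaluate_assembly(fx$bench, asm$alignments, asm$contigs,
                          hets = hets_small())
  cols <- c("target_hap", "target_seq", "t_pos", "klass", "sub_type",
            "ti_tv", "length")
  expect_equal(ev$catalog[cols], asm$truth_catalog[cols])
  # Ti/Tv against a lookup-table oracle over all 12 ordered substitutions
  ti_lookup <- c("A>G" = "Ti", "G>A" = "Ti", "C>T" = "Ti", "T>C" = "Ti",
                 "A>C" = "Tv", "A>T" = "Tv", "C>A" = "Tv", "C>G" = "Tv",
                 "G>C" = "Tv", "G>T" = "Tv", "T>A" = "Tv", "T>G" = "Tv")
  subs <- ev$catalog[ev$catalog$klass == "substitution", ]
  expect_equal(subs$ti_tv, unname(ti_lookup[subs$sub_type]))
  # phase-consistent records sit at het sites and carry the other allele
  pc <- ev$catalog[ev$catalog$klass == "phase_consistent", ]
  h <- hets_small()
  expect_true(all(paste(pc$target_seq, pc$t_pos) %in% paste(h$seq, h$pos)))
})

test_that("qv follows the closed form, caps at zero errors, excludes phase hits", {
  cat1 <- data.frame(klass = "substitution", length = 1L)
  expect_equal(as.numeric(qv(cat1, aligned_bp = 1e6)), 60)
  cat0 <- cat1[0, ]
  q0 <- qv(cat0, aligned_bp = 1e4)
  expect_equal(as.numeric(q0), 90)
  expect_true(attr(q0, "capped"))
  catp <- data.frame(klass = c("substitution", "phase_consistent"),
                     length = c(1L, 1L))
  expect_equal(attr(qv(catp, aligned_bp = 1e6), "n_discrepancies"), 1)
  # per-event vs per-bp indel counting
  cati <- data.frame(klass = c("insertion", "deletion"), length = c(5L, 3L))
  expect_equal(attr(qv(cati, aligned_bp = 1e6), "n_discrepancies"), 2)
  expect_equal(attr(qv(cati, aligned_bp = 1e6, per_bp = TRUE),
                    "n_discrepancies"), 8)
})

test_that("mononucleotide run quality: formula, spanning rule, planted noise", {
  # 200 aligned 10 bp runs with 2 erroneous -> Q20
  detail <- data.frame(seq = "s", start = seq_len(200) * 100,
                       end = seq_len(200) * 100 + 10, run_len_bp = 10L,
                       aligned = TRUE, erroneous = rep(c(TRUE, FALSE),
                                                       c(2, 198)))
  tab <- dibench:::run_quality_table(detail)
  expect_equal(tab$q, 20)
  # run overlapping an alignment end is excluded from both counts
  fx <- fx_small()
  runs <- runs_small()
  mono <- runs[runs$unit_len == 1 & runs$seq == "chr1_hap1", ]
  r1 <- mono[10, ]
  seg <- data.frame(query = "chr1_hap1_ctg", query_len = r1$end,
                    q_start = 0L, q_end = r1$end, strand = "+",
                    target_seq = "chr1_hap1", t_start = 0L, t_end = r1$end,
                    cigar = paste0(r1$end, "="), is_primary = TRUE,
                    target_hap = "hap1", stringsAsFactors = FALSE)
  res <- mononuc_run_quality(seg, fx$bench, runs,
                             c(chr1_hap1_ctg = substr(fx$bench$hap1[[1]], 1,
                                                      r1$end)))
  det <- res$detail
  expect_false(det$aligned[det$seq == "chr1_hap1" & det$start == r1$start])
  expect_true(all(det$aligned[det$seq == "chr1_hap1" & det$end < r1$end]))

  # homopolymer noise planted only in runs >= 15 bp
  asm <- corrupt_assembly(fx, error_spec(hp_noise = list(min_len = 15L,
                                                         p = 0.8), seed = 4L))
  ev <- evaluate_assembly(fx$bench, asm$alignments, asm$contigs,
                          runs = runs)
  tab <- ev$run_quality$table
  expect_true(all(tab$capped[tab$run_len < 15]))
  expect_true(any(!tab$capped[tab$run_len >= 15]))
})

test_that("uncovered bases equal planted dropouts exactly", {
  fx <- fx_small()
  drops <- list(list(seq = "chr1_hap1", start = 50000L, end = 70000L),
                list(seq = "chr1_hap2", start = 120000L, end = 125000L))
  asm <- corrupt_assembly(fx, error_spec(dropout_regions = drops, seed = 2L))
  ev <- evaluate_assembly(fx$bench, asm$alignments, asm$contigs)
  expect_equal(ev$uncovered$total, 25000)
  expect_equal(ev$uncovered$bed[order(ev$uncovered$bed$seq), ],
               data.frame(seq = c("chr1_hap1", "chr1_hap2"),
                          start = c(50000L, 120000L),
                          end = c(70000L, 125000L)),
               ignore_attr = TRUE)
})

test_that("stratification restricts and sums exactly over a partition", {
  fx <- fx_small()
  asm <- corrupt_assembly(fx, error_spec(n_sub = 30L, n_ins = 10L,
                                         n_del = 10L, seed = 21L))
  ev <- evaluate_assembly(fx$bench, asm$alignments, asm$contigs,
                          hets = hets_small(), runs = runs_small())
  whole <- stratify(ev, fx$bench)
  expect_equal(unname(whole$counts["substitution"]), 60L)
  expect_equal(whole$aligned_bp, ev$aligned_bp)
  expect_equal(as.numeric(whole$qv), as.numeric(ev$qv))

  half <- 100000L
  left <- data.frame(seq = c("chr1_hap1", "chr1_hap2"), start = 0L,
                     end = half)
  right <- data.frame(seq = c("chr1_hap1", "chr1_hap2"), start = half,
                      end = c(nchar(fx$bench$hap1[[1]]),
                              nchar(fx$bench$hap2[[1]])))
  sl <- stratify(ev, fx$bench, include = left)
  sr <- stratify(ev, fx$bench, include = right)
  expect_equal(sl$counts + sr$counts, whole$counts)
  expect_equal(sl$aligned_bp + sr$aligned_bp, whole$aligned_bp)
  expect_equal(sl$uncovered + sr$uncovered, whole$uncovered)
  # pooled rates recombine to the unstratified rate
  pooled <- (sl$counts + sr$counts) /
    ((sl$aligned_bp + sr$aligned_bp) / 1e6)
  expect_equal(pooled, whole$rates_per_mb)
  # run-table denominators split by run start position
  expect_equal(sum(sl$run_quality$aligned) + sum(sr$run_quality$aligned),
               sum(whole$run_quality$aligned))

  # exclusion semantics: excluding a region removes its discrepancies
  excl_iv <- data.frame(seq = ev$catalog$target_seq[1],
                        start = ev$catalog$t_pos[1],
                        end = ev$catalog$t_pos[1] + 1L)
  se <- stratify(ev, fx$bench, exclude = excl_iv)
  expect_equal(sum(se$counts[c("substitution", "insertion", "deletion")]),
               sum(whole$counts[c("substitution", "insertion", "deletion")]) - 1L)
  expect_equal(se$aligned_bp, whole$aligned_bp - 1)
  # empty stratum is undefined, not zero
  expect_true(stratify(ev, fx$bench,
                       include = data.frame(seq = "chr1_hap1", start = 0L,
                                            end = 0L))$undefined)
})

test_that("BAM alignments are read equivalently to PAF", {
  fx <- fx_small()
  ctg <- substr(fx$bench$hap1[[1]], 1001, 3000)
  sam <- tempfile(fileext = ".sam")
  write_mini_sam(sam, c(chr1_hap1 = fx$bench$hap1[[1]]),
                 list(list(qname = "c1", rname = "chr1_hap1", pos = 1001L,
                           cigar = "2000M", seq = ctg)))
  segs <- read_alignments(sam, fx$bench)
  expect_equal(segs$t_start, 1000L)
  expect_equal(segs$t_end, 3000L)
  res <- catalog_discrepancies(segs, fx$bench, hets_small(),
                               c(c1 = ctg))
  expect_equal(nrow(res$catalog), 0)
})
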