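# read_eval: error spectra, calibration, runs, dispersion, GC coverage

test_that("CIGAR semantics on handmade reads", {
  set.seed(31)
  ref <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
               collapse = "")
  bench <- load_benchmark(c(r_hap1 = ref),
                          c(r_hap2 = chartr("AC", "CA", ref)))
  # perfect 1000 bp read
  sam <- write_mini_sam(tempfile(fileext = ".sam"), c(r_hap1 = ref), list(
    list(qname = "perfect", rname = "r_hap1", pos = 1L, cigar = "1000M",
         seq = substr(ref, 1, 1000), qual = strrep("I", 1000))))
  p <- profile_reads(sam, bench, het_mask = FALSE)
  expect_equal(p$aligned_bp, 1000)
  expect_equal(sum(p$sub_counts) + p$ins_events + p$del_events, 0)

  # 500M2I498M with 3 mismatches
  left <- substr(ref, 1, 500); right <- substr(ref, 501, 998)
  rd <- paste0(left, "GG", right)
  for (at in c(10, 250, 700)) {
    b <- substr(rd, at, at)
    substr(rd, at, at) <- setdiff(c("A", "C", "G", "T"), b)[1]
  }
  sam2 <- write_mini_sam(tempfile(fileext = ".sam"), c(r_hap1 = ref), list(
    list(qname = "indelread", rname = "r_hap1", pos = 1L,
         cigar = "500M2I498M", seq = rd, qual = strrep("I", 1000))))
  p2 <- profile_reads(sam2, bench, het_mask = FALSE)
  expect_equal(p2$ins_events, 1)
  expect_equal(p2$ins_bp, 2)
  expect_equal(sum(p2$sub_counts), 3)
  expect_equal(p2$aligned_bp, 998)

  # soft clips accumulate into clipped_bp
  sam3 <- write_mini_sam(tempfile(fileext = ".sam"), c(r_hap1 = ref), list(
    list(qname = "clipped", rname = "r_hap1", pos = 101L, cigar = "50S900M",
         seq = paste0(strrep("A", 50), substr(ref, 101, 1000)),
         qual = strrep("I", 950))))
  p3 <- profile_reads(sam3, bench, het_mask = FALSE)
  expect_equal(p3$clipped_bp, 50)
  expect_equal(p3$aligned_bp, 900)
  expect_equal(p3$total_read_bp, 950)
})

test_that("simulated reads recover programmed error rates within 3 sigma", {
  fx <- fx_small()
  rr <- cached("rr_fixed", simulate_reads(
    fx, read_spec(depth = 10, read_len_mean = 5000, sub_rate = 1e-3,
                  ins_rate = 5e-4, del_rate = 5e-4, q_model = "fixed",
                  seed = 2L), out_prefix = tempfile()))
  prof <- cached("prof_fixed", profile_reads(rr$bam, fx$bench,
                                             runs = runs_small(),
                                             hets = hets_small()))
  # exact agreement with per-read truth counters
  expect_equal(sum(prof$sub_counts), sum(rr$truth$n_sub))
  expect_equal(prof$ins_events, sum(rr$truth$n_ins))
  expect_equal(prof$del_events, sum(rr$truth$n_del))
  # rates within 3 sigma binomial of the programmed profile
  for (chk in list(c(sum(prof$sub_counts), 1e-3),
                   c(prof$ins_events, 5e-4),
                   c(prof$del_events, 5e-4))) {
    n <- prof$aligned_bp
    expect_lt(abs(chk[1] - n * chk[2]), 3 * sqrt(n * chk[2]) + 1)
  }
  # counter conservation: aligned + clipped + inserted = total read bases
  expect_equal(prof$aligned_bp + prof$clipped_bp + prof$ins_bp,
               prof$total_read_bp)
})

test_that("substitution spectrum arithmetic and Ti/Tv combinatorics", {
  prof <- structure(list(
    sub_counts = matrix(1, 4, 4, dimnames = list(ref = c("A", "C", "G", "T"),
                                                 called = c("A", "C", "G", "T"))),
    aligned_bp = 1e6), class = "ReadProfile")
  diag(prof$sub_counts) <- 0
  sp <- substitution_spectrum(prof)
  expect_equal(nrow(sp$table), 12)
  expect_equal(sp$titv_ratio, 0.5)   # 4 transition cells / 8 transversion
  prof$sub_counts[] <- 0
  prof$sub_counts["A", "G"] <- 10
  sp2 <- substitution_spectrum(prof)
  expect_equal(sp2$tv_per_mb, 0)
  expect_equal(sp2$ti_per_mb, 10)
})

test_that("quality calibration: formula, bounds, truthful model within 1 Q unit", {
  per_q <- matrix(0, 94, 4,
                  dimnames = list(NULL, c("aligned", "mismatch",
                                          "ins_events", "del_events")))
  per_q[41, ] <- c(1e6, 100, 0, 0)   # reported Q40 row
  per_q[21, ] <- c(1e4, 0, 0, 0)     # zero errors -> bound
  prof <- structure(list(per_q = per_q, has_qual = TRUE),
                    class = "ReadProfile")
  cal <- quality_calibration(prof, cap = 40)
  expect_equal(cal$observed_q[cal$reported_q == 40], 40)
  expect_true(cal$capped[cal$reported_q == 20])

  fx <- fx_small()
  rr <- cached("rr_truthful", simulate_reads(
    fx, read_spec(depth = 8, read_len_mean = 5000, ins_rate = 0,
                  del_rate = 0, q_model = "truthful", seed = 6L),
    out_prefix = tempfile()))
  prof_t <- cached("prof_truthful",
                   profile_reads(rr$bam, fx$bench, hets = hets_small()))
  cal_t <- quality_calibration(prof_t)
  cal_t <- cal_t[cal_t$errors >= 10, ]
  expect_gt(nrow(cal_t), 2)
  expect_true(all(abs(cal_t$observed_q - cal_t$reported_q) < 1))
})

test_that("+5 Q miscalibration above Q30 is detected only above Q30", {
  fx <- fx_small()
  rr <- simulate_reads(
    fx, read_spec(depth = 8, read_len_mean = 5000, ins_rate = 0,
                  del_rate = 0, q_model = "miscalibrated",
                  miscal_offset = 5L, miscal_above = 30L, seed = 8L),
    out_prefix = tempfile())
  prof <- profile_reads(rr$bam, fx$bench, hets = hets_small())
  cal <- quality_calibration(prof)
  cal <- cal[cal$errors >= 10, ]
  low <- cal[cal$reported_q <= 30, ]
  high <- cal[cal$reported_q > 30, ]
  expect_true(all(abs(low$observed_q - low$reported_q) < 1))
  expect_true(all(high$observed_q < high$reported_q - 3))
})

test_that("homopolymer observations honor the length and 5 bp flank rules", {
  # reference with a 12 bp A-run at positions 101..112 (0-based 100..111)
  set.seed(17)
  flanks <- function(n) paste(sample(c("C", "G", "T"), n, replace = TRUE),
                              collapse = "")
  ref <- paste0(flanks(100), strrep("A", 12), flanks(100))
  bench <- load_benchmark(c(h_hap1 = ref), c(h_hap2 = chartr("CG", "GC", ref)))
  runs <- annotate_runs(c(h_hap1 = ref))
  reads <- list(
    list(qname = "clean", rname = "h_hap1", pos = 1L, cigar = "212M",
         seq = ref, qual = strrep("I", 212)),
    # 1 bp deletion inside the run -> wrong length
    list(qname = "del_in_run", rname = "h_hap1", pos = 1L,
         cigar = "105M1D106M", seq = paste0(substr(ref, 1, 105),
                                            substr(ref, 107, 212)),
         qual = strrep("I", 211)),
    # substitution 3 bp before the run, run itself perfect -> flank rule
    local({
      rd <- ref
      substr(rd, 98, 98) <- "A"
      list(qname = "flank_sub", rname = "h_hap1", pos = 1L, cigar = "212M",
           seq = rd, qual = strrep("I", 212))
    }),
    # substitution 7 bp before the run: outside the flank -> still correct
    local({
      rd <- ref
      substr(rd, 94, 94) <- setdiff(c("A", "C", "G", "T"),
                                    substr(rd, 94, 94))[1]
      list(qname = "far_sub", rname = "h_hap1", pos = 1L, cigar = "212M",
           seq = rd, qual = strrep("I", 212))
    }))
  sam <- write_mini_sam(tempfile(fileext = ".sam"),
                        c(h_hap1 = ref), reads)
  prof <- profile_reads(sam, bench, runs = runs, het_mask = FALSE, flank = 5L)
  det <- prof$run_detail[prof$run_detail$run_len_bp == 12, ]
  expect_equal(det$spanned, 4L)
  expect_equal(det$correct, 2L)   # clean + far_sub only
  tab <- hp_quality_by_length(prof)
  row <- tab[tab$run_len == 12, ]
  expect_equal(row$incorrect, 2L)
  expect_equal(row$q, -10 * log10(2 / 4))
})

test_that("het-site masking removes cross-haplotype mismatches", {
  fx_snv <- cached("fx_snv_only", simulate_diploid_genome(
    genome_spec(n_chroms = 1L, chrom_len_bp = 150000L, het_indel_rate = 0,
                seed = 19L)))
  hets <- build_het_catalog(fx_snv$bench, fx_snv$alignments)
  base_spec <- read_spec(depth = 8, read_len_mean = 4000, seed = 23L)
  rr0 <- simulate_reads(fx_snv, base_spec, out_prefix = tempfile())
  cross_spec <- read_spec(depth = 8, read_len_mean = 4000,
                          crossmap_frac = 0.4, seed = 23L)
  rr1 <- simulate_reads(fx_snv, cross_spec, out_prefix = tempfile())
  expect_gt(sum(rr1$truth$crossmapped), 0)
  p0 <- profile_reads(rr0$bam, fx_snv$bench, hets = hets, het_mask = TRUE)
  p1 <- profile_reads(rr1$bam, fx_snv$bench, hets = hets, het_mask = TRUE)
  r0 <- sum(p0$sub_counts) / p0$aligned_bp
  r1 <- sum(p1$sub_counts) / p1$aligned_bp
  sigma <- 3 * sqrt(sum(p0$sub_counts)) / p0$aligned_bp
  expect_lt(abs(r1 - r0), 3 * sigma)
  # with masking off, het sites on cross-mapped reads inflate the mismatch
  # count by roughly (#crossmapped bases x het rate); check a safe fraction
  cross_bp <- sum(rr1$truth$read_len[rr1$truth$crossmapped])
  expect_gt(sum(p1_raw <- sum(profile_reads(rr1$bam, fx_snv$bench,
                                            het_mask = FALSE)$sub_counts)),
            sum(p1$sub_counts) + 0.3 * cross_bp * 1e-3)
})

test_that("arrival dispersion detects over- and under-dispersion", {
  set.seed(47)
  L <- 2e6; bin <- 1000
  starts <- list(chr = as.integer(sort(stats::runif(2e4, 0, L))))
  d <- arrival_dispersion(starts, c(chr = L), bin_size = bin)
  expect_equal(d$n_bins, 2000)
  expect_lt(d$D_below, 0.03)
  expect_lt(d$D_above, 0.03)
  # duplicating arrivals in half the bins inflates both D values
  dup <- starts$chr[starts$chr < L / 2]
  over <- list(chr = sort(c(starts$chr, dup)))
  d2 <- arrival_dispersion(over, c(chr = L), bin_size = bin)
  expect_gt(d2$D_below, 2 * d$D_below)
  expect_gt(d2$D_above, 2 * d$D_above)
  # constant arrivals: steeper than Poisson, D > 0
  const <- list(chr = as.integer(rep(seq(0, L - bin, by = bin) + 1,
                                     each = 10)))
  d3 <- arrival_dispersion(const, c(chr = L), bin_size = bin)
  expect_gt(max(d3$D_below, d3$D_above), d$D_above)
  expect_error(arrival_dispersion(list(chr = 1:10), c(chr = 50000),
                                  bin_size = 1000), "100 bins")
})

test_that("coverage_vs_gc drops N-heavy windows and tracks programmed bias", {
  set.seed(53)
  ref <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
               collapse = "")
  refn <- paste0(substr(ref, 1, 2000), strrep("N", 300),
                 substr(ref, 2301, 5000))
  prof <- structure(list(coverage = list(g_hap1 = rep(10L, 5000))),
                    class = "ReadProfile")
  bench <- load_benchmark(c(g_hap1 = refn), c(g_hap2 = ref))
  gc <- coverage_vs_gc(prof, bench, window = 100)
  # three windows are >10% N and must be dropped
  expect_equal(sum(gc$n_windows), 47)
  expect_true(all(gc$mean_coverage == 10))
})
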