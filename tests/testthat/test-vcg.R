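# vcg_builder: variant application, GQ masking, scoring

iv_contains_points_helper <- function(tv, probes) {
  hit <- rep(FALSE, length(probes))
  for (i in seq_len(nrow(tv))) {
    hit <- hit | (probes >= tv$hap1_pos0[i] &
                    probes < tv$hap1_pos0[i] + nchar(tv$ref[i]))
  }
  hit
}

mini_calls <- function(recs) {
  df <- do.call(rbind, lapply(recs, as.data.frame))
  df$is_ref_block <- df$is_ref_block %||% FALSE
  df$end <- df$end %||% (df$pos + nchar(df$ref) - 1L)
  df$phased <- grepl("|", df$gt, fixed = TRUE)
  class(df) <- c("PhasedCallset", "data.frame")
  df
}

test_that("variant application implements phase semantics and guards REF", {
  set.seed(61)
  ref <- c(rA = paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                      collapse = ""))
  substr(ref[["rA"]], 100, 100) <- "A"
  calls <- mini_calls(list(
    list(chrom = "rA", pos = 100L, ref = "A", alt = "G", gt = "1|0",
         gq = 50L)))
  h0 <- apply_phased_variants(ref, calls, 0L)
  h1 <- apply_phased_variants(ref, calls, 1L)
  expect_equal(substr(h0$seqs[["rA"]], 100, 100), "G")  # hap 0 takes allele 1
  expect_equal(substr(h1$seqs[["rA"]], 100, 100), "A")
  expect_true(h0$applied)

  # empty callset -> identity sequence and identity coordinate map
  empty <- mini_calls(list(list(chrom = "rA", pos = 1L, ref = substr(ref, 1, 1),
                                alt = "T", gt = "0|0", gq = 50L)))[0, ]
  id <- apply_phased_variants(ref, empty, 0L)
  expect_identical(unname(id$seqs[["rA"]]), unname(ref[["rA"]]))
  probes <- c(0L, 250L, 999L)
  expect_equal(dibench:::map_ref_to_cons(id$coord_map, "rA", probes), probes)

  # unphased het is not applied; homozygous unphased is applied
  calls2 <- mini_calls(list(
    list(chrom = "rA", pos = 200L, ref = substr(ref, 200, 200),
         alt = "T", gt = "0/1", gq = 50L),
    list(chrom = "rA", pos = 300L, ref = substr(ref, 300, 300),
         alt = "C", gt = "1/1", gq = 50L)))
  calls2$ref[2] <- substr(ref, 300, 300)
  h <- apply_phased_variants(ref, calls2, 1L)
  expect_equal(substr(h$seqs[["rA"]], 200, 200),
               unname(substr(ref[["rA"]], 200, 200)))
  if (substr(ref, 300, 300) != "C")
    expect_equal(substr(h$seqs[["rA"]], 300, 300), "C")
  expect_equal(h$applied, c(FALSE, TRUE))

  bad <- mini_calls(list(list(chrom = "rA", pos = 100L, ref = "T", alt = "G",
                              gt = "1|0", gq = 50L)))
  expect_error(apply_phased_variants(ref, bad, 0L), "REF mismatch")
})

test_that("round trip: truth VCF applied to the reference reproduces each haplotype", {
  fx <- cached("fx_sv", simulate_diploid_genome(genome_spec(
    n_chroms = 1L, chrom_len_bp = 120000L,
    sv_events = list(list(type = "insertion", length = 3000L),
                     list(type = "deletion", length = 2500L)),
    seed = 29L)))
  vcf <- tempfile(fileext = ".vcf")
  write_truth_vcf(fx$truth_variants, fx$bench$hap1, vcf)
  calls <- read_phased_calls(vcf)
  h0 <- apply_phased_variants(fx$bench$hap1, calls, 0L)
  h1 <- apply_phased_variants(fx$bench$hap1, calls, 1L)
  expect_identical(unname(h0$seqs[[1]]), unname(fx$bench$hap1[[1]]))
  expect_identical(unname(h1$seqs[[1]]), unname(fx$bench$hap2[[1]]))
  # coordinate map: probes between variants map to identical bases
  set.seed(1)
  probes <- sort(sample(nchar(fx$bench$hap1[[1]]) - 1, 200))
  mapped <- dibench:::map_ref_to_cons(h1$coord_map, names(fx$bench$hap1),
                                      probes)
  outside <- !iv_contains_points_helper(fx$truth_variants, probes)
  expect_true(all(substring(fx$bench$hap1[[1]], probes[outside] + 1,
                            probes[outside] + 1) ==
                  substring(h1$seqs[[1]], mapped[outside] + 1,
                            mapped[outside] + 1)))
})

test_that("GQ masking thresholds and monotonicity", {
  set.seed(67)
  ref <- c(rB = paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                      collapse = ""))
  rb <- function(p) substr(ref[["rB"]], p, p)
  calls <- mini_calls(list(
    list(chrom = "rB", pos = 500L, ref = rb(500), alt = "A", gt = "1|0",
         gq = 15L),
    list(chrom = "rB", pos = 900L, ref = rb(900), alt = "C", gt = "0|1",
         gq = 35L)))
  calls$alt[1] <- setdiff(c("A", "C", "G", "T"), rb(500))[1]
  calls$alt[2] <- setdiff(c("A", "C", "G", "T"), rb(900))[1]
  cons <- apply_phased_variants(ref, calls, 0L)
  m10 <- mask_regions(cons, calls, 10L)
  m20 <- mask_regions(cons, calls, 20L)
  m40 <- mask_regions(cons, calls, 40L)
  expect_equal(nrow(m10$masked), 0)
  expect_equal(nrow(m20$masked[m20$masked$reason == "low_GQ", ]), 1)
  expect_equal(m20$masked$start, 499L)
  expect_equal(substr(m20$seqs[["rB"]], 500, 500), "N")
  expect_equal(nrow(m40$masked), 2)
  widths <- vapply(list(m10, m20, m40), function(m)
    sum(m$masked$end - m$masked$start), 0)
  expect_false(is.unsorted(widths))

  # gVCF: low-GQ blocks and uncovered positions are masked as uncalled
  gvcf <- mini_calls(list(
    list(chrom = "rB", pos = 1L, ref = rb(1), alt = "<NON_REF>", gt = "0|0",
         gq = 50L, is_ref_block = TRUE, end = 1000L),
    list(chrom = "rB", pos = 1001L, ref = rb(1001), alt = "<NON_REF>",
         gt = "0|0", gq = 5L, is_ref_block = TRUE, end = 1500L)))
  mg <- mask_regions(cons, calls, 20L, gvcf = gvcf, ref_seqs = ref)
  unc <- mg$masked[mg$masked$reason == "uncalled", ]
  # low-GQ block [1000,1500) plus the tail [1500,2000) absent from any block;
  # both variant loci sit inside the good block
  expect_equal(sum(unc$end - unc$start), 1000)
})

test_that("build_and_score: clean round trip caps, omissions follow closed form", {
  fx <- fx_small()
  vcf <- tempfile(fileext = ".vcf")
  tv <- fx$truth_variants
  tv$gq <- 60L   # all confident
  write_truth_vcf(tv, fx$bench$hap1, vcf)
  calls <- read_phased_calls(vcf)
  sc <- build_and_score(fx, calls, thresholds = c(10L, 20L, 30L, 40L))
  expect_true(all(sc$qv_capped))
  expect_true(all(sc$covered_fraction > 0.999))
  expect_false(is.unsorted(rev(sc$covered_fraction)))  # non-increasing in GQ

  # omit ~1% of variants: QV equals the closed form on omitted bases
  set.seed(5)
  drop <- sample(nrow(tv), max(1, round(0.01 * nrow(tv))))
  vcf2 <- tempfile(fileext = ".vcf")
  write_truth_vcf(tv[-drop, ], fx$bench$hap1, vcf2)
  sc2 <- build_and_score(fx, read_phased_calls(vcf2), thresholds = 10L)
  omitted <- tv[drop, ]
  n_events <- nrow(omitted)   # each omitted variant is one discrepancy event
  expect_equal(sc2$n_discrepancies, n_events)
  expect_equal(sc2$qv, -10 * log10(n_events / sc2$aligned_bp),
               tolerance = 1e-9)
})

test_that("masked coverage is non-increasing across GQ thresholds 10..40", {
  fx <- fx_small()
  vcf <- tempfile(fileext = ".vcf")
  write_truth_vcf(fx$truth_variants, fx$bench$hap1, vcf)  # programmed GQs
  sc <- build_and_score(fx, read_phased_calls(vcf))
  expect_equal(sc$gq_min, c(10L, 20L, 30L, 40L))
  expect_false(is.unsorted(sc$masked_bp))
  expect_false(is.unsorted(rev(sc$covered_fraction)))
  expect_true(all(sc$qv_capped))  # all applied alleles are truth alleles
})
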