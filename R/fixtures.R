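# Synthetic fixtures: diploid genomes, corrupted assemblies, simulated reads.
# Every modification is logged in a truth table; one RNG substream per
# generator stage so adding a feature never perturbs another's draws.

#' Specification for a synthetic diploid genome
#'
#' Defaults describe a small human-like fixture: two chromosome pairs,
#' heterozygous SNV rate 1e-3/bp and het indel rate 1e-4/bp (typical human
#' heterozygosity), seeded homopolymer/STR runs, no N gaps.
#'
#' @param n_chroms chromosomes per haplotype
#' @param chrom_len_bp length of each chromosome
#' @param het_snv_rate,het_indel_rate per-bp heterozygous variant rates
#'   (must be <= 0.05)
#' @param sv_events list of list(type = "insertion"/"deletion", length)
#'   planted as large het variants
#' @param run_density_per_mb target seeded tandem runs per Mb (split across
#'   unit sizes 1-4)
#' @param run_len_range seeded run lengths in bp
#' @param n_gaps list of list(chrom, start, len) N gaps on both haplotypes
#' @param min_spacing minimum bp between planted variants (default 2k for
#'   k = 31 so each variant's markers are independent)
#' @param seed RNG seed
#' @return list of class `GenomeSpec`
#' @export
genome_spec <- function(n_chroms = 2L, chrom_len_bp = 2500000L,
                        het_snv_rate = 1e-3, het_indel_rate = 1e-4,
                        sv_events = list(), run_density_per_mb = 100,
                        run_len_range = c(8L, 30L), n_gaps = list(),
                        min_spacing = 62L, seed = 1L) {
  stopifnot(het_snv_rate >= 0, het_snv_rate <= 0.05,
            het_indel_rate >= 0, het_indel_rate <= 0.05)
  structure(as.list(environment()), class = "GenomeSpec")
}

#' Simulate a diploid benchmark genome with known truth
#'
#' hap2 is derived from hap1 by planting heterozygous variants; the truth
#' variant table, a truth VCF representation (hap1 as the reference), and
#' exact truth hap2-to-hap1 alignments are emitted alongside the benchmark.
#'
#' @param spec a [genome_spec()]
#' @return list of class `DiploidFixture`: bench, truth_variants
#'   (chrom, pos = 1-based VCF position, ref, alt, type, gq, hap1_pos0,
#'   hap2_pos0), alignments (hap2 query vs hap1 target, CIGAR =/X/I/D),
#'   non_n_bp (generator's own tally), spec
#' @export
simulate_diploid_genome <- function(spec = genome_spec()) {
  hap1 <- character(0); hap2 <- character(0)
  all_vars <- list(); all_aln <- list()
  for (ci in seq_len(spec$n_chroms)) {
    nm1 <- sprintf("chr%d_hap1", ci); nm2 <- sprintf("chr%d_hap2", ci)
    len <- spec$chrom_len_bp
    s1 <- with_seed(substream_seed(spec$seed, paste0("seq", ci)), {
      chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      # seed tandem runs
      n_runs <- round(spec$run_density_per_mb * len / 1e6)
      if (n_runs > 0) {
        max_run <- spec$run_len_range[2]
        if (n_runs * (max_run + 20) > len)
          stop("infeasible run density for sequence length")
        at <- sort(sample.int(len - max_run - 20, n_runs))
        at <- at[c(TRUE, diff(at) > max_run + 10)]
        for (p in at) {
          u <- sample(1:4, 1, prob = c(0.5, 0.2, 0.15, 0.15))
          unit <- sample(c("A", "C", "G", "T"), u)
          rl <- sample(seq(spec$run_len_range[1], max_run), 1)
          rl <- max(rl, u * 3L)
          runseq <- rep(unit, length.out = rl)
          chars[p:(p + rl - 1)] <- runseq
          # break accidental extension on both sides
          if (p > 1 && chars[p - 1] == runseq[1])
            chars[p - 1] <- setdiff(c("A", "C", "G", "T"), runseq[1])[1]
          aft <- p + rl
          if (aft <= len && chars[aft] == runseq[(rl %% length(unit)) + 1])
            chars[aft] <- setdiff(c("A", "C", "G", "T"),
                                  runseq[(rl %% length(unit)) + 1])[1]
        }
      }
      for (g in spec$n_gaps) {
        if (identical(g$chrom, ci) || identical(g$chrom, nm1)) {
          chars[(g$start + 1):(g$start + g$len)] <- "N"
        }
      }
      paste(chars, collapse = "")
    })

    vars <- with_seed(substream_seed(spec$seed, paste0("variants", ci)), {
      plant_het_variants(s1, spec, ci)
    })
    built <- apply_variant_cigar(s1, vars)
    hap1[nm1] <- s1
    hap2[nm2] <- built$seq
    if (nrow(vars) > 0) {
      vars$chrom <- nm1
      vars$hap2_pos0 <- built$hap2_pos0
      all_vars[[ci]] <- vars
    }
    all_aln[[ci]] <- data.frame(
      query = nm2, query_len = nchar(built$seq), q_start = 0L,
      q_end = nchar(built$seq), strand = "+", target_seq = nm1,
      t_start = 0L, t_end = nchar(s1), cigar = built$cigar,
      is_primary = TRUE, target_hap = "hap1", stringsAsFactors = FALSE)
  }
  truth <- if (length(all_vars)) do.call(rbind, all_vars) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), type = character(), gq = integer(),
               hap1_pos0 = integer(), hap2_pos0 = integer(),
               stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  bench <- load_benchmark(hap1, hap2)
  non_n <- sum(nchar(hap1)) + sum(nchar(hap2)) -
    sum(vapply(c(hap1, hap2), function(s)
      sum(gregexpr("N", s, fixed = TRUE)[[1]] > 0), 0))
  structure(list(bench = bench, truth_variants = truth,
                 alignments = do.call(rbind, all_aln),
                 non_n_bp = non_n, spec = spec),
            class = "DiploidFixture")
}

# plant het SNVs/indels/SVs on one chromosome; returns VCF-style records
# ordered by position with 0-based hap1 anchor positions
plant_het_variants <- function(s1, spec, ci) {
  len <- nchar(s1)
  chars <- strsplit(s1, "")[[1]]
  k_guard <- spec$min_spacing
  bases <- c("A", "C", "G", "T")
  # place large SVs first so small variants can avoid their footprints
  sv_recs <- list()
  sv_iv <- matrix(numeric(0), ncol = 2)
  for (sv in spec$sv_events) {
    tries <- 0
    repeat {
      tries <- tries + 1
      if (tries > 1000) stop("could not place SV without collisions")
      p0 <- sample.int(len - sv$length - 2L * k_guard, 1) + k_guard
      span <- if (sv$type == "deletion") sv$length else 0L
      if (nrow(sv_iv) == 0 ||
          all(p0 + span + k_guard < sv_iv[, 1] |
                p0 - k_guard > sv_iv[, 2])) break
    }
    rb <- chars[p0 + 1]
    if (sv$type == "insertion") {
      ins <- paste(sample(bases, sv$length, replace = TRUE), collapse = "")
      sv_recs[[length(sv_recs) + 1]] <- data.frame(
        pos = p0 + 1L, ref = rb, alt = paste0(rb, ins), type = "sv_ins",
        hap1_pos0 = p0, stringsAsFactors = FALSE)
    } else if (sv$type == "deletion") {
      del <- substr(s1, p0 + 2L, p0 + 1L + sv$length)
      sv_recs[[length(sv_recs) + 1]] <- data.frame(
        pos = p0 + 1L, ref = paste0(rb, del), alt = rb, type = "sv_del",
        hap1_pos0 = p0, stringsAsFactors = FALSE)
    } else stop("unsupported sv type: ", sv$type)
    sv_iv <- rbind(sv_iv, c(p0, p0 + span))
  }
  n_snv <- stats::rbinom(1, len, spec$het_snv_rate)
  n_ind <- stats::rbinom(1, len, spec$het_indel_rate)
  pos_all <- sort(sample.int(len - 2L * k_guard, n_snv + n_ind) + k_guard)
  pos_all <- pos_all[c(TRUE, diff(pos_all) > k_guard)]
  if (nrow(sv_iv) > 0) {
    clear <- vapply(pos_all, function(p)
      all(p + k_guard < sv_iv[, 1] | p - k_guard > sv_iv[, 2]), TRUE)
    pos_all <- pos_all[clear]
  }
  is_snv <- sample(rep(c(TRUE, FALSE),
                       c(min(n_snv, length(pos_all)),
                         max(0, length(pos_all) - n_snv))))
  recs <- vector("list", length(pos_all))
  for (i in seq_along(pos_all)) {
    p0 <- pos_all[i] - 1L  # 0-based
    rb <- chars[p0 + 1]
    if (!rb %in% bases) next
    if (is_snv[i]) {
      alt <- sample(setdiff(bases, rb), 1)
      recs[[i]] <- data.frame(pos = p0 + 1L, ref = rb, alt = alt,
                              type = "snv", hap1_pos0 = p0,
                              stringsAsFactors = FALSE)
    } else {
      l <- min(1L + stats::rgeom(1, 0.4), 10L)
      if (stats::runif(1) < 0.5) { # insertion in hap2
        ins <- paste(sample(bases, l, replace = TRUE), collapse = "")
        recs[[i]] <- data.frame(pos = p0 + 1L, ref = rb,
                                alt = paste0(rb, ins), type = "ins",
                                hap1_pos0 = p0, stringsAsFactors = FALSE)
      } else {                     # deletion in hap2
        del <- substr(s1, p0 + 2L, p0 + 1L + l)
        if (grepl("N", del) || nchar(del) < l) next
        recs[[i]] <- data.frame(pos = p0 + 1L, ref = paste0(rb, del),
                                alt = rb, type = "del", hap1_pos0 = p0,
                                stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, c(recs[!vapply(recs, is.null, TRUE)], sv_recs))
  if (is.null(out) || nrow(out) == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      type = character(), gq = integer(),
                      hap1_pos0 = integer(), stringsAsFactors = FALSE))
  out <- out[order(out$pos), , drop = FALSE]
  # drop overlaps introduced by deletion spans
  span_end <- out$hap1_pos0 + nchar(out$ref)
  keep <- c(TRUE, out$hap1_pos0[-1] >= cummax(span_end)[-nrow(out)] + k_guard)
  out <- out[keep, , drop = FALSE]
  out$gq <- sample(2:60, nrow(out), replace = TRUE)
  out$chrom <- NA_character_
  rownames(out) <- NULL
  out[, c("chrom", "pos", "ref", "alt", "type", "gq", "hap1_pos0")]
}

# apply VCF-style records (sorted, non-overlapping) to a sequence; returns
# the derived sequence, the truth CIGAR (query = derived, target = source)
# and the 0-based derived-coordinate anchor of every record
apply_variant_cigar <- function(src, vars) {
  if (nrow(vars) == 0)
    return(list(seq = src, cigar = paste0(nchar(src), "="),
                hap2_pos0 = integer(0)))
  pieces <- character(0); lens <- integer(0); ops <- character(0)
  hap2_pos0 <- integer(nrow(vars))
  cur <- 0L   # 0-based position on src
  out_len <- 0L
  for (i in seq_len(nrow(vars))) {
    p0 <- vars$hap1_pos0[i]
    ref <- vars$ref[i]; alt <- vars$alt[i]
    if (p0 > cur) {
      pieces <- c(pieces, substr(src, cur + 1L, p0))
      lens <- c(lens, p0 - cur); ops <- c(ops, "=")
      out_len <- out_len + (p0 - cur)
    }
    hap2_pos0[i] <- out_len
    if (nchar(ref) == 1 && nchar(alt) == 1) {        # SNV
      pieces <- c(pieces, alt)
      lens <- c(lens, 1L); ops <- c(ops, "X")
      out_len <- out_len + 1L
    } else if (nchar(alt) > nchar(ref)) {            # insertion (in derived)
      pieces <- c(pieces, alt)
      lens <- c(lens, 1L, nchar(alt) - 1L); ops <- c(ops, "=", "I")
      out_len <- out_len + nchar(alt)
    } else {                                         # deletion (in derived)
      pieces <- c(pieces, alt)
      lens <- c(lens, 1L, nchar(ref) - 1L); ops <- c(ops, "=", "D")
      out_len <- out_len + 1L
    }
    cur <- p0 + nchar(ref)
  }
  if (cur < nchar(src)) {
    pieces <- c(pieces, substr(src, cur + 1L, nchar(src)))
    lens <- c(lens, nchar(src) - cur); ops <- c(ops, "=")
  }
  list(seq = paste(pieces, collapse = ""), cigar = cig_build(lens, ops),
       hap2_pos0 = hap2_pos0)
}

# cumulative hap1 -> hap2 coordinate offset just before hap1 position p0
hap1_to_hap2_pos <- function(truth_variants, chrom, p0) {
  v <- truth_variants[truth_variants$chrom == chrom &
                        truth_variants$hap1_pos0 + nchar(truth_variants$ref) <= p0, ,
                      drop = FALSE]
  p0 + sum(nchar(v$alt)) - sum(nchar(v$ref))
}

#' Write a diploid fixture to disk
#'
#' Emits hap1/hap2 FASTA, the truth VCF (hap1 as reference, one phased
#' sample with genotype 0|1 and the programmed GQ), the truth alignment PAF,
#' and the truth variant TSV.
#' @param fix a `DiploidFixture`
#' @param dir output directory
#' @return dir, invisibly
#' @export
write_fixture <- function(fix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(fix$bench$hap1, file.path(dir, "hap1.fasta"))
  write_fasta(fix$bench$hap2, file.path(dir, "hap2.fasta"))
  write_truth_vcf(fix$truth_variants, fix$bench$hap1,
                  file.path(dir, "truth.vcf"))
  write_paf(fix$alignments, file.path(dir, "truth.paf"))
  utils::write.table(fix$truth_variants, file.path(dir, "truth_variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write truth variants as a phased VCF (genotype 0|1, hap index 0 = the
#' reference haplotype)
#' @param vars truth variant table (chrom, pos, ref, alt, gq)
#' @param ref_seqs named character vector, the reference the positions refer to
#' @param path output VCF
#' @param sample sample name
#' @export
write_truth_vcf <- function(vars, ref_seqs, path, sample = "truth") {
  con <- file(path, "w")
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##contig=<ID=", names(ref_seqs), ",length=",
                      nchar(ref_seqs), ">"),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype Quality">',
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sample, sep = "\t")), con)
  if (nrow(vars) > 0) {
    writeLines(paste(vars$chrom, vars$pos, ".", vars$ref, vars$alt, "60",
                     "PASS", ".", "GT:GQ",
                     paste0("0|1:", vars$gq), sep = "\t"), con)
  }
  close(con)
  invisible(path)
}

#' Write alignment segments as PAF with cg CIGAR tags
#' @param segs alignment segments data.frame
#' @param path output PAF
#' @export
write_paf <- function(segs, path) {
  n_match <- vapply(segs$cigar, function(cg) {
    o <- cig_ops(cg); sum(o$len[o$op %in% c("=", "M")])
  }, 0)
  aln_len <- vapply(segs$cigar, function(cg) {
    o <- cig_ops(cg); sum(o$len[o$op %in% c("=", "M", "X", "I", "D")])
  }, 0)
  tlen <- segs$t_end - segs$t_start
  lines <- paste(segs$query, segs$query_len, segs$q_start, segs$q_end,
                 segs$strand, segs$target_seq,
                 segs$t_end + 0, segs$t_start, segs$t_end,
                 n_match, aln_len, 60,
                 ifelse(segs$is_primary, "tp:A:P", "tp:A:S"),
                 paste0("cg:Z:", segs$cigar), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

# ---- corrupted assemblies --------------------------------------------------

#' Specification for planted assembly errors
#'
#' Counts are per haplotype.  Planted events avoid each other and het sites
#' by at least `guard` bp so every event maps to exactly one truth record.
#'
#' @param n_sub,n_ins,n_del planted substitutions / insertions / deletions
#'   per haplotype
#' @param n_phase_sub substitutions planted at het SNV sites carrying the
#'   alternate haplotype's allele (phase-consistent errors) per haplotype
#' @param indel_len_range small indel lengths
#' @param big_events list of list(seq, pos, type = "insertion"/"deletion",
#'   length) for NGAx-scale indels at fixed positions
#' @param switch_points list of list(chrom = index or hap1 name, pos =
#'   hap1 coordinate); the corrupted hap1 contig continues on hap2 sequence
#'   from the homologous position (a phase switch)
#' @param dropout_regions list of list(seq, start, end) removed from contigs
#'   (alignment splits; bases become uncovered)
#' @param collapse_regions list of list(chrom = index or hap1 name, start,
#'   end): within the region the hap2 contig carries hap1's alleles at het
#'   SNVs (an SNV-level haplotype collapse)
#' @param hp_noise NULL or list(min_len, p): homopolymer runs of at least
#'   min_len bp get a +-1 length error with probability p
#' @param guard minimum distance between planted events / het sites
#' @param seed RNG seed
#' @return list of class `ErrorSpec`
#' @export
error_spec <- function(n_sub = 0L, n_ins = 0L, n_del = 0L, n_phase_sub = 0L,
                       indel_len_range = c(1L, 10L), big_events = list(),
                       switch_points = list(), dropout_regions = list(),
                       collapse_regions = list(), hp_noise = NULL,
                       guard = 62L, seed = 1L) {
  structure(as.list(environment()), class = "ErrorSpec")
}

#' Corrupt a benchmark into a test assembly with a known error catalog
#'
#' Each benchmark haplotype sequence becomes one contig carrying the planted
#' errors.  The truth error catalog is expressed in benchmark coordinates in
#' the same classification scheme [catalog_discrepancies()] reports, and
#' exact truth alignments (contig vs benchmark) are emitted.
#'
#' @param fix a `DiploidFixture` (needed for het-aware planting) or a
#'   `DiploidBenchmark` when no het-dependent events are requested
#' @param spec an [error_spec()]
#' @return list of class `AssemblyFixture`: contigs, truth_catalog,
#'   alignments, dropouts (interval set), spec
#' @export
corrupt_assembly <- function(fix, spec = error_spec()) {
  bench <- if (inherits(fix, "DiploidFixture")) fix$bench else fix
  truth_vars <- if (inherits(fix, "DiploidFixture")) fix$truth_variants else NULL
  if ((spec$n_phase_sub > 0 || length(spec$switch_points) > 0 ||
       length(spec$collapse_regions) > 0) && is.null(truth_vars))
    stop("phase-dependent events require a DiploidFixture with truth variants")

  seqs <- c(bench$hap1, bench$hap2)
  haps <- c(rep("hap1", length(bench$hap1)), rep("hap2", length(bench$hap2)))
  contigs <- character(0)
  catalog <- list(); aln <- list(); dropouts <- empty_iv()

  # per-haplotype counts are split across that haplotype's sequences
  share <- function(n, nseq, idx) n %/% nseq + (idx <= n %% nseq)
  hap_seq_idx <- stats::ave(seq_along(haps), haps, FUN = seq_along)
  hap_nseq <- stats::ave(seq_along(haps), haps, FUN = length)

  for (si in seq_along(seqs)) {
    nm <- names(seqs)[si]; hap <- haps[si]
    src <- seqs[[nm]]
    sspec <- spec
    for (f in c("n_sub", "n_ins", "n_del", "n_phase_sub"))
      sspec[[f]] <- share(spec[[f]], hap_nseq[si], hap_seq_idx[si])
    events <- with_seed(substream_seed(spec$seed, paste0("errors_", nm)), {
      plan_contig_events(nm, hap, src, bench, truth_vars, sspec)
    })
    built <- build_corrupt_contig(nm, hap, src, events, spec, bench, truth_vars)
    contigs[built$contig_name] <- built$seq
    catalog[[nm]] <- built$catalog
    aln[[nm]] <- built$alignments
    dropouts <- rbind(dropouts, built$dropouts)
  }
  truth_catalog <- do.call(rbind, catalog[!vapply(catalog, is.null, TRUE)])
  if (is.null(truth_catalog))
    truth_catalog <- data.frame(target_hap = character(),
                                target_seq = character(), t_pos = integer(),
                                klass = character(), sub_type = character(),
                                ti_tv = character(), length = integer(),
                                stringsAsFactors = FALSE)
  truth_catalog <- truth_catalog[order(truth_catalog$target_hap,
                                       truth_catalog$target_seq,
                                       truth_catalog$t_pos), , drop = FALSE]
  rownames(truth_catalog) <- NULL
  structure(list(contigs = contigs, truth_catalog = truth_catalog,
                 alignments = do.call(rbind, aln), dropouts = dropouts,
                 spec = spec),
            class = "AssemblyFixture")
}

# choose event positions for one contig; returns a data.frame of events
# (t_pos 0-based on the source sequence, klass, length, alt payload)
plan_contig_events <- function(nm, hap, src, bench, truth_vars, spec) {
  len <- nchar(src)
  guard <- spec$guard
  blocked <- integer(0)   # positions events must stay away from
  if (!is.null(truth_vars)) {
    # het positions on this sequence (either haplotype)
    if (hap == "hap1") {
      v <- truth_vars[truth_vars$chrom == nm, , drop = FALSE]
      blocked <- v$hap1_pos0
    } else {
      tok <- sub("[_.].*$", "", nm)
      v <- truth_vars[sub("[_.].*$", "", truth_vars$chrom) == tok, , drop = FALSE]
      blocked <- v$hap2_pos0
    }
  }
  fixed_pos <- integer(0)
  for (ev in spec$big_events) if (identical(ev$seq, nm))
    fixed_pos <- c(fixed_pos, ev$pos)
  taken <- c(blocked, fixed_pos)
  bases <- c("A", "C", "G", "T")
  draw_pos <- function(n, span = 1L) {
    out <- integer(0)
    tries <- 0
    while (length(out) < n) {
      tries <- tries + 1
      if (tries > 50 * n + 1000) stop("could not place planted events")
      p <- sample.int(len - 2L * guard - span, 1) + guard
      if (all(abs(c(taken, out) - p) > guard + span) &&
          !grepl("N", substr(src, p, p + span + 2)))
        out <- c(out, p)
    }
    taken <<- c(taken, out)
    sort(out)
  }
  evs <- list()
  if (spec$n_sub > 0) {
    pos <- draw_pos(spec$n_sub)
    rb <- substring(src, pos + 1, pos + 1)
    ab <- vapply(rb, function(b) sample(setdiff(bases, b), 1), "")
    evs$sub <- data.frame(t_pos = pos, klass = "substitution", length = 1L,
                          payload = unname(ab), stringsAsFactors = FALSE)
  }
  if (spec$n_ins > 0) {
    pos <- draw_pos(spec$n_ins)
    l <- sample(seq(spec$indel_len_range[1], spec$indel_len_range[2]),
                spec$n_ins, replace = TRUE)
    ins <- vapply(l, function(x)
      paste(sample(bases, x, replace = TRUE), collapse = ""), "")
    evs$ins <- data.frame(t_pos = pos, klass = "insertion", length = l,
                          payload = ins, stringsAsFactors = FALSE)
  }
  if (spec$n_del > 0) {
    span <- spec$indel_len_range[2]
    pos <- draw_pos(spec$n_del, span = span)
    l <- sample(seq(spec$indel_len_range[1], spec$indel_len_range[2]),
                spec$n_del, replace = TRUE)
    evs$del <- data.frame(t_pos = pos, klass = "deletion", length = l,
                          payload = "", stringsAsFactors = FALSE)
  }
  if (spec$n_phase_sub > 0) {
    # het SNV sites on this sequence, assembly allele := other haplotype's
    snv <- truth_vars[truth_vars$type == "snv", , drop = FALSE]
    if (hap == "hap1") {
      snv <- snv[snv$chrom == nm, , drop = FALSE]
      hp <- snv$hap1_pos0; other <- snv$alt
    } else {
      tok <- sub("[_.].*$", "", nm)
      snv <- snv[sub("[_.].*$", "", snv$chrom) == tok, , drop = FALSE]
      hp <- snv$hap2_pos0; other <- snv$ref
    }
    ok <- vapply(hp, function(p) all(abs(setdiff(taken, blocked) - p) > guard),
                 TRUE)
    if (sum(ok) < spec$n_phase_sub)
      stop("not enough het sites to plant phase-consistent substitutions")
    pick <- sort(sample(which(ok), spec$n_phase_sub))
    evs$phase <- data.frame(t_pos = hp[pick], klass = "phase_consistent",
                            length = 1L, payload = other[pick],
                            stringsAsFactors = FALSE)
    taken <- c(taken, hp[pick])
  }
  for (ev in spec$big_events) {
    if (!identical(ev$seq, nm)) next
    if (ev$type == "insertion") {
      ins <- paste(sample(bases, ev$length, replace = TRUE), collapse = "")
      evs[[paste0("big", ev$pos)]] <- data.frame(
        t_pos = ev$pos, klass = "insertion", length = ev$length,
        payload = ins, stringsAsFactors = FALSE)
    } else {
      evs[[paste0("big", ev$pos)]] <- data.frame(
        t_pos = ev$pos, klass = "deletion", length = ev$length,
        payload = "", stringsAsFactors = FALSE)
    }
  }
  if (!is.null(spec$hp_noise)) {
    runs <- annotate_runs(stats::setNames(src, nm), unit_sizes = 1L)
    runs <- runs[runs$run_len_bp >= spec$hp_noise$min_len, , drop = FALSE]
    if (nrow(runs) > 0) {
      hit <- stats::runif(nrow(runs)) < spec$hp_noise$p
      for (i in which(hit)) {
        p <- runs$start[i] + sample.int(runs$run_len_bp[i] - 1L, 1)
        if (any(abs(taken - p) <= guard)) next
        if (stats::runif(1) < 0.5) {
          evs[[paste0("hp", p)]] <- data.frame(
            t_pos = p, klass = "insertion", length = 1L,
            payload = runs$unit[i], stringsAsFactors = FALSE)
        } else {
          evs[[paste0("hp", p)]] <- data.frame(
            t_pos = p, klass = "deletion", length = 1L, payload = "",
            stringsAsFactors = FALSE)
        }
        taken <- c(taken, p)
      }
    }
  }
  for (cr in spec$collapse_regions) {
    crn <- if (is.numeric(cr$chrom)) sprintf("chr%d_%s", cr$chrom, hap)
           else cr$chrom
    if (!identical(crn, nm) || hap != "hap2") next
    tok <- sub("[_.].*$", "", nm)
    snv <- truth_vars[truth_vars$type == "snv" &
                        sub("[_.].*$", "", truth_vars$chrom) == tok, ,
                      drop = FALSE]
    inreg <- snv$hap2_pos0 >= cr$start & snv$hap2_pos0 < cr$end
    if (any(inreg))
      evs[[paste0("collapse", cr$start)]] <- data.frame(
        t_pos = snv$hap2_pos0[inreg], klass = "phase_consistent",
        length = 1L, payload = snv$ref[inreg], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, evs)
  if (is.null(out))
    out <- data.frame(t_pos = integer(), klass = character(),
                      length = integer(), payload = character(),
                      stringsAsFactors = FALSE)
  dup <- duplicated(out$t_pos)
  out <- out[!dup, , drop = FALSE]
  out[order(out$t_pos), , drop = FALSE]
}

# apply events to the source sequence; build contig, truth catalog rows and
# truth alignments (handling dropouts and phase switches)
build_corrupt_contig <- function(nm, hap, src, events, spec, bench,
                                 truth_vars) {
  contig_name <- paste0(nm, "_ctg")
  drops <- list()
  for (d in spec$dropout_regions) if (identical(d$seq, nm))
    drops[[length(drops) + 1]] <- d
  switches <- list()
  for (sw in spec$switch_points) {
    swn <- if (is.numeric(sw$chrom)) sprintf("chr%d_hap1", sw$chrom) else sw$chrom
    if (identical(swn, nm)) switches[[length(switches) + 1]] <- sw
  }
  if (length(switches) > 1) stop("at most one switch point per contig")

  # base-level events -> contig pieces + CIGAR on [seg_start, seg_end)
  apply_events <- function(seq, ev, seg_start, seg_end) {
    ev <- ev[ev$t_pos >= seg_start & ev$t_pos < seg_end, , drop = FALSE]
    pieces <- character(0); lens <- integer(0); ops <- character(0)
    cur <- seg_start
    for (i in seq_len(nrow(ev))) {
      p <- ev$t_pos[i]
      if (p > cur) {
        pieces <- c(pieces, substr(seq, cur + 1, p))
        lens <- c(lens, p - cur); ops <- c(ops, "=")
      }
      if (ev$klass[i] %in% c("substitution", "phase_consistent")) {
        pieces <- c(pieces, ev$payload[i])
        lens <- c(lens, 1L); ops <- c(ops, "X")
        cur <- p + 1L
      } else if (ev$klass[i] == "insertion") {
        # inserted bases appear after target base p (left-anchored)
        pieces <- c(pieces, substr(seq, p + 1, p + 1), ev$payload[i])
        lens <- c(lens, 1L, ev$length[i]); ops <- c(ops, "=", "I")
        cur <- p + 1L
      } else { # deletion of [p+1, p+length] keeping anchor p
        pieces <- c(pieces, substr(seq, p + 1, p + 1))
        lens <- c(lens, 1L, ev$length[i]); ops <- c(ops, "=", "D")
        cur <- p + 1L + ev$length[i]
      }
    }
    if (cur < seg_end) {
      pieces <- c(pieces, substr(seq, cur + 1, seg_end))
      lens <- c(lens, seg_end - cur); ops <- c(ops, "=")
    }
    list(seq = paste(pieces, collapse = ""),
         cigar = cig_build(lens, ops))
  }

  # segment the source at dropouts (and at the switch point)
  seg_bounds <- list()
  cur <- 0L; len <- nchar(src)
  sw_at <- if (length(switches)) switches[[1]]$pos else NA
  cuts <- sort(unique(c(
    unlist(lapply(drops, function(d) c(d$start, d$end))),
    if (!is.na(sw_at)) sw_at)))
  bounds <- unique(c(0L, cuts, len))
  drop_iv <- if (length(drops))
    do.call(rbind, lapply(drops, function(d)
      data.frame(seq = nm, start = d$start, end = d$end,
                 stringsAsFactors = FALSE))) else empty_iv()

  contig_parts <- character(0)
  alns <- list()
  cat_rows <- list()
  q_cursor <- 0L
  for (bi in seq_len(length(bounds) - 1)) {
    s <- bounds[bi]; e <- bounds[bi + 1]
    if (nrow(drop_iv) > 0 &&
        any(drop_iv$start <= s & drop_iv$end >= e)) next  # dropped segment
    after_switch <- !is.na(sw_at) && s >= sw_at
    if (after_switch && hap == "hap1") {
      # splice the homologous hap2 sequence from the mapped position on
      tok <- sub("[_.].*$", "", nm)
      nm2 <- paste0(tok, "_hap2")
      s2 <- hap1_to_hap2_pos(truth_vars, nm, s)
      e2 <- hap1_to_hap2_pos(truth_vars, nm, e)
      piece <- substr(bench$hap2[[nm2]], s2 + 1L, e2)
      contig_parts <- c(contig_parts, piece)
      alns[[length(alns) + 1]] <- data.frame(
        query = contig_name, query_len = NA_integer_,
        q_start = q_cursor, q_end = q_cursor + nchar(piece), strand = "+",
        target_seq = nm2, t_start = s2, t_end = e2,
        cigar = paste0(nchar(piece), "="), is_primary = TRUE,
        target_hap = "hap2", stringsAsFactors = FALSE)
      q_cursor <- q_cursor + nchar(piece)
      next
    }
    res <- apply_events(src, events, s, e)
    contig_parts <- c(contig_parts, res$seq)
    alns[[length(alns) + 1]] <- data.frame(
      query = contig_name, query_len = NA_integer_,
      q_start = q_cursor, q_end = q_cursor + nchar(res$seq), strand = "+",
      target_seq = nm, t_start = s, t_end = e, cigar = res$cigar,
      is_primary = TRUE, target_hap = hap, stringsAsFactors = FALSE)
    q_cursor <- q_cursor + nchar(res$seq)
    ev <- events[events$t_pos >= s & events$t_pos < e, , drop = FALSE]
    if (nrow(ev) > 0) {
      rb <- substring(src, ev$t_pos + 1, ev$t_pos + 1)
      st <- ifelse(ev$klass == "substitution",
                   paste0(rb, ">", ev$payload), NA)
      cat_rows[[length(cat_rows) + 1]] <- data.frame(
        target_hap = hap, target_seq = nm,
        # deletions are reported at their first deleted base (anchor + 1)
        t_pos = ev$t_pos + (ev$klass == "deletion"),
        klass = ev$klass, sub_type = st,
        ti_tv = ifelse(is.na(st), NA,
                       ifelse(st %in% TRANSITIONS, "Ti", "Tv")),
        length = ev$length, stringsAsFactors = FALSE)
    }
  }
  seq <- paste(contig_parts, collapse = "")
  alns <- do.call(rbind, alns)
  if (!is.null(alns)) alns$query_len <- nchar(seq)
  catalog <- do.call(rbind, cat_rows)
  list(contig_name = contig_name, seq = seq, catalog = catalog,
       alignments = alns, dropouts = drop_iv)
}
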