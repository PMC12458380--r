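# Variant constructed genomes: apply phased calls to a reference per
# haplotype, mask low-GQ / uncalled / unphased positions, score the result.

#' Read a phased variant call set (VCF or gVCF)
#'
#' Uses VariantAnnotation; gVCF reference blocks (symbolic `<NON_REF>` ALT
#' or an INFO END field) are returned with `is_ref_block = TRUE` and their
#' block end.
#'
#' @param path VCF/gVCF file (bgzipped + indexed accepted)
#' @param sample sample column to use (default: first)
#' @return data.frame (chrom, pos, ref, alt, gt, gq, phased, is_ref_block,
#'   end) of class `PhasedCallset`; pos/end are 1-based
#' @export
read_phased_calls <- function(path, sample = 1L) {
  v <- VariantAnnotation::readVcf(path)
  gr <- SummarizedExperiment::rowRanges(v)
  alt <- as.character(unlist(lapply(VariantAnnotation::alt(v), function(a)
    paste(as.character(a), collapse = ","))))
  gt <- VariantAnnotation::geno(v)$GT[, sample]
  gq <- if ("GQ" %in% names(VariantAnnotation::geno(v)))
    as.integer(VariantAnnotation::geno(v)$GQ[, sample]) else NA_integer_
  info <- VariantAnnotation::info(v)
  end_info <- if ("END" %in% names(info)) as.integer(info$END) else
    rep(NA_integer_, length(gr))
  is_block <- alt %in% c("<NON_REF>", "<*>", "") | !is.na(end_info)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    pos = GenomicRanges::start(gr),
    ref = as.character(VariantAnnotation::ref(v)),
    alt = alt, gt = gt,
    gq = gq,
    phased = grepl("|", gt, fixed = TRUE),
    is_ref_block = is_block,
    end = ifelse(is_block,
                 ifelse(is.na(end_info), GenomicRanges::end(gr), end_info),
                 GenomicRanges::end(gr)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("PhasedCallset", "data.frame")
  out
}

# genotype allele index for one haplotype; NA for missing
gt_allele <- function(gt, hap_index) {
  parts <- strsplit(gt, "[|/]")
  vapply(parts, function(p) {
    if (length(p) < hap_index + 1) return(NA_integer_)
    suppressWarnings(as.integer(p[hap_index + 1]))
  }, 1L)
}

# is the genotype homozygous (both alleles equal and called)?
gt_hom <- function(gt) {
  parts <- strsplit(gt, "[|/]")
  vapply(parts, function(p)
    length(p) == 2 && !any(p == ".") && p[1] == p[2], TRUE)
}

#' Apply phased variants to a reference for one haplotype
#'
#' Selects, for each applied record, the allele indexed by `hap_index` of
#' the phased genotype and substitutes it into the reference.  Unphased
#' heterozygous records are not applied (they are masked by
#' [mask_regions()]); homozygous records are applied regardless of phasing.
#' A mismatch between a record's REF allele and the reference sequence is
#' fatal (it indicates the wrong reference build).
#'
#' @param ref_seqs named character vector of reference sequences (or FASTA
#'   path)
#' @param calls a `PhasedCallset`
#' @param hap_index 0 or 1 (which side of `a|b` to apply)
#' @return list(seqs = constructed sequences, coord_map, applied = logical
#'   per call row)
#' @export
apply_phased_variants <- function(ref_seqs, calls, hap_index) {
  if (is.character(ref_seqs) && length(ref_seqs) == 1 &&
      file.exists(ref_seqs)) ref_seqs <- read_fasta(ref_seqs)
  stopifnot(hap_index %in% c(0L, 1L))
  vr <- calls[!calls$is_ref_block, , drop = FALSE]
  allele <- gt_allele(vr$gt, hap_index)
  hom <- gt_hom(vr$gt)
  apply_rec <- !is.na(allele) & (vr$phased | hom)
  out_seqs <- character(0)
  maps <- list()
  applied_key <- character(0)
  for (chrom in names(ref_seqs)) {
    src <- ref_seqs[[chrom]]
    rec <- vr[vr$chrom == chrom & apply_rec[seq_len(nrow(vr))], , drop = FALSE]
    al <- allele[vr$chrom == chrom & apply_rec]
    o <- order(rec$pos)
    rec <- rec[o, , drop = FALSE]; al <- al[o]
    # drop reference-allele picks (no sequence change) but keep for map
    sel_alt <- character(nrow(rec))
    for (i in seq_len(nrow(rec))) {
      alts <- strsplit(rec$alt[i], ",", fixed = TRUE)[[1]]
      sel_alt[i] <- if (al[i] == 0) rec$ref[i] else alts[al[i]]
    }
    # overlap guard
    if (nrow(rec) > 1) {
      span_end <- rec$pos + nchar(rec$ref) - 1L
      if (any(rec$pos[-1] <= cummax(span_end)[-nrow(rec)]))
        stop("overlapping variant records on ", chrom)
    }
    # REF check + build
    pieces <- character(0)
    map <- list()
    cur <- 0L; out_len <- 0L
    for (i in seq_len(nrow(rec))) {
      p0 <- rec$pos[i] - 1L
      ref_here <- substr(src, p0 + 1L, p0 + nchar(rec$ref[i]))
      if (!identical(ref_here, rec$ref[i]))
        stop("REF mismatch at ", chrom, ":", rec$pos[i], " (VCF '",
             rec$ref[i], "' vs reference '", ref_here,
             "'); wrong reference build?")
      if (p0 > cur) {
        pieces <- c(pieces, substr(src, cur + 1L, p0))
        map[[length(map) + 1]] <- data.frame(
          chrom = chrom, ref_start = cur, ref_end = p0,
          cons_start = out_len, cons_end = out_len + (p0 - cur),
          kind = "match", stringsAsFactors = FALSE)
        out_len <- out_len + (p0 - cur)
      }
      pieces <- c(pieces, sel_alt[i])
      map[[length(map) + 1]] <- data.frame(
        chrom = chrom, ref_start = p0, ref_end = p0 + nchar(rec$ref[i]),
        cons_start = out_len, cons_end = out_len + nchar(sel_alt[i]),
        kind = "variant", stringsAsFactors = FALSE)
      out_len <- out_len + nchar(sel_alt[i])
      cur <- p0 + nchar(rec$ref[i])
      applied_key <- c(applied_key, paste(chrom, rec$pos[i]))
    }
    if (cur < nchar(src)) {
      pieces <- c(pieces, substr(src, cur + 1L, nchar(src)))
      map[[length(map) + 1]] <- data.frame(
        chrom = chrom, ref_start = cur, ref_end = nchar(src),
        cons_start = out_len, cons_end = out_len + nchar(src) - cur,
        kind = "match", stringsAsFactors = FALSE)
    }
    out_seqs[chrom] <- paste(pieces, collapse = "")
    maps[[chrom]] <- do.call(rbind, map)
  }
  coord_map <- do.call(rbind, maps)
  rownames(coord_map) <- NULL
  applied <- rep(FALSE, nrow(calls))
  applied[!calls$is_ref_block] <-
    paste(vr$chrom, vr$pos) %in% applied_key & apply_rec
  list(seqs = out_seqs, coord_map = coord_map, applied = applied)
}

# map a reference position (0-based) to constructed coordinates
map_ref_to_cons <- function(coord_map, chrom, pos) {
  m <- coord_map[coord_map$chrom == chrom, , drop = FALSE]
  vapply(pos, function(p) {
    i <- which(m$ref_start <= p & p < m$ref_end)[1]
    if (is.na(i)) return(NA_integer_)
    if (m$kind[i] == "match") m$cons_start[i] + (p - m$ref_start[i])
    else m$cons_start[i]  # inside a variant: anchor to its start
  }, 1L)
}

#' Mask a constructed genome below a genotype-quality threshold
#'
#' Masks (replaces with N in the constructed sequence):
#' * `low_GQ`: applied variant loci with GQ < `gq_min`;
#' * `filtered`: unphased heterozygous loci (which were never applied);
#' * `uncalled`: when a gVCF is given, reference-block positions with
#'   GQ < `gq_min` plus positions absent from any block or variant record.
#' Masked intervals are reported in reference coordinates.
#'
#' @param construction result of [apply_phased_variants()]
#' @param calls the `PhasedCallset` (variant records)
#' @param gq_min GQ threshold (the conventional set is 10, 20, 30, 40)
#' @param gvcf optional `PhasedCallset` carrying gVCF reference blocks (may
#'   be the same object as `calls`)
#' @param ref_seqs named reference sequences (needed for `uncalled` bounds)
#' @param pad extra masked bases on each side of a masked locus
#' @return list of class `VCGResult`: seqs (masked), coord_map, masked
#'   (data.frame seq/start/end/reason, reference coordinates), gq_min
#' @export
mask_regions <- function(construction, calls, gq_min, gvcf = NULL,
                         ref_seqs = NULL, pad = 0L) {
  vr <- calls[!calls$is_ref_block, , drop = FALSE]
  applied <- construction$applied[!calls$is_ref_block]
  masked <- empty_iv(); masked$reason <- character(0)
  add_mask <- function(chrom, start, end, reason) {
    if (length(start) == 0) return()
    masked <<- rbind(masked, data.frame(
      seq = chrom, start = pmax(0L, start - pad), end = end + pad,
      reason = reason, stringsAsFactors = FALSE))
  }
  low <- applied & !is.na(vr$gq) & vr$gq < gq_min
  add_mask(vr$chrom[low], vr$pos[low] - 1L,
           vr$pos[low] - 1L + nchar(vr$ref[low]), "low_GQ")
  hetunph <- !applied & !vr$is_ref_block &
    !gt_hom(vr$gt) & !vr$phased
  add_mask(vr$chrom[hetunph], vr$pos[hetunph] - 1L,
           vr$pos[hetunph] - 1L + nchar(vr$ref[hetunph]), "filtered")
  if (!is.null(gvcf)) {
    stopifnot(!is.null(ref_seqs))
    blocks <- gvcf[gvcf$is_ref_block, , drop = FALSE]
    good <- blocks[!is.na(blocks$gq) & blocks$gq >= gq_min, , drop = FALSE]
    called <- rbind(
      data.frame(seq = good$chrom, start = good$pos - 1L, end = good$end,
                 stringsAsFactors = FALSE),
      data.frame(seq = vr$chrom, start = vr$pos - 1L,
                 end = vr$pos - 1L + nchar(vr$ref), stringsAsFactors = FALSE))
    whole <- data.frame(seq = names(ref_seqs), start = 0L,
                        end = nchar(ref_seqs), stringsAsFactors = FALSE)
    unc <- iv_setdiff(whole, called)
    if (nrow(unc) > 0) add_mask(unc$seq, unc$start, unc$end, "uncalled")
  }
  # apply masks to the constructed sequences
  seqs <- construction$seqs
  if (nrow(masked) > 0) {
    for (chrom in unique(masked$seq)) {
      mm <- masked[masked$seq == chrom, , drop = FALSE]
      ch <- strsplit(seqs[[chrom]], "")[[1]]
      for (i in seq_len(nrow(mm))) {
        c0 <- map_ref_to_cons(construction$coord_map, chrom, mm$start[i])
        c1 <- map_ref_to_cons(construction$coord_map, chrom, mm$end[i] - 1L)
        if (is.na(c0) || is.na(c1)) next
        # cover the full constructed span of the last mapped segment
        seg <- construction$coord_map[
          construction$coord_map$chrom == chrom &
            construction$coord_map$ref_start <= (mm$end[i] - 1L) &
            (mm$end[i] - 1L) < construction$coord_map$ref_end, , drop = FALSE]
        c1 <- if (nrow(seg) > 0 && seg$kind[1] == "variant")
          seg$cons_end[1] - 1L else c1
        ch[(c0 + 1):(c1 + 1)] <- "N"
      }
      seqs[chrom] <- paste(ch, collapse = "")
    }
  }
  structure(list(seqs = seqs, coord_map = construction$coord_map,
                 masked = masked, gq_min = gq_min),
            class = "VCGResult")
}

#' Build variant constructed genomes at one or more GQ thresholds
#'
#' @param ref_seqs named reference sequences or FASTA path
#' @param calls `PhasedCallset` (variant records; may include gVCF blocks)
#' @param gvcf optional separate gVCF callset for callability masking
#' @param thresholds GQ thresholds (default 10, 20, 30, 40)
#' @return named list (one `VCGResult` pair per threshold, each with
#'   `hap0`/`hap1` results)
#' @export
build_vcg <- function(ref_seqs, calls, gvcf = NULL,
                      thresholds = c(10L, 20L, 30L, 40L)) {
  stopifnot(length(thresholds) > 0)
  if (is.character(ref_seqs) && length(ref_seqs) == 1 &&
      file.exists(ref_seqs)) ref_seqs <- read_fasta(ref_seqs)
  cons <- lapply(0:1, function(h) apply_phased_variants(ref_seqs, calls, h))
  out <- lapply(thresholds, function(thr) {
    list(hap0 = mask_regions(cons[[1]], calls, thr, gvcf, ref_seqs),
         hap1 = mask_regions(cons[[2]], calls, thr, gvcf, ref_seqs))
  })
  names(out) <- paste0("gq", thresholds)
  out
}

# compose an alignment between a constructed sequence and the benchmark
# haplotype derived from the same reference: both are the reference plus a
# variant list, so walking the two sorted lists yields an exact CIGAR
# (query = constructed, target = benchmark haplotype).  "M" ops are emitted
# (not "=") so downstream comparison uses the real sequences.
compose_construction_alignment <- function(chrom, ref_len, applied_df,
                                           truth_df, query_name, target_name,
                                           target_hap, query_len, target_len) {
  ev <- merge(applied_df, truth_df, by = "pos", all = TRUE,
              suffixes = c("_q", "_t"))
  ev <- ev[order(ev$pos), , drop = FALSE]
  lens <- integer(0); ops <- character(0)
  push <- function(l, o) { if (l > 0) { lens <<- c(lens, l); ops <<- c(ops, o) } }
  cur <- 0L
  for (i in seq_len(nrow(ev))) {
    p0 <- ev$pos[i] - 1L
    ref_q <- ev$ref_q[i] %||% NA; ref_t <- ev$ref_t[i] %||% NA
    qa <- if (is.na(ev$allele_q[i] %||% NA)) NA else ev$allele_q[i]
    ta <- if (is.na(ev$allele_t[i] %||% NA)) NA else ev$allele_t[i]
    ref_allele <- if (!is.na(ref_q)) ref_q else ref_t
    if (is.na(qa)) qa <- ref_allele   # not applied: query carries reference
    if (is.na(ta)) ta <- ref_allele   # not in truth: target carries reference
    push(p0 - cur, "M")
    lq <- nchar(qa); lt <- nchar(ta)
    push(min(lq, lt), "M")
    if (lq > lt) push(lq - lt, "I")
    if (lt > lq) push(lt - lq, "D")
    cur <- p0 + nchar(ref_allele)
  }
  push(ref_len - cur, "M")
  data.frame(query = query_name, query_len = query_len, q_start = 0L,
             q_end = query_len, strand = "+", target_seq = target_name,
             t_start = 0L, t_end = target_len, cigar = cig_build(lens, ops),
             is_primary = TRUE, target_hap = target_hap,
             stringsAsFactors = FALSE)
}

#' Build variant constructed genomes and score them against the benchmark
#'
#' For each GQ threshold the constructed haplotypes are aligned to their
#' benchmark haplotypes by composing the applied variant list with the truth
#' variant list (both are expressed against the same reference, here the
#' fixture's hap1), discrepancies are cataloged with masked intervals
#' excluded, and coverage plus QV are reported.
#'
#' @param fix a `DiploidFixture` (provides the reference = hap1, the truth
#'   variants, and the benchmark)
#' @param calls `PhasedCallset` to evaluate (e.g. a degraded copy of the
#'   truth VCF)
#' @param gvcf optional gVCF callset
#' @param thresholds GQ thresholds
#' @param qv_cap Phred cap
#' @return data.frame (gq_min, masked_bp, aligned_bp, covered_fraction,
#'   n_discrepancies, qv, qv_capped) plus attribute "vcg" (the per-threshold
#'   `VCGResult`s)
#' @export
build_and_score <- function(fix, calls, gvcf = NULL,
                            thresholds = c(10L, 20L, 30L, 40L), qv_cap = 90) {
  stopifnot(inherits(fix, "DiploidFixture"))
  bench <- fix$bench
  ref_seqs <- bench$hap1
  vcgs <- build_vcg(ref_seqs, calls, gvcf, thresholds)
  vr <- calls[!calls$is_ref_block, , drop = FALSE]
  rows <- list()
  for (ti in seq_along(thresholds)) {
    thr <- thresholds[ti]
    res <- vcgs[[ti]]
    segs <- list(); seqs_all <- character(0); excl <- empty_iv()
    for (h in 0:1) {
      vcg <- if (h == 0) res$hap0 else res$hap1
      construction_applied <- apply_phased_variants(ref_seqs, calls, h)
      app <- vr[construction_applied$applied[!calls$is_ref_block], ,
                drop = FALSE]
      for (chrom in names(ref_seqs)) {
        target_name <- if (h == 0) chrom else
          bench$pairing$hap2[match(chrom, bench$pairing$hap1)]
        if (is.na(target_name)) next
        qname <- paste0(chrom, "_vcg_hap", h)
        appc <- app[app$chrom == chrom, , drop = FALSE]
        applied_df <- data.frame(pos = appc$pos, ref = appc$ref,
                                 allele = vapply(seq_len(nrow(appc)),
                                                 function(i) {
            a <- gt_allele(appc$gt[i], h)
            if (a == 0) appc$ref[i] else
              strsplit(appc$alt[i], ",")[[1]][a]
          }, ""), stringsAsFactors = FALSE)
        names(applied_df) <- c("pos", "ref_q", "allele_q")
        tv <- fix$truth_variants[fix$truth_variants$chrom == chrom, ,
                                 drop = FALSE]
        truth_df <- if (h == 0)
          data.frame(pos = integer(0), ref_t = character(0),
                     allele_t = character(0), stringsAsFactors = FALSE)
        else data.frame(pos = tv$pos, ref_t = tv$ref, allele_t = tv$alt,
                        stringsAsFactors = FALSE)
        qseq <- vcg[[paste0("hap", h)]]$seqs[[chrom]] %||%
          vcg$seqs[[chrom]]
        cons_seq <- if (h == 0) res$hap0$seqs[[chrom]] else
          res$hap1$seqs[[chrom]]
        seqs_all[qname] <- cons_seq
        tlen <- nchar(bench_seq(bench, target_name))
        segs[[qname]] <- compose_construction_alignment(
          chrom, nchar(ref_seqs[[chrom]]), applied_df, truth_df, qname,
          target_name, if (h == 0) "hap1" else "hap2",
          nchar(cons_seq), tlen)
      }
      # masked reference intervals -> benchmark coordinates
      vcg_obj <- if (h == 0) res$hap0 else res$hap1
      mk <- vcg_obj$masked
      if (nrow(mk) > 0) {
        tv_all <- fix$truth_variants
        proj <- function(chrom, p) {
          if (h == 0) return(p)
          hap1_to_hap2_pos(tv_all, chrom, p)
        }
        for (i in seq_len(nrow(mk))) {
          chrom <- mk$seq[i]
          tname <- if (h == 0) chrom else
            bench$pairing$hap2[match(chrom, bench$pairing$hap1)]
          if (is.na(tname)) next
          excl <- rbind(excl, data.frame(
            seq = tname, start = proj(chrom, mk$start[i]),
            end = proj(chrom, mk$end[i]), stringsAsFactors = FALSE))
        }
      }
    }
    segs <- do.call(rbind, segs)
    cat_res <- catalog_discrepancies(segs, bench, hets = NULL,
                                     assembly_seqs = seqs_all)
    ev <- list(catalog = cat_res$catalog, aligned_iv = cat_res$aligned_iv,
               blocks = segs, run_quality = NULL, qv_cap = qv_cap)
    class(ev) <- "AssemblyEval"
    strat <- stratify(ev, bench, exclude = if (nrow(excl) > 0) excl else NULL,
                      qv_cap = qv_cap)
    q <- strat$qv
    rows[[ti]] <- data.frame(
      gq_min = thr, masked_bp = iv_width(excl),
      aligned_bp = strat$aligned_bp,
      covered_fraction = strat$aligned_bp / bench$total_diploid_bp,
      n_discrepancies = attr(q, "n_discrepancies") %||% NA,
      qv = as.numeric(q), qv_capped = isTRUE(attr(q, "capped")))
  }
  out <- do.call(rbind, rows)
  attr(out, "vcg") <- vcgs
  out
}
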