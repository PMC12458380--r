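# Assembly evaluation against the diploid benchmark.

#' Read assembly-to-benchmark alignments
#'
#' Accepts PAF (with `cg:Z:` CIGAR tags) or BAM/SAM.  Target haplotype is
#' resolved from the target sequence name via the benchmark.
#'
#' @param path PAF, BAM or SAM file
#' @param bench DiploidBenchmark used to resolve target haplotypes
#' @param min_len drop segments whose target span is below this
#' @param primary_only drop secondary/supplementary records
#' @return data.frame of alignment segments (query, query_len, q_start,
#'   q_end, strand, target_seq, target_hap, t_start, t_end, cigar,
#'   is_primary)
#' @export
read_alignments <- function(path, bench = NULL, min_len = 0L,
                            primary_only = TRUE) {
  ext <- tolower(tools::file_ext(path))
  segs <- if (ext == "paf") read_paf(path) else read_aln_bam(path, ext)
  if (!is.null(bench)) {
    hap <- bench_hap_of(bench, segs$target_seq)
    if (any(is.na(hap)))
      stop("alignment target not in benchmark: ",
           segs$target_seq[which(is.na(hap))[1]])
    segs$target_hap <- hap
  }
  if (primary_only) segs <- segs[segs$is_primary, , drop = FALSE]
  segs <- segs[(segs$t_end - segs$t_start) >= min_len, , drop = FALSE]
  rownames(segs) <- NULL
  segs
}

read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_segments())
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 12) stop("malformed PAF line: ", substr(l, 1, 60))
    tags <- f[-(1:12)]
    cg <- tags[startsWith(tags, "cg:Z:")]
    if (length(cg) == 0)
      stop("PAF record lacks cg:Z: CIGAR tag (re-run the aligner with ",
           "--cs or -c to emit CIGARs): ", f[1], " -> ", f[6])
    tp <- tags[startsWith(tags, "tp:A:")]
    data.frame(query = f[1], query_len = as.integer(f[2]),
               q_start = as.integer(f[3]), q_end = as.integer(f[4]),
               strand = f[5], target_seq = f[6],
               t_start = as.integer(f[8]), t_end = as.integer(f[9]),
               cigar = sub("^cg:Z:", "", cg[1]),
               is_primary = length(tp) == 0 || substr(tp[1], 6, 6) == "P",
               stringsAsFactors = FALSE)
  })
  segs <- do.call(rbind, out)
  segs$target_hap <- NA_character_
  validate_segments(segs)
}

read_aln_bam <- function(path, ext) {
  if (ext == "sam") path <- Rsamtools::asBam(path, overwrite = TRUE,
                                             indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  keep <- !is.na(b$pos)
  flag <- b$flag[keep]
  cig <- b$cigar[keep]
  opsl <- lapply(cig, cig_ops)
  qlen <- vapply(opsl, cig_qlen, 0)
  tlen <- vapply(opsl, cig_tlen, 0)
  lead_clip <- vapply(opsl, function(o) {
    i <- which(!o$op %in% c("S", "H"))[1]
    if (is.na(i) || i == 1) 0L else sum(o$len[seq_len(i - 1)])
  }, 0L)
  segs <- data.frame(
    query = as.character(b$qname[keep]), query_len = qlen,
    q_start = lead_clip, q_end = qlen - vapply(opsl, function(o) {
      i <- which(!o$op %in% c("S", "H"))
      if (length(i) == 0 || max(i) == nrow(o)) 0L
      else sum(o$len[(max(i) + 1L):nrow(o)])
    }, 0L),
    strand = ifelse(bitwAnd(flag, 16L) > 0, "-", "+"),
    target_seq = as.character(b$rname[keep]),
    t_start = b$pos[keep] - 1L, t_end = b$pos[keep] - 1L + tlen,
    cigar = cig,
    is_primary = bitwAnd(flag, 256L) == 0 & bitwAnd(flag, 2048L) == 0,
    stringsAsFactors = FALSE)
  segs$target_hap <- NA_character_
  validate_segments(segs)
}

empty_segments <- function() {
  data.frame(query = character(), query_len = integer(), q_start = integer(),
             q_end = integer(), strand = character(), target_seq = character(),
             t_start = integer(), t_end = integer(), cigar = character(),
             is_primary = logical(), target_hap = character(),
             stringsAsFactors = FALSE)
}

validate_segments <- function(segs) {
  for (i in seq_len(nrow(segs))) {
    ops <- cig_ops(segs$cigar[i])
    ops <- ops[!ops$op %in% c("S", "H"), , drop = FALSE]
    ql <- sum(ops$len[ops$op %in% c("M", "=", "X", "I")])
    tl <- sum(ops$len[ops$op %in% c("M", "=", "X", "D", "N")])
    if (ql != segs$q_end[i] - segs$q_start[i])
      stop("CIGAR query length mismatch for ", segs$query[i])
    if (tl != segs$t_end[i] - segs$t_start[i])
      stop("CIGAR target length mismatch for ", segs$query[i])
  }
  segs
}

# oriented query sequence and oriented q_start for a segment (PAF semantics:
# for '-' strand the CIGAR walks the reverse-complemented query)
seg_oriented_query <- function(seg, assembly_seqs) {
  qseq <- assembly_seqs[[seg$query]]
  if (is.null(qseq)) stop("assembly sequence missing: ", seg$query)
  if (seg$strand == "-") {
    list(seq = revcomp(qseq), q0 = nchar(qseq) - seg$q_end)
  } else {
    list(seq = qseq, q0 = seg$q_start)
  }
}

# per-segment op table with cumulative target/query offsets
seg_op_table <- function(seg) {
  ops <- cig_ops(seg$cigar)
  ops <- ops[!ops$op %in% c("H"), , drop = FALSE]
  t_adv <- ifelse(ops$op %in% c("M", "=", "X", "D", "N"), ops$len, 0L)
  q_adv <- ifelse(ops$op %in% c("M", "=", "X", "I", "S"), ops$len, 0L)
  ops$tstart <- seg$t_start + c(0L, cumsum(head(t_adv, -1)))
  ops$qstart <- c(0L, cumsum(head(q_adv, -1)))  # offset from oriented q0
  ops
}

#' Split alignments at large indels for NGAx
#'
#' Each segment is split at every single insertion or deletion operation of
#' length at least `max_indel` (inclusive threshold).
#'
#' @param segments alignment segments
#' @param max_indel split threshold in bp (default 10000)
#' @return alignment blocks with the same columns as the input
#' @export
split_for_ngax <- function(segments, max_indel = 10000L) {
  out <- lapply(seq_len(nrow(segments)), function(i) {
    seg <- segments[i, ]
    ops <- seg_op_table(seg)
    big <- which(ops$op %in% c("I", "D") & ops$len >= max_indel)
    if (length(big) == 0) return(seg)
    bounds <- c(0L, big, nrow(ops) + 1L)
    pieces <- list()
    for (j in seq_len(length(big) + 1)) {
      lo <- bounds[j] + 1L; hi <- bounds[j + 1] - 1L
      if (lo > hi) next
      sub <- ops[lo:hi, , drop = FALSE]
      cons_t <- sub$op %in% c("M", "=", "X", "D", "N")
      cons_q <- sub$op %in% c("M", "=", "X", "I")
      if (!any(cons_t) && !any(cons_q)) next
      p <- seg
      p$t_start <- sub$tstart[1]
      p$t_end <- sub$tstart[nrow(sub)] +
        ifelse(cons_t[nrow(sub)], sub$len[nrow(sub)], 0L)
      oq0 <- sub$qstart[1]
      oq1 <- sub$qstart[nrow(sub)] +
        ifelse(cons_q[nrow(sub)], sub$len[nrow(sub)], 0L)
      if (seg$strand == "-") {
        q0_or <- seg$query_len - seg$q_end
        p$q_start <- seg$query_len - (q0_or + oq1)
        p$q_end <- seg$query_len - (q0_or + oq0)
      } else {
        p$q_start <- seg$q_start + oq0
        p$q_end <- seg$q_start + oq1
      }
      p$cigar <- cig_build(sub$len, sub$op)
      pieces[[length(pieces) + 1]] <- p
    }
    do.call(rbind, pieces)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' NGAx curve from alignment blocks
#'
#' Blocks are sorted by descending target-span length; point i of the curve
#' is (cumulative target bp / reference_bp, length of block i).  The
#' reference length defaults to the total non-N diploid benchmark length.
#'
#' @param blocks alignment blocks (from [split_for_ngax()])
#' @param bench DiploidBenchmark (for the reference length)
#' @param reference_bp override the denominator
#' @return data.frame (rank, block_length, cum_bp, cum_fraction) of class
#'   `NgaxCurve` with attribute `reference_bp`
#' @export
ngax <- function(blocks, bench = NULL, reference_bp = NULL) {
  if (is.null(reference_bp)) {
    stopifnot(!is.null(bench))
    reference_bp <- bench$total_diploid_bp
  }
  len <- sort(as.numeric(blocks$t_end - blocks$t_start), decreasing = TRUE)
  cum <- cumsum(len)
  curve <- data.frame(rank = seq_along(len), block_length = len,
                      cum_bp = cum, cum_fraction = cum / reference_bp)
  attr(curve, "reference_bp") <- reference_bp
  class(curve) <- c("NgaxCurve", "data.frame")
  curve
}

#' NGA value at a coverage percentage
#' @param curve an `NgaxCurve`
#' @param x percentage of the reference (NGA50: x = 50)
#' @return block length at the first point whose cumulative fraction reaches
#'   x%, or NA if the curve never reaches it
#' @export
nga <- function(curve, x = 50) {
  i <- which(curve$cum_fraction >= x / 100)[1]
  if (is.na(i)) NA_real_ else curve$block_length[i]
}

TRANSITIONS <- c("A>G", "G>A", "C>T", "T>C")

#' Catalog base-level discrepancies between assembly and benchmark
#'
#' Walks every alignment segment and records each mismatch and indel in
#' benchmark coordinates.  A substitution at a heterozygous SNV site whose
#' assembly allele equals the alternate haplotype's allele is classified as
#' `phase_consistent` rather than a substitution (het indel sites are not
#' reclassified).  Benchmark N positions never host discrepancies.
#' Overlapping alignments are resolved by keeping the record from the longer
#' alignment (ties by query name), and aligned bases are counted once per
#' haplotype position.
#'
#' @param segments alignment segments with resolved `target_hap`
#' @param bench DiploidBenchmark
#' @param hets het catalog from [build_het_catalog()] (NULL disables phase
#'   classification)
#' @param assembly_seqs named character vector of assembly contigs
#' @return list(catalog, aligned_bp, aligned_iv); catalog columns:
#'   target_hap, target_seq, t_pos, klass, sub_type, ti_tv, length, query,
#'   q_pos
#' @export
catalog_discrepancies <- function(segments, bench, hets = NULL,
                                  assembly_seqs) {
  het_key <- character(0); het_other <- character(0)
  if (!is.null(hets) && nrow(hets) > 0) {
    snv <- hets[hets$type == "snv", , drop = FALSE]
    het_key <- paste(snv$seq, snv$pos)
    het_other <- snv$allele_other
  }
  ord <- order(-(segments$t_end - segments$t_start), segments$query)
  segments <- segments[ord, , drop = FALSE]
  recs <- list()
  for (i in seq_len(nrow(segments))) {
    seg <- segments[i, ]
    tseq <- bench_seq(bench, seg$target_seq)
    oq <- seg_oriented_query(seg, assembly_seqs)
    ops <- seg_op_table(seg)
    for (j in seq_len(nrow(ops))) {
      op <- ops$op[j]; len <- ops$len[j]
      ti <- ops$tstart[j]; qi <- oq$q0 + ops$qstart[j]
      if (op %in% c("M", "X")) {
        tb <- utf8ToInt(substr(tseq, ti + 1, ti + len))
        qb <- utf8ToInt(substr(oq$seq, qi + 1, qi + len))
        d <- which(tb != qb)
        if (length(d) > 0) {
          rb <- vapply(tb[d], intToUtf8, ""); ab <- vapply(qb[d], intToUtf8, "")
          ok <- rb %in% c("A", "C", "G", "T") & ab %in% c("A", "C", "G", "T")
          d <- d[ok]; rb <- rb[ok]; ab <- ab[ok]
          if (length(d) > 0) {
            key <- paste(seg$target_seq, ti + d - 1L)
            m <- match(key, het_key)
            phase <- !is.na(m) & het_other[pmax(m, 1)] == ab
            phase[is.na(m)] <- FALSE
            st <- paste0(rb, ">", ab)
            recs[[length(recs) + 1]] <- data.frame(
              target_hap = seg$target_hap, target_seq = seg$target_seq,
              t_pos = ti + d - 1L,
              klass = ifelse(phase, "phase_consistent", "substitution"),
              sub_type = ifelse(phase, NA, st),
              ti_tv = ifelse(phase, NA,
                             ifelse(st %in% TRANSITIONS, "Ti", "Tv")),
              length = 1L, query = seg$query, q_pos = qi + d - 1L,
              stringsAsFactors = FALSE)
          }
        }
      } else if (op == "I") {
        recs[[length(recs) + 1]] <- data.frame(
          target_hap = seg$target_hap, target_seq = seg$target_seq,
          t_pos = ti - 1L, klass = "insertion", sub_type = NA, ti_tv = NA,
          length = len, query = seg$query, q_pos = qi,
          stringsAsFactors = FALSE)
      } else if (op == "D") {
        recs[[length(recs) + 1]] <- data.frame(
          target_hap = seg$target_hap, target_seq = seg$target_seq,
          t_pos = ti, klass = "deletion", sub_type = NA, ti_tv = NA,
          length = len, query = seg$query, q_pos = qi - 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  catalog <- if (length(recs)) do.call(rbind, recs) else
    data.frame(target_hap = character(), target_seq = character(),
               t_pos = integer(), klass = character(), sub_type = character(),
               ti_tv = character(), length = integer(), query = character(),
               q_pos = integer(), stringsAsFactors = FALSE)
  # overlap resolution: first record (from the longest alignment) wins
  if (nrow(catalog) > 0) {
    dkey <- paste(catalog$target_seq, catalog$t_pos, catalog$klass)
    catalog <- catalog[!duplicated(dkey), , drop = FALSE]
    catalog <- catalog[order(catalog$target_hap, catalog$target_seq,
                             catalog$t_pos), , drop = FALSE]
    rownames(catalog) <- NULL
  }
  aligned_iv <- iv_reduce(data.frame(seq = segments$target_seq,
                                     start = segments$t_start,
                                     end = segments$t_end,
                                     stringsAsFactors = FALSE))
  aligned_iv <- iv_intersect(aligned_iv, bench_non_n_iv(bench))
  list(catalog = catalog, aligned_bp = iv_width(aligned_iv),
       aligned_iv = aligned_iv)
}

#' Alignment-based Phred quality value
#'
#' QV = -10*log10(#discrepancies / #aligned bases).  By default every indel
#' counts as one discrepancy regardless of length (`per_bp = TRUE` counts
#' indel bases instead); phase-consistent records are excluded.  Zero
#' discrepancies are reported as the cap with attribute `capped = TRUE`.
#'
#' @param catalog discrepancy catalog (or the list from
#'   [catalog_discrepancies()])
#' @param aligned_bp aligned base denominator (taken from the list if given)
#' @param per_bp count indel bases instead of events
#' @param cap reported lower bound for an error-free input
#' @return Phred value with attributes "capped" and "n_discrepancies"
#' @export
qv <- function(catalog, aligned_bp = NULL, per_bp = FALSE, cap = 90) {
  if (is.list(catalog) && !is.data.frame(catalog)) {
    if (is.null(aligned_bp)) aligned_bp <- catalog$aligned_bp
    catalog <- catalog$catalog
  }
  stopifnot(aligned_bp > 0)
  n <- discrepancy_count(catalog, per_bp)
  out <- phred(n, aligned_bp, cap = cap)
  attr(out, "n_discrepancies") <- n
  out
}

discrepancy_count <- function(catalog, per_bp = FALSE) {
  sub <- sum(catalog$klass == "substitution")
  ind <- catalog$klass %in% c("insertion", "deletion")
  sub + if (per_bp) sum(catalog$length[ind]) else sum(ind)
}

#' Mononucleotide run accuracy of an assembly
#'
#' A benchmark run is *aligned* when fully spanned (with at least one
#' anchored base on each side) by a single alignment block, and *erroneous*
#' when the assembly sequence between the anchors differs from the benchmark
#' run (wrong length or any substitution).  Reported per benchmark run
#' length as -10*log10(#erroneous / #aligned); zero-error lengths are capped
#' bounds.
#'
#' @param segments alignment blocks
#' @param bench DiploidBenchmark
#' @param runs RunCatalog (restricted internally to unit_len == 1)
#' @param assembly_seqs named character vector of contigs
#' @param cap Phred cap for zero-error rows
#' @return list(table = per-length data.frame, detail = per-run data.frame)
#' @export
mononuc_run_quality <- function(segments, bench, runs, assembly_seqs,
                                cap = 90) {
  runs <- as.data.frame(runs)
  runs <- runs[runs$unit_len == 1, , drop = FALSE]
  detail <- runs[, c("seq", "start", "end", "run_len_bp")]
  detail$aligned <- FALSE
  detail$erroneous <- FALSE
  for (i in seq_len(nrow(segments))) {
    seg <- segments[i, ]
    cand <- which(detail$seq == seg$target_seq &
                    detail$start - 1L >= seg$t_start &
                    detail$end + 1L <= seg$t_end &
                    !detail$aligned)
    if (length(cand) == 0) next
    detail$aligned[cand] <- TRUE
    ops <- seg_op_table(seg)
    # fast path: a run whose neighbourhood only touches "=" ops is correct
    ev <- ops[ops$op %in% c("M", "X", "I", "D", "N"), , drop = FALSE]
    if (nrow(ev) == 0) next
    ev_iv <- iv_reduce(data.frame(
      seq = "x", start = ev$tstart - 1L,
      end = ev$tstart + ifelse(ev$op %in% c("M", "X", "D", "N"),
                               ev$len, 0L) + 1L))
    s <- detail$start[cand]; e <- detail$end[cand]
    j <- findInterval(s - 1L, ev_iv$start)
    near <- (j >= 1 & ifelse(j >= 1, ev_iv$end[pmax(j, 1)], 0L) > s - 1L) |
      (j < nrow(ev_iv) & ev_iv$start[pmin(j + 1L, nrow(ev_iv))] < e + 1L)
    slow <- cand[near]
    if (length(slow) == 0) next
    oq <- seg_oriented_query(seg, assembly_seqs)
    tseq <- bench_seq(bench, seg$target_seq)
    proj <- function(t) { # query offset of target pos t, NA if not aligned
      j <- findInterval(t, ops$tstart)
      while (j >= 1 && !(ops$op[j] %in% c("M", "=", "X", "D", "N") &&
                         t < ops$tstart[j] + ops$len[j])) j <- j - 1
      if (j < 1) return(NA_integer_)
      if (!ops$op[j] %in% c("M", "=", "X")) return(NA_integer_)
      oq$q0 + ops$qstart[j] + (t - ops$tstart[j])
    }
    for (ri in slow) {
      s <- detail$start[ri]; e <- detail$end[ri]
      qa <- proj(s - 1L); qb <- proj(e)
      if (is.na(qa) || is.na(qb)) { detail$erroneous[ri] <- TRUE; next }
      got <- substr(oq$seq, qa + 2L, qb)   # query bases strictly between anchors
      want <- substr(tseq, s + 1L, e)
      detail$erroneous[ri] <- !identical(got, want)
    }
  }
  list(table = run_quality_table(detail, cap), detail = detail)
}

run_quality_table <- function(detail, cap = 90) {
  d <- detail[detail$aligned, , drop = FALSE]
  if (nrow(d) == 0)
    return(data.frame(run_len = integer(), aligned = integer(),
                      erroneous = integer(), q = numeric(), capped = logical()))
  tab <- do.call(rbind, lapply(split(d, d$run_len_bp), function(x) {
    q <- phred(sum(x$erroneous), nrow(x), cap = cap)
    data.frame(run_len = x$run_len_bp[1], aligned = nrow(x),
               erroneous = sum(x$erroneous), q = as.numeric(q),
               capped = isTRUE(attr(q, "capped")))
  }))
  tab <- tab[order(tab$run_len), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Benchmark bases uncovered by primary alignments
#'
#' @param segments alignment segments (already filtered to primary)
#' @param bench DiploidBenchmark
#' @return list(total, bed) where bed is the per-haplotype complement of the
#'   aligned target intervals intersected with non-N positions
#' @export
uncovered_bases <- function(segments, bench) {
  non_n <- bench_non_n_iv(bench)
  aligned <- iv_reduce(data.frame(seq = segments$target_seq,
                                  start = segments$t_start,
                                  end = segments$t_end,
                                  stringsAsFactors = FALSE))
  unc <- iv_setdiff(non_n, aligned)
  list(total = iv_width(unc), bed = unc)
}

#' Evaluate a test assembly end to end
#'
#' Convenience wrapper: reads alignments, splits for NGAx, catalogs
#' discrepancies, computes QV, run accuracy, uncovered bases, and (when a
#' MarkerSet is given) phase blocks and switch statistics.
#'
#' @param bench DiploidBenchmark
#' @param alignments path or segments data.frame
#' @param assembly_seqs named character vector of contigs (or FASTA path)
#' @param hets het catalog (optional)
#' @param runs RunCatalog (optional; skips run accuracy if NULL)
#' @param markers MarkerSet (optional; skips phasing if NULL)
#' @param params HmmParams for phasing
#' @param split_indel NGAx split threshold
#' @param qv_cap Phred cap
#' @param exclude optional interval set excluded from all metrics (e.g. the
#'   benchmark's low-confidence regions)
#' @return list with segments, blocks, ngax, catalog, aligned_bp, qv,
#'   uncovered, run_quality, phase (class `AssemblyEval`)
#' @export
evaluate_assembly <- function(bench, alignments, assembly_seqs, hets = NULL,
                              runs = NULL, markers = NULL,
                              params = hmm_params(), split_indel = 10000L,
                              qv_cap = 90, exclude = NULL) {
  if (is.character(assembly_seqs) && length(assembly_seqs) == 1 &&
      file.exists(assembly_seqs)) assembly_seqs <- read_fasta(assembly_seqs)
  segs <- if (is.character(alignments)) read_alignments(alignments, bench)
          else alignments
  blocks <- split_for_ngax(segs, max_indel = split_indel)
  cat_res <- catalog_discrepancies(segs, bench, hets, assembly_seqs)
  rq <- if (!is.null(runs))
    mononuc_run_quality(blocks, bench, runs, assembly_seqs, cap = qv_cap)
  phase <- NULL
  if (!is.null(markers)) {
    pb <- phase_assembly(assembly_seqs, markers, params)
    phase <- list(blocks = pb,
                  stats = switch_stats(pb, max(cat_res$aligned_bp, 1)))
  }
  res <- list(segments = segs, blocks = blocks,
              ngax = ngax(blocks, bench),
              catalog = cat_res$catalog, aligned_bp = cat_res$aligned_bp,
              aligned_iv = cat_res$aligned_iv,
              qv = qv(cat_res, cap = qv_cap),
              uncovered = uncovered_bases(segs, bench),
              run_quality = if (!is.null(runs)) rq,
              phase = phase, qv_cap = qv_cap)
  class(res) <- "AssemblyEval"
  if (!is.null(exclude))
    res$stratified_excl <- stratify(res, bench, exclude = exclude)
  res
}

#' @export
print.AssemblyEval <- function(x, ...) {
  cat("AssemblyEval:", nrow(x$segments), "alignments; aligned_bp =",
      format(x$aligned_bp, big.mark = ","), "\n")
  cat("  QV:", if (isTRUE(attr(x$qv, "capped"))) ">=" else "",
      round(as.numeric(x$qv), 2),
      "(", attr(x$qv, "n_discrepancies"), "discrepancies )\n")
  cat("  NGA50:", format(nga(x$ngax, 50), big.mark = ","),
      "; uncovered non-N bp:", format(x$uncovered$total, big.mark = ","), "\n")
  if (!is.null(x$phase))
    cat("  phase switches:", x$phase$stats$n_switches, "\n")
  invisible(x)
}

#' Region-stratified recomputation of assembly metrics
#'
#' Restricts the discrepancy catalog, aligned bases, run observations, NGAx
#' and uncovered bases to (union of `include`) minus (union of `exclude`).
#' Point-anchored quantities (discrepancies, run observations via the run
#' start) are assigned to a stratum by position, so counts over a partition
#' of the genome sum exactly to the unstratified totals; interval quantities
#' (aligned/uncovered bp) are intersected.
#'
#' @param result an `AssemblyEval`
#' @param bench DiploidBenchmark
#' @param include interval set (data.frame seq/start/end or BED path); NULL =
#'   whole genome
#' @param exclude interval set removed from the stratum
#' @param qv_cap Phred cap
#' @return list of stratified metrics; `undefined = TRUE` when the stratum is
#'   empty
#' @export
stratify <- function(result, bench, include = NULL, exclude = NULL,
                     qv_cap = result$qv_cap %||% 90) {
  as_iv <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.character(x)) x <- read_bed(x)
    iv_reduce(x)
  }
  whole <- data.frame(seq = c(names(bench$hap1), names(bench$hap2)),
                      start = 0L,
                      end = c(nchar(bench$hap1), nchar(bench$hap2)),
                      stringsAsFactors = FALSE)
  stratum <- as_iv(include) %||% whole
  if (!is.null(exclude)) stratum <- iv_setdiff(stratum, as_iv(exclude))
  if (iv_width(stratum) == 0) {
    return(list(undefined = TRUE))
  }
  cat0 <- result$catalog
  keep <- iv_contains_points(stratum, cat0$target_seq, cat0$t_pos)
  cat1 <- cat0[keep, , drop = FALSE]
  aligned_iv <- iv_intersect(result$aligned_iv, stratum)
  aligned_bp <- iv_width(aligned_iv)
  non_n_in <- iv_width(iv_intersect(bench_non_n_iv(bench), stratum))
  counts <- c(substitution = sum(cat1$klass == "substitution"),
              insertion = sum(cat1$klass == "insertion"),
              deletion = sum(cat1$klass == "deletion"),
              phase_consistent = sum(cat1$klass == "phase_consistent"),
              ti = sum(cat1$ti_tv %in% "Ti"), tv = sum(cat1$ti_tv %in% "Tv"))
  run_tab <- NULL
  if (!is.null(result$run_quality)) {
    det <- result$run_quality$detail
    keep_r <- iv_contains_points(stratum, det$seq, det$start)
    run_tab <- run_quality_table(det[keep_r, , drop = FALSE], cap = qv_cap)
  }
  blocks_iv <- iv_reduce(data.frame(seq = result$blocks$target_seq,
                                    start = result$blocks$t_start,
                                    end = result$blocks$t_end,
                                    stringsAsFactors = FALSE))
  ng_curve <- NULL
  strat_blocks <- iv_intersect(blocks_iv, stratum)
  if (nrow(strat_blocks) > 0)
    ng_curve <- ngax(data.frame(t_start = strat_blocks$start,
                                t_end = strat_blocks$end),
                     reference_bp = non_n_in)
  list(undefined = FALSE, counts = counts, aligned_bp = aligned_bp,
       qv = if (aligned_bp > 0) qv(cat1, aligned_bp, cap = qv_cap) else NA,
       rates_per_mb = if (aligned_bp > 0) counts / (aligned_bp / 1e6) else NA,
       run_quality = run_tab, ngax = ng_curve,
       uncovered = non_n_in - aligned_bp, stratum_bp = iv_width(stratum))
}
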