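# Read simulation with parameterized error / quality / coverage models.

#' Specification for simulated sequencing reads
#'
#' @param depth mean coverage per haplotype sequence
#' @param read_len_mean,read_len_cv lognormal read length model
#' @param sub_rate,ins_rate,del_rate per-bp error rates (sub_rate is ignored
#'   under the truthful/miscalibrated quality models, where substitution
#'   errors are drawn from the per-base quality)
#' @param q_model "fixed" (constant reported quality matching sub_rate),
#'   "truthful" (per-base qualities drawn from `q_levels`, substitution
#'   probability exactly 10^(-q/10)), or "miscalibrated" (truthful errors,
#'   but reported quality inflated by `miscal_offset` for bases above
#'   `miscal_above`)
#' @param q_levels,q_probs support of the per-base quality distribution
#' @param miscal_offset,miscal_above miscalibration parameters
#' @param hp_noise NULL or list(min_len, p0): homopolymer runs of at least
#'   min_len bp inside a read get a +-1 length error with probability
#'   min(0.5, p0 * (run_len - min_len + 1)) (error grows with run length)
#' @param gc_bias NULL or list(threshold, slope): logistic start-site
#'   dropout, acceptance probability 1/(1+exp(slope*(gc - threshold))) with
#'   gc the %GC of the 500 bp window at the read start
#' @param crossmap_frac fraction of reads aligned to the homologous sequence
#'   of the *other* haplotype (het alleles appear as mismatches; requires
#'   truth variants)
#' @param clip_prob,clip_len_mean soft-clip model (random extra bases)
#' @param seed RNG seed
#' @return list of class `ReadSpec`
#' @export
read_spec <- function(depth = 30, read_len_mean = 10000, read_len_cv = 0.2,
                      sub_rate = 1e-3, ins_rate = 5e-4, del_rate = 5e-4,
                      q_model = c("fixed", "truthful", "miscalibrated"),
                      q_levels = c(20L, 25L, 30L, 35L, 40L),
                      q_probs = c(0.05, 0.15, 0.3, 0.3, 0.2),
                      miscal_offset = 5L, miscal_above = 30L,
                      hp_noise = NULL, gc_bias = NULL, crossmap_frac = 0,
                      clip_prob = 0, clip_len_mean = 100L, seed = 1L) {
  q_model <- match.arg(q_model)
  structure(as.list(environment()), class = "ReadSpec")
}

#' Simulate reads aligned to the benchmark
#'
#' Reads are drawn from every benchmark haplotype sequence with
#' Poisson-uniform start positions (optionally modulated by the GC-bias
#' curve), carry injected substitution/indel/homopolymer errors, and are
#' emitted as a coordinate-sorted, indexed BAM whose records hold the truth
#' CIGARs (self-alignment; no external aligner).  Per-read truth is
#' returned.
#'
#' @param fix a `DiploidFixture` (or a `DiploidBenchmark` when
#'   `crossmap_frac = 0`)
#' @param spec a [read_spec()]
#' @param out_prefix path prefix for the BAM (default tempfile)
#' @param runs RunCatalog of the benchmark (computed internally when NULL
#'   and hp_noise is set)
#' @return list(bam, truth = per-read data.frame, spec)
#' @export
simulate_reads <- function(fix, spec = read_spec(), out_prefix = tempfile(),
                           runs = NULL) {
  bench <- if (inherits(fix, "DiploidFixture")) fix$bench else fix
  truth_vars <- if (inherits(fix, "DiploidFixture")) fix$truth_variants else NULL
  if (spec$crossmap_frac > 0 && is.null(truth_vars))
    stop("crossmap_frac > 0 requires a DiploidFixture with truth variants")
  if (!is.null(spec$hp_noise) && is.null(runs))
    runs <- annotate_runs(bench, unit_sizes = 1L)
  stopifnot(spec$depth >= 1)

  seqs <- c(bench$hap1, bench$hap2)
  haps <- c(rep("hap1", length(bench$hap1)), rep("hap2", length(bench$hap2)))
  sam_lines <- list()
  truth_rows <- list()
  qmap <- NULL
  for (si in seq_along(seqs)) {
    nm <- names(seqs)[si]
    res <- with_seed(substream_seed(spec$seed, paste0("reads_", nm)), {
      sim_reads_one_seq(nm, haps[si], seqs[[nm]], bench, truth_vars, spec,
                        runs, sprintf("r%02d", si))
    })
    sam_lines[[nm]] <- res$sam
    truth_rows[[nm]] <- res$truth
  }
  sam_path <- paste0(out_prefix, ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(seqs), "\tLN:", nchar(seqs)))
  writeLines(c(hdr, unlist(sam_lines, use.names = FALSE)), sam_path)
  bam <- Rsamtools::asBam(sam_path, destination = out_prefix,
                          overwrite = TRUE, indexDestination = TRUE)
  unlink(sam_path)
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  list(bam = bam, truth = truth, spec = spec)
}

# simulate all reads for one source sequence; returns SAM lines + truth
sim_reads_one_seq <- function(nm, hap, seq, bench, truth_vars, spec, runs,
                              prefix) {
  len <- nchar(seq)
  n_reads <- max(1L, round(spec$depth * len / spec$read_len_mean))
  sdlog <- sqrt(log(1 + spec$read_len_cv^2))
  rl <- pmax(200L, round(stats::rlnorm(n_reads,
                                       log(spec$read_len_mean) - sdlog^2 / 2,
                                       sdlog)))
  rl <- pmin(rl, len)
  # start positions (0-based), with optional GC-bias rejection
  starts <- integer(n_reads)
  for (i in seq_len(n_reads)) {
    for (try in 1:25) {
      s <- sample.int(len - rl[i] + 1L, 1) - 1L
      if (is.null(spec$gc_bias)) break
      # dropout depends on the composition of the read's own span
      w <- substr(seq, s + 1, min(len, s + rl[i]))
      gc <- 100 * (nchar(gsub("[^GC]", "", w)) / nchar(w))
      p_acc <- 1 / (1 + exp(spec$gc_bias$slope * (gc - spec$gc_bias$threshold)))
      if (stats::runif(1) < p_acc) break
    }
    starts[i] <- s
  }
  crossmap <- stats::runif(n_reads) < spec$crossmap_frac

  # homologous target bookkeeping for cross-mapped reads
  tok <- sub("[_.].*$", "", nm)
  other_nm <- if (hap == "hap1") paste0(tok, "_hap2") else paste0(tok, "_hap1")
  has_partner <- other_nm %in% c(names(bench$hap1), names(bench$hap2))

  run_tab <- NULL
  if (!is.null(spec$hp_noise) && !is.null(runs)) {
    run_tab <- runs[runs$seq == nm & runs$unit_len == 1 &
                      runs$run_len_bp >= spec$hp_noise$min_len, , drop = FALSE]
  }

  sam <- character(n_reads)
  truth <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    target_nm <- nm; target_seq <- seq
    s <- starts[i]; e <- s + rl[i]
    if (crossmap[i] && has_partner) {
      target_nm <- other_nm
      target_seq <- bench_seq(bench, other_nm)
    }
    rd <- build_read(nm, hap, seq, target_nm, target_seq, s, e, truth_vars,
                     spec, run_tab, crossmap[i] && has_partner)
    qname <- sprintf("%s_%06d", prefix, i)
    sam[i] <- paste(qname, 0L, target_nm, rd$pos1, 60L, rd$cigar, "*", 0L,
                    0L, rd$seq, rd$qual, sep = "\t")
    truth[[i]] <- data.frame(
      qname = qname, source_seq = nm, source_hap = hap,
      target_seq = target_nm, start0 = rd$pos1 - 1L, read_len = nchar(rd$seq),
      n_sub = rd$n_sub, n_ins = rd$n_ins, n_del = rd$n_del,
      ins_bp = rd$ins_bp, del_bp = rd$del_bp, clipped_bp = rd$clipped_bp,
      crossmapped = crossmap[i] && has_partner, stringsAsFactors = FALSE)
  }
  list(sam = sam, truth = do.call(rbind, truth))
}

# construct one read over source interval [s, e); returns SAM fields + truth
# counters.  For cross-mapped reads the het alleles of the source haplotype
# are additional events relative to the homologous target (SNVs and indels).
build_read <- function(nm, hap, seq, target_nm, target_seq, s, e, truth_vars,
                       spec, run_tab, crossmapped) {
  bases <- c("A", "C", "G", "T")
  if (!crossmapped) {
    tpos1 <- s + 1L
    ref_chars <- strsplit(substr(seq, s + 1, e), "")[[1]]
    het_ev <- NULL
  } else {
    # project the source interval onto the homologous target and express
    # het variants as read-vs-target events
    if (hap == "hap1") {
      v <- truth_vars[truth_vars$chrom == nm, , drop = FALSE]
      self_pos <- v$hap1_pos0; targ_pos <- v$hap2_pos0
      self_allele <- v$ref; targ_allele <- v$alt
    } else {
      tokv <- sub("[_.].*$", "", truth_vars$chrom)
      v <- truth_vars[tokv == sub("[_.].*$", "", nm), , drop = FALSE]
      self_pos <- v$hap2_pos0; targ_pos <- v$hap1_pos0
      self_allele <- v$alt; targ_allele <- v$ref
    }
    # only keep reads whose ends fall between variants for clean projection
    inside <- which(self_pos >= s & self_pos + nchar(self_allele) <= e - 1)
    off_before <- sum(nchar(targ_allele[self_pos + nchar(self_allele) <= s]) -
                        nchar(self_allele[self_pos + nchar(self_allele) <= s]))
    t_s <- s + off_before
    tpos1 <- t_s + 1L
    ref_chars <- strsplit(substr(seq, s + 1, e), "")[[1]]
    het_ev <- if (length(inside))
      data.frame(off = self_pos[inside] - s,
                 self = self_allele[inside], targ = targ_allele[inside],
                 stringsAsFactors = FALSE) else NULL
  }
  rl <- length(ref_chars)

  # per-base reported qualities and substitution errors
  if (spec$q_model == "fixed") {
    qrep <- rep(max(2L, min(60L, round(-10 * log10(max(spec$sub_rate, 1e-6))))), rl)
    sub_mask <- stats::runif(rl) < spec$sub_rate
  } else {
    qtrue <- sample(spec$q_levels, rl, replace = TRUE, prob = spec$q_probs)
    sub_mask <- stats::runif(rl) < 10^(-qtrue / 10)
    qrep <- if (spec$q_model == "miscalibrated")
      qtrue + ifelse(qtrue > spec$miscal_above, spec$miscal_offset, 0L)
    else qtrue
  }
  sub_alt <- character(rl)
  if (any(sub_mask)) {
    idx <- which(sub_mask)
    sub_alt[idx] <- vapply(ref_chars[idx], function(b)
      if (b %in% bases) sample(setdiff(bases, b), 1) else b, "")
    sub_mask[idx][!ref_chars[idx] %in% bases] <- FALSE
  }

  # indel events (sparse); avoid first/last base
  ins_off <- which(stats::runif(rl) < spec$ins_rate)
  ins_off <- ins_off[ins_off > 1 & ins_off < rl]
  ins_len <- if (length(ins_off)) pmin(1L + stats::rgeom(length(ins_off), 0.6), 5L)
             else integer(0)
  del_off <- which(stats::runif(rl) < spec$del_rate)
  del_off <- del_off[del_off > 1 & del_off < rl - 6]
  del_len <- if (length(del_off)) pmin(1L + stats::rgeom(length(del_off), 0.6), 5L)
             else integer(0)

  # homopolymer length noise inside long runs fully within the read
  if (!is.null(run_tab) && nrow(run_tab) > 0 && !crossmapped) {
    inr <- which(run_tab$start > s + 5 & run_tab$end < e - 5)
    for (j in inr) {
      p_err <- min(0.5, spec$hp_noise$p0 *
                     (run_tab$run_len_bp[j] - spec$hp_noise$min_len + 1))
      if (stats::runif(1) >= p_err) next
      off <- run_tab$start[j] - s + sample.int(run_tab$run_len_bp[j] - 1L, 1)
      if (stats::runif(1) < 0.5) {
        ins_off <- c(ins_off, off); ins_len <- c(ins_len, 1L)
      } else {
        del_off <- c(del_off, off); del_len <- c(del_len, 1L)
      }
    }
  }

  # resolve het events for crossmapped reads into sub/indel ops
  status <- rep("=", rl)            # per source-base op vs target
  status[sub_mask] <- "X"
  read_char <- ref_chars
  read_char[sub_mask] <- sub_alt[sub_mask]
  ins_seq_at <- rep("", rl)         # insertion (in read) after source base i
  del_after <- rep(0L, rl)          # target bases deleted after source base i
  if (length(ins_off)) {
    for (j in seq_along(ins_off))
      ins_seq_at[ins_off[j]] <- paste0(ins_seq_at[ins_off[j]],
                                       paste(sample(bases, ins_len[j],
                                                    replace = TRUE),
                                             collapse = ""))
  }
  if (length(del_off)) {
    o <- order(del_off)
    del_off <- del_off[o]; del_len <- del_len[o]
    last_end <- -1L
    keep <- rep(TRUE, length(del_off))
    for (j in seq_along(del_off)) {
      if (del_off[j] <= last_end) { keep[j] <- FALSE; next }
      last_end <- del_off[j] + del_len[j]
    }
    del_off <- del_off[keep]; del_len <- del_len[keep]
    for (j in seq_along(del_off))
      status[(del_off[j] + 1):min(rl, del_off[j] + del_len[j])] <- "D"
  }
  if (!is.null(het_ev)) {
    for (j in seq_len(nrow(het_ev))) {
      o <- het_ev$off[j] + 1L       # 1-based offset of the variant anchor
      ls <- nchar(het_ev$self[j]); lt <- nchar(het_ev$targ[j])
      if (ls == 1 && lt == 1) {
        if (status[o] == "=") { status[o] <- "X" }
        # read carries the source allele; vs target it is a mismatch
      } else if (ls > lt) {
        # source insertion relative to target: read has extra bases
        extra <- substr(het_ev$self[j], lt + 1, ls)
        # represent as I after the anchor; drop those source bases from
        # the aligned walk by marking them "I"
        if (all(status[(o + 1):(o + ls - 1)] == "="))
          status[(o + 1):(o + ls - 1)] <- "I"
      } else if (lt > ls) {
        # source deletion relative to target: target has extra bases
        del_after[o] <- del_after[o] + (lt - ls)
      }
    }
  }

  # assemble read sequence, qualities, CIGAR
  emitted <- status != "D"
  out_seq <- character(0); out_q <- integer(0)
  lens <- integer(0); ops <- character(0)
  push <- function(l, o) { lens <<- c(lens, l); ops <<- c(ops, o) }
  i <- 1L
  while (i <= rl) {
    st <- status[i]
    j <- i
    while (j < rl && status[j + 1] == st &&
           ins_seq_at[j] == "" && del_after[j] == 0L) j <- j + 1L
    n <- j - i + 1L
    if (st == "D") {
      push(n, "D")
    } else if (st == "I") {
      out_seq <- c(out_seq, read_char[i:j]); out_q <- c(out_q, qrep[i:j])
      push(n, "I")
    } else {
      out_seq <- c(out_seq, read_char[i:j]); out_q <- c(out_q, qrep[i:j])
      push(n, st)
    }
    if (ins_seq_at[j] != "" && st != "D") {
      ext <- strsplit(ins_seq_at[j], "")[[1]]
      out_seq <- c(out_seq, ext)
      out_q <- c(out_q, if (spec$q_model == "fixed") rep(qrep[1], length(ext))
                 else sample(spec$q_levels, length(ext), replace = TRUE,
                             prob = spec$q_probs))
      push(length(ext), "I")
    }
    if (del_after[j] > 0L && st != "D") push(del_after[j], "D")
    i <- j + 1L
  }
  # counts from the merged CIGAR (adjacent same-op runs collapse to one event)
  mops <- cig_ops(cig_build(lens, ops))
  n_sub <- sum(status == "X")
  n_ins <- sum(mops$op == "I"); ins_bp <- sum(mops$len[mops$op == "I"])
  n_del <- sum(mops$op == "D"); del_bp <- sum(mops$len[mops$op == "D"])

  # optional soft clip at read start
  clipped_bp <- 0L
  if (spec$clip_prob > 0 && stats::runif(1) < spec$clip_prob) {
    cl <- max(1L, stats::rpois(1, spec$clip_len_mean))
    out_seq <- c(sample(bases, cl, replace = TRUE), out_seq)
    out_q <- c(rep(2L, cl), out_q)
    lens <- c(cl, lens); ops <- c("S", ops)
    clipped_bp <- cl
  }
  list(pos1 = tpos1, cigar = cig_build(lens, ops),
       seq = paste(out_seq, collapse = ""),
       qual = intToUtf8(pmin(out_q, 93L) + 33L),
       n_sub = n_sub, n_ins = n_ins, n_del = n_del,
       ins_bp = ins_bp, del_bp = del_bp, clipped_bp = clipped_bp)
}
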