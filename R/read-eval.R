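# Read profiling against the diploid benchmark.

#' Profile aligned sequencing reads
#'
#' Processes primary, non-duplicate, non-QC-fail alignments from a BAM (or
#' SAM) aligned to the diploid benchmark and accumulates: aligned and
#' clipped bases, the 12-cell substitution spectrum, indel events and bases,
#' per-reported-quality tallies, per-base coverage, read start positions,
#' and homopolymer/STR run observations (correct iff the read reproduces the
#' run length exactly and has no substitutions within the run or its
#' `flank` clean flanking bases).
#'
#' Reads originating from either haplotype may map across homologous
#' sequences; with `het_mask = TRUE` (default) a mismatch at a het SNV where
#' the read carries the alternate haplotype's allele is not counted as an
#' error.
#'
#' @param bam path to a BAM/SAM aligned to the benchmark
#' @param bench DiploidBenchmark
#' @param runs RunCatalog (optional; enables the run table)
#' @param hets het catalog (required when `het_mask = TRUE`)
#' @param het_mask mask alternate-haplotype-consistent mismatches
#' @param flank clean flanking bases required around run observations
#' @return object of class `ReadProfile`
#' @export
profile_reads <- function(bam, bench, runs = NULL, hets = NULL,
                          het_mask = TRUE, flank = 5L) {
  if (het_mask && is.null(hets))
    stop("het_mask = TRUE requires a het catalog (or pass het_mask = FALSE)")
  ext <- tolower(tools::file_ext(bam))
  if (ext == "sam") bam <- Rsamtools::asBam(bam, overwrite = TRUE,
                                            indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq", "qual"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- b$flag
  keep <- !is.na(b$pos) &
    bitwAnd(flag, 256L) == 0 & bitwAnd(flag, 2048L) == 0 &  # secondary/suppl
    bitwAnd(flag, 1024L) == 0 & bitwAnd(flag, 512L) == 0 &  # dup/qcfail
    bitwAnd(flag, 4L) == 0
  rname <- as.character(b$rname)[keep]
  pos <- b$pos[keep]; cig <- b$cigar[keep]
  seqs <- as.character(b$seq)[keep]
  qual <- as.character(b$qual)[keep]
  has_q <- length(qual) > 0 && !all(qual == "*" | !nzchar(qual))

  snv <- if (!is.null(hets)) hets[hets$type == "snv", , drop = FALSE] else NULL
  runs_df <- if (!is.null(runs)) as.data.frame(runs) else NULL

  agg <- list(aligned_bp = 0, clipped_bp = 0, total_read_bp = 0,
              sub_counts = matrix(0, 4, 4), ins_events = 0, del_events = 0,
              ins_bp = 0, del_bp = 0, per_q = matrix(0, 94, 4),
              coverage = list(), starts = list(), run_detail = NULL)
  run_detail <- list()
  for (tname in unique(rname)) {
    sel <- rname == tname
    ref <- bench_seq(bench, tname)
    hp <- integer(0); ho <- character(0)
    if (!is.null(snv)) {
      hs <- snv[snv$seq == tname, , drop = FALSE]
      hp <- hs$pos; ho <- hs$allele_other
      o <- order(hp); hp <- hp[o]; ho <- ho[o]
    }
    rs <- integer(0); re <- integer(0)
    rt <- NULL
    if (!is.null(runs_df)) {
      rt <- runs_df[runs_df$seq == tname, , drop = FALSE]
      rt <- rt[order(rt$start), , drop = FALSE]
      rs <- rt$start; re <- rt$end
    }
    res <- cpp_profile_reads(ref, pos[sel], cig[sel], seqs[sel],
                             if (has_q) qual[sel] else rep(NA_character_, sum(sel)),
                             as.integer(hp), ho, het_mask,
                             as.integer(rs), as.integer(re), as.integer(flank))
    agg$aligned_bp <- agg$aligned_bp + res$aligned_bp
    agg$clipped_bp <- agg$clipped_bp + res$clipped_bp
    agg$total_read_bp <- agg$total_read_bp + res$total_read_bp
    agg$sub_counts <- agg$sub_counts + res$sub_counts
    agg$ins_events <- agg$ins_events + res$ins_events
    agg$del_events <- agg$del_events + res$del_events
    agg$ins_bp <- agg$ins_bp + res$ins_bp
    agg$del_bp <- agg$del_bp + res$del_bp
    agg$per_q <- agg$per_q + res$per_q
    agg$coverage[[tname]] <- res$coverage
    agg$starts[[tname]] <- res$starts
    if (!is.null(rt)) {
      rt$spanned <- res$run_spanned
      rt$correct <- res$run_correct
      run_detail[[tname]] <- rt
    }
  }
  dimnames(agg$sub_counts) <- list(ref = c("A", "C", "G", "T"),
                                   called = c("A", "C", "G", "T"))
  colnames(agg$per_q) <- c("aligned", "mismatch", "ins_events", "del_events")
  agg$run_detail <- if (length(run_detail)) do.call(rbind, run_detail)
  agg$has_qual <- has_q
  agg$flank <- flank
  rownames(agg$run_detail) <- NULL
  class(agg) <- "ReadProfile"
  agg
}

#' @export
print.ReadProfile <- function(x, ...) {
  cat("ReadProfile: aligned_bp =", format(x$aligned_bp, big.mark = ","),
      "; clipped_bp =", format(x$clipped_bp, big.mark = ","), "\n")
  cat("  substitutions:", sum(x$sub_counts), "; ins:", x$ins_events,
      "events /", x$ins_bp, "bp ; del:", x$del_events, "events /",
      x$del_bp, "bp\n")
  invisible(x)
}

#' Twelve-type substitution spectrum and Ti/Tv rates
#'
#' @param profile a `ReadProfile`
#' @return list(table = 12-row data.frame with per-Mb rates, ti_per_mb,
#'   tv_per_mb, titv_ratio)
#' @export
substitution_spectrum <- function(profile) {
  bases <- c("A", "C", "G", "T")
  rows <- list()
  for (r in bases) for (b in bases) {
    if (r == b) next
    rows[[length(rows) + 1]] <- data.frame(
      sub_type = paste0(r, ">", b), count = profile$sub_counts[r, b],
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab$per_mb <- tab$count / (profile$aligned_bp / 1e6)
  tab$ti_tv <- ifelse(tab$sub_type %in% TRANSITIONS, "Ti", "Tv")
  ti <- sum(tab$count[tab$ti_tv == "Ti"])
  tv <- sum(tab$count[tab$ti_tv == "Tv"])
  list(table = tab, ti_per_mb = ti / (profile$aligned_bp / 1e6),
       tv_per_mb = tv / (profile$aligned_bp / 1e6),
       titv_ratio = if (tv > 0) ti / tv else NA_real_)
}

#' Per-Mb read error rates
#' @param profile a `ReadProfile`
#' @return list(sub_per_mb, ins_per_mb, del_per_mb) (event rates)
#' @export
read_error_rates <- function(profile) {
  mb <- profile$aligned_bp / 1e6
  list(sub_per_mb = sum(profile$sub_counts) / mb,
       ins_per_mb = profile$ins_events / mb,
       del_per_mb = profile$del_events / mb)
}

#' Homopolymer quality by run length
#'
#' For each benchmark homopolymer fully spanned by a read alignment together
#' with its flanking bases, the observation is correct iff the read
#' reproduces the run length exactly and carries no substitution within the
#' run or flanks.  Q = -10*log10(incorrect / spanned) per run length.
#'
#' @param profile a `ReadProfile` built with a RunCatalog, or a BAM path
#' @param bench,runs,hets passed through to [profile_reads()] when `profile`
#'   is a path
#' @param flank flanking bases (used only when profiling from a path)
#' @param cap Phred cap for zero-error rows
#' @param unit_len restrict to this unit size (1 = homopolymers)
#' @return data.frame (run_len, spanned, incorrect, q, capped)
#' @export
hp_quality_by_length <- function(profile, bench = NULL, runs = NULL,
                                 hets = NULL, flank = 5L, cap = 90,
                                 unit_len = 1L) {
  if (is.character(profile))
    profile <- profile_reads(profile, bench, runs = runs, hets = hets,
                             flank = flank)
  det <- profile$run_detail
  if (is.null(det)) stop("profile was built without a RunCatalog")
  det <- det[det$unit_len == unit_len & det$spanned > 0, , drop = FALSE]
  if (nrow(det) == 0)
    return(data.frame(run_len = integer(), spanned = integer(),
                      incorrect = integer(), q = numeric(),
                      capped = logical()))
  tab <- do.call(rbind, lapply(split(det, det$run_len_bp), function(x) {
    spanned <- sum(x$spanned); bad <- spanned - sum(x$correct)
    q <- phred(bad, spanned, cap = cap)
    data.frame(run_len = x$run_len_bp[1], spanned = spanned, incorrect = bad,
               q = as.numeric(q), capped = isTRUE(attr(q, "capped")))
  }))
  tab <- tab[order(tab$run_len), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Observed vs reported base-quality calibration
#'
#' For each reported quality bin, observed Q =
#' -10*log10((mismatches + ins + del events attributed to the base) /
#' aligned).  Indels are attributed to the reported quality of the read base
#' immediately 5' of the event.  Bins with zero errors are reported as
#' capped bounds.
#'
#' @param profile a `ReadProfile`
#' @param cap Phred cap for zero-error bins
#' @param min_aligned drop bins with fewer aligned bases
#' @return data.frame (reported_q, aligned, errors, observed_q, capped)
#' @export
quality_calibration <- function(profile, cap = 60, min_aligned = 1) {
  if (!isTRUE(profile$has_qual)) {
    warning("BAM lacks base qualities; calibration table omitted")
    return(NULL)
  }
  pq <- profile$per_q
  qs <- which(pq[, "aligned"] >= min_aligned) - 1L
  out <- lapply(qs, function(q) {
    row <- pq[q + 1L, ]
    err <- row["mismatch"] + row["ins_events"] + row["del_events"]
    ph <- phred(err, row["aligned"], cap = cap)
    data.frame(reported_q = q, aligned = unname(row["aligned"]),
               errors = unname(err), observed_q = as.numeric(ph),
               capped = isTRUE(attr(ph, "capped")))
  })
  do.call(rbind, out)
}

#' Read-arrival dispersion versus Poisson
#'
#' Bins primary read starts, applies the transform
#' x -> (x - median) / sqrt(lambda) with lambda the mean arrivals per bin,
#' and compares the empirical CDF of the transformed counts against the
#' identically transformed Poisson(lambda) CDF.  D_below / D_above are the
#' sup-norm differences over count values below and at-or-above the median.
#'
#' @param profile a `ReadProfile` (its stored start positions are used) or a
#'   named list of integer start-position vectors per sequence
#' @param bench DiploidBenchmark, or a named numeric vector of sequence
#'   lengths (useful for synthetic arrival streams)
#' @param bin_size bin width in bp (default 1000)
#' @return list(bin_size, lambda, median, cdf = data.frame, D_below, D_above)
#' @export
arrival_dispersion <- function(profile, bench, bin_size = 1000L) {
  starts <- if (inherits(profile, "ReadProfile")) profile$starts else profile
  counts <- integer(0)
  for (nm in names(starts)) {
    len <- if (is.numeric(bench)) bench[[nm]] else nchar(bench_seq(bench, nm))
    nbins <- len %/% bin_size  # complete bins only
    if (nbins < 1) next
    s <- starts[[nm]]
    s <- s[s >= 0 & s < nbins * bin_size]
    counts <- c(counts, tabulate(s %/% bin_size + 1L, nbins = nbins))
  }
  if (length(counts) < 100)
    stop("fewer than 100 bins (", length(counts),
         "); statistics would be unstable - decrease bin_size")
  lambda <- mean(counts)
  if (lambda < 5)
    warning("mean arrivals per bin ", round(lambda, 2),
            " < 5; increase bin_size")
  med <- stats::median(counts)
  v <- seq(0L, max(counts))
  emp <- stats::ecdf(counts)(v)
  pois <- stats::ppois(v, lambda)
  dif <- abs(emp - pois)
  below <- v < med
  cdf <- data.frame(count = v, scaled = (v - med) / sqrt(lambda),
                    empirical = emp, poisson = pois)
  list(bin_size = bin_size, lambda = lambda, median = med, cdf = cdf,
       n_bins = length(counts),
       D_below = if (any(below)) max(dif[below]) else 0,
       D_above = max(dif[!below]))
}

#' Mean coverage as a function of window %GC
#'
#' Non-overlapping windows of the benchmark; windows with more than 10% N
#' are dropped and Ns are excluded from the GC fraction.  Coverage comes
#' from primary alignments (the `ReadProfile` coverage track).
#'
#' @param profile a `ReadProfile`
#' @param bench DiploidBenchmark
#' @param window window size in bp (default 100)
#' @return data.frame (gc_percent, mean_coverage, n_windows)
#' @export
coverage_vs_gc <- function(profile, bench, window = 100L) {
  gc_all <- numeric(0); cov_all <- numeric(0)
  for (nm in names(profile$coverage)) {
    seq <- bench_seq(bench, nm)
    cv <- profile$coverage[[nm]]
    len <- nchar(seq)
    nwin <- len %/% window
    if (nwin < 1) next
    ch <- strsplit(substr(seq, 1, nwin * window), "")[[1]]
    grp <- rep(seq_len(nwin), each = window)
    is_gc <- ch %in% c("G", "C")
    is_n <- !(ch %in% c("A", "C", "G", "T"))
    n_n <- tapply(is_n, grp, sum)
    n_gc <- tapply(is_gc, grp, sum)
    ok <- n_n <= 0.1 * window
    gc <- 100 * n_gc / (window - n_n)
    covw <- tapply(cv[seq_len(nwin * window)], grp, mean)
    gc_all <- c(gc_all, gc[ok]); cov_all <- c(cov_all, covw[ok])
  }
  if (length(gc_all) == 0)
    return(data.frame(gc_percent = integer(), mean_coverage = numeric(),
                      n_windows = integer()))
  bin <- round(gc_all)
  out <- do.call(rbind, lapply(split(seq_along(bin), bin), function(i) {
    data.frame(gc_percent = bin[i[1]], mean_coverage = mean(cov_all[i]),
               n_windows = length(i))
  }))
  rownames(out) <- NULL
  out
}
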