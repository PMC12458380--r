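# Two-state HMM phase-block segmentation over haplotype-specific markers.

#' HMM parameters for phase segmentation
#'
#' @param p_switch per-observation probability of switching haplotype state.
#'   The default 1e-5, together with the default `p_error`, makes roughly four
#'   consecutive discordant markers the break-even point for a switch, so
#'   isolated noisy markers are absorbed into blocks.
#' @param p_error probability that a marker's source haplotype disagrees with
#'   the true underlying haplotype (emission noise)
#' @return list of class `HmmParams`
#' @export
hmm_params <- function(p_switch = 1e-5, p_error = 0.02) {
  stopifnot(p_switch > 0, p_switch < 0.5, p_error > 0, p_error < 0.5)
  structure(list(p_switch = p_switch, p_error = p_error), class = "HmmParams")
}

#' Scan a contig for haplotype-specific markers
#'
#' Every canonical k-mer of the contig found in either haplotype's marker set
#' yields one observation; positions are 0-based k-mer start offsets and are
#' strictly increasing.  A contig shorter than k yields an empty scan.
#'
#' @param contig_seq nucleotide string
#' @param markers a `MarkerSet` from [extract_markers()]
#' @param contig name recorded in the observations
#' @param weight_by_count down-weight multi-copy markers as 1/count
#' @return data.frame (contig, pos, source, weight) with attribute `k`
#' @export
scan_markers <- function(contig_seq, markers, contig = "contig",
                         weight_by_count = FALSE) {
  res <- cpp_scan_markers(contig_seq, markers$hap1_markers,
                          markers$hap2_markers, markers$k)
  obs <- data.frame(contig = contig, pos = res$pos,
                    source = c("hap1", "hap2")[res$source],
                    weight = 1, stringsAsFactors = FALSE)
  if (weight_by_count && nrow(obs) > 0) {
    # weight = 1/count of the matched marker within its haplotype
    key <- canonical_kmers_at(contig_seq, obs$pos, markers$k)
    i1 <- match(key, markers$hap1_markers)
    i2 <- match(key, markers$hap2_markers)
    cnt <- ifelse(!is.na(i1), markers$hap1_counts[i1], markers$hap2_counts[i2])
    obs$weight <- 1 / cnt
  }
  attr(obs, "k") <- markers$k
  obs
}

canonical_kmers_at <- function(seq, pos, k) {
  fw <- substring(seq, pos + 1, pos + k)
  rc <- vapply(fw, revcomp, "")
  ifelse(fw <= rc, fw, rc)
}

#' Viterbi segmentation of marker observations into phase blocks
#'
#' Maximum-probability state path under a two-state HMM: uniform initial
#' distribution, symmetric per-observation transition probability
#' `p_switch`, and emission probability `1 - p_error` when a marker's source
#' agrees with the state.  Consecutive same-state observations are merged
#' into blocks; block boundaries are placed at the midpoint between the end
#' of the last marker of one block and the start of the first marker of the
#' next.  Ties are broken toward the previous state, so switch counts are
#' conservative and deterministic.
#'
#' @param obs observations from [scan_markers()] (sorted by pos)
#' @param params an `HmmParams`
#' @param contig_len optional contig length; when given the first/last blocks
#'   extend to the contig ends
#' @return data.frame (contig, start, end, state, n_support, n_conflict)
#' @export
viterbi_phase <- function(obs, params = hmm_params(), contig_len = NULL) {
  blocks0 <- data.frame(contig = character(), start = integer(),
                        end = integer(), state = character(),
                        n_support = integer(), n_conflict = integer(),
                        stringsAsFactors = FALSE)
  if (is.null(obs) || nrow(obs) == 0) return(blocks0)
  stopifnot(!is.unsorted(obs$pos))
  k <- attr(obs, "k") %||% 1L
  src <- ifelse(obs$source == "hap1", 1L, 2L)
  path <- cpp_viterbi2(src, as.numeric(obs$weight),
                       params$p_switch, params$p_error)
  r <- rle(path)
  n_blocks <- length(r$values)
  idx_end <- cumsum(r$lengths)
  idx_start <- c(1L, head(idx_end, -1) + 1L)
  start <- integer(n_blocks); end <- integer(n_blocks)
  for (b in seq_len(n_blocks)) {
    first_pos <- obs$pos[idx_start[b]]
    last_pos <- obs$pos[idx_end[b]]
    start[b] <- if (b == 1) {
      if (!is.null(contig_len)) 0L else first_pos
    } else {
      prev_last <- obs$pos[idx_end[b - 1]] + k
      as.integer((prev_last + first_pos) %/% 2)
    }
    end[b] <- if (b == n_blocks) {
      if (!is.null(contig_len)) as.integer(contig_len) else last_pos + k
    } else {
      as.integer((last_pos + k + obs$pos[idx_start[b + 1]]) %/% 2)
    }
  }
  n_support <- vapply(seq_len(n_blocks), function(b)
    sum(src[idx_start[b]:idx_end[b]] == r$values[b]), 0L)
  n_conflict <- vapply(seq_len(n_blocks), function(b)
    sum(src[idx_start[b]:idx_end[b]] != r$values[b]), 0L)
  data.frame(contig = obs$contig[1], start = start, end = end,
             state = c("hap1", "hap2")[r$values],
             n_support = n_support, n_conflict = n_conflict,
             stringsAsFactors = FALSE)
}

#' Phase a whole assembly
#'
#' Runs [scan_markers()] + [viterbi_phase()] on every contig.
#' @param assembly named character vector of contig sequences
#' @param markers MarkerSet
#' @param params HmmParams
#' @param exclude optional interval set (contig coordinates) removed from the
#'   observation stream before segmentation (e.g. loci where markers are
#'   known to be unreliable)
#' @return data.frame of phase blocks across contigs
#' @export
phase_assembly <- function(assembly, markers, params = hmm_params(),
                           exclude = NULL) {
  out <- lapply(names(assembly), function(nm) {
    obs <- scan_markers(assembly[[nm]], markers, contig = nm)
    if (!is.null(exclude) && nrow(obs) > 0) {
      drop <- iv_contains_points(exclude, obs$contig, obs$pos)
      obs <- obs[!drop, , drop = FALSE]
      attr(obs, "k") <- markers$k
    }
    viterbi_phase(obs, params, contig_len = nchar(assembly[[nm]]))
  })
  do.call(rbind, out)
}

#' Phase-switch summary statistics
#'
#' @param blocks phase blocks from [viterbi_phase()]/[phase_assembly()]
#' @param aligned_bp total aligned bases used as the rate denominator
#' @return list(n_switches, switch_rate_per_mb, per_contig)
#' @export
switch_stats <- function(blocks, aligned_bp) {
  stopifnot(aligned_bp > 0)
  per_contig <- do.call(rbind, lapply(split(blocks, blocks$contig), function(b) {
    data.frame(contig = b$contig[1], n_blocks = nrow(b),
               n_switches = nrow(b) - 1L,
               largest_block = max(b$end - b$start),
               stringsAsFactors = FALSE)
  }))
  if (is.null(per_contig))
    per_contig <- data.frame(contig = character(), n_blocks = integer(),
                             n_switches = integer(), largest_block = integer())
  n_switches <- sum(per_contig$n_switches)
  list(n_switches = n_switches,
       switch_rate_per_mb = n_switches / (aligned_bp / 1e6),
       per_contig = per_contig)
}
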