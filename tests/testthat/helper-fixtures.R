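# Shared small fixtures, cached across test files within one session.

.dibench_cache <- local({
  if (!exists(".dibench_test_cache", envir = globalenv()))
    assign(".dibench_test_cache", new.env(parent = emptyenv()),
           envir = globalenv())
  get(".dibench_test_cache", envir = globalenv())
})

cached <- function(key, expr) {
  if (!exists(key, envir = .dibench_cache))
    assign(key, force(expr), envir = .dibench_cache)
  get(key, envir = .dibench_cache)
}

# 1-chromosome 200 kb diploid fixture with default rates
fx_small <- function() cached("fx_small", simulate_diploid_genome(
  genome_spec(n_chroms = 1L, chrom_len_bp = 200000L, seed = 3L)))

hets_small <- function() cached("hets_small",
  build_het_catalog(fx_small()$bench, fx_small()$alignments))

runs_small <- function() cached("runs_small", annotate_runs(fx_small()$bench))

markers_small <- function() cached("markers_small",
  extract_markers(fx_small()$bench, k = 21L))

# independent run-annotation oracle: vectorized period scan (same definition,
# different algorithm family than the C++ scanner)
runs_oracle <- function(seq, unit_sizes = 1:4,
                        min_copies = ifelse(unit_sizes == 1, 2L, 3L)) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  ok <- ch %in% c("A", "C", "G", "T")
  out <- list()
  primitive <- function(unit) {
    u <- nchar(unit)
    for (d in seq_len(u - 1)) {
      if (u %% d != 0) next
      if (identical(strrep(substr(unit, 1, d), u / d), unit)) return(FALSE)
    }
    TRUE
  }
  for (ui in seq_along(unit_sizes)) {
    u <- unit_sizes[ui]
    if (n <= u) next
    eq <- c(rep(FALSE, u), ch[(u + 1):n] == ch[1:(n - u)] &
              ok[(u + 1):n] & ok[1:(n - u)])
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      s <- starts[j] - u   # 1-based start of the run
      e <- ends[j]         # 1-based inclusive end
      if (!all(ok[s:e])) next
      len <- e - s + 1L
      if (len %/% u < min_copies[ui]) next
      unit <- paste(ch[s:(s + u - 1)], collapse = "")
      if (!primitive(unit)) next
      out[[length(out) + 1]] <- data.frame(
        start = s - 1L, end = e, unit = unit, unit_len = u,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(start = integer(), end = integer(), unit = character(),
                      unit_len = integer(), stringsAsFactors = FALSE)
  res[order(res$start, res$unit_len), , drop = FALSE]
}

# brute-force canonical k-mer set of one sequence (toy scale)
kmer_set_oracle <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  fw <- substring(seq, 1:(n - k + 1), k:n)
  fw <- fw[!grepl("[^ACGT]", fw)]
  rc <- vapply(fw, function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))), "")
  unique(ifelse(fw <= rc, fw, rc))
}

# exhaustive two-state path enumeration; returns max log-prob and whether the
# given path attains it
viterbi_logprob <- function(path, src, p_switch, p_error) {
  lp <- log(0.5) +
    sum(ifelse(path == src, log(1 - p_error), log(p_error)))
  if (length(path) > 1)
    lp <- lp + sum(ifelse(diff(path) == 0, log(1 - p_switch), log(p_switch)))
  lp
}

viterbi_enum_max <- function(src, p_switch, p_error) {
  n <- length(src)
  grid <- as.matrix(expand.grid(rep(list(1:2), n)))
  max(apply(grid, 1, viterbi_logprob, src = src, p_switch = p_switch,
            p_error = p_error))
}

# minimal SAM writer for handmade read cases
write_mini_sam <- function(path, refs, reads) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(refs), "\tLN:", nchar(refs)))
  recs <- vapply(reads, function(r)
    paste(r$qname, r$flag %||% 0L, r$rname, r$pos, 60L, r$cigar, "*", 0L, 0L,
          r$seq, r$qual %||% "*", sep = "\t"), "")
  writeLines(c(hdr, recs), path)
  path
}
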