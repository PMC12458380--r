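# Diploid benchmark index: truth genome, het sites, haplotype markers, runs.

#' Load a diploid truth genome benchmark
#'
#' Reads the two haplotype FASTA files, optionally a low-confidence BED, and
#' builds the `DiploidBenchmark` object that all evaluations consume.
#' Haplotype pairing (which hap2 sequence is homologous to which hap1
#' sequence) is taken from `pairing` when supplied, otherwise inferred by
#' matching a shared chromosome token in the sequence names (everything up to
#' the first `_` or the full name).  Sequences without a partner are treated
#' as hemizygous (e.g. sex chromosomes).
#'
#' @param hap1_fasta,hap2_fasta paths to the two haplotype FASTAs (or named
#'   character vectors of sequences, for programmatic use)
#' @param lowconf_bed optional BED of low-confidence regions (0-based
#'   half-open); names must match benchmark sequence names
#' @param pairing optional data.frame(hap1, hap2) of homologous sequence names
#' @return an object of class `DiploidBenchmark`
#' @export
load_benchmark <- function(hap1_fasta, hap2_fasta, lowconf_bed = NULL,
                           pairing = NULL) {
  hap1 <- if (is.character(hap1_fasta) && length(hap1_fasta) == 1 &&
              file.exists(hap1_fasta)) read_fasta(hap1_fasta) else toupper(hap1_fasta)
  hap2 <- if (is.character(hap2_fasta) && length(hap2_fasta) == 1 &&
              file.exists(hap2_fasta)) read_fasta(hap2_fasta) else toupper(hap2_fasta)
  if (is.null(names(hap1)) || is.null(names(hap2)))
    stop("haplotype sequences must be named")
  dup <- intersect(names(hap1), names(hap2))
  if (length(dup) > 0)
    stop("duplicate sequence names across haplotypes: ",
         paste(dup, collapse = ", "),
         " (rename, e.g. suffix _hap1/_hap2)")

  if (is.null(pairing)) {
    tok <- function(x) sub("[_.].*$", "", x)
    t1 <- tok(names(hap1)); t2 <- tok(names(hap2))
    m <- match(t1, t2)
    pairing <- data.frame(hap1 = names(hap1)[!is.na(m)],
                          hap2 = names(hap2)[m[!is.na(m)]],
                          stringsAsFactors = FALSE)
  } else {
    pairing <- as.data.frame(pairing, stringsAsFactors = FALSE)
    names(pairing)[1:2] <- c("hap1", "hap2")
    bad <- !(pairing$hap1 %in% names(hap1)) | !(pairing$hap2 %in% names(hap2))
    if (any(bad)) stop("pairing references unknown sequences")
  }

  lowconf <- empty_iv()
  if (!is.null(lowconf_bed)) {
    lowconf <- if (is.data.frame(lowconf_bed)) lowconf_bed else read_bed(lowconf_bed)
    all_names <- c(names(hap1), names(hap2))
    bad <- !(lowconf$seq %in% all_names)
    if (any(bad))
      stop("low-confidence BED references unknown sequence: line ",
           which(bad)[1], " (", lowconf$seq[which(bad)[1]], ")")
    lens <- c(nchar(hap1), nchar(hap2))[lowconf$seq]
    if (any(lowconf$end > lens | lowconf$start < 0))
      stop("low-confidence interval out of sequence bounds")
    lowconf <- iv_reduce(lowconf)
  }

  non_n <- function(x) nchar(x) - vapply(gregexpr("N", x, fixed = TRUE),
                                         function(m) sum(m > 0), 0L)
  total <- sum(non_n(hap1)) + sum(non_n(hap2))

  bench <- structure(list(hap1 = hap1, hap2 = hap2, pairing = pairing,
                          lowconf = lowconf, total_diploid_bp = total),
                     class = "DiploidBenchmark")
  bench
}

#' @export
print.DiploidBenchmark <- function(x, ...) {
  cat("DiploidBenchmark:", length(x$hap1), "+", length(x$hap2), "sequences,",
      format(x$total_diploid_bp, big.mark = ","), "non-N diploid bp,",
      nrow(x$pairing), "homologous pairs,",
      nrow(x$lowconf), "low-confidence intervals\n")
  invisible(x)
}

# haplotype of a benchmark sequence name ("hap1"/"hap2")
bench_hap_of <- function(bench, seqname) {
  ifelse(seqname %in% names(bench$hap1), "hap1",
         ifelse(seqname %in% names(bench$hap2), "hap2", NA_character_))
}

bench_seq <- function(bench, seqname) {
  if (seqname %in% names(bench$hap1)) return(bench$hap1[[seqname]])
  if (seqname %in% names(bench$hap2)) return(bench$hap2[[seqname]])
  stop("unknown benchmark sequence: ", seqname)
}

# non-N intervals of every benchmark sequence, as an interval set
bench_non_n_iv <- function(bench) {
  seqs <- c(bench$hap1, bench$hap2)
  out <- lapply(names(seqs), function(nm) {
    s <- seqs[[nm]]
    m <- gregexpr("[^N]+", s)[[1]]
    if (m[1] == -1) return(NULL)
    data.frame(seq = nm, start = as.integer(m) - 1L,
               end = as.integer(m) + attr(m, "match.length") - 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty_iv() else out
}

#' Catalog heterozygous sites from hap1-vs-hap2 alignments
#'
#' Walks base-level CIGARs of alignments between homologous haplotype
#' sequences and records every inter-haplotype difference as a mirrored pair
#' of het-site records (one per haplotype).  Alignments must have hap2
#' sequences as query and hap1 sequences as target (the orientation the
#' fixtures module emits); alignments between unpaired sequences are skipped
#' with a warning.
#'
#' @param bench a `DiploidBenchmark`
#' @param alignments alignment segments from [read_alignments()] (PAF with cg
#'   tags or BAM), hap2 query vs hap1 target
#' @return data.frame with columns hap, seq, pos (0-based), allele_self,
#'   allele_other, type ("snv"/"ins"/"del" relative to self), lowconf
#' @export
build_het_catalog <- function(bench, alignments) {
  segs <- if (is.character(alignments)) read_alignments(alignments, bench = bench)
          else alignments
  acc <- new.env(parent = emptyenv())
  acc$hap <- list(); acc$seq <- list(); acc$pos <- list()
  acc$self <- list(); acc$other <- list(); acc$type <- list()
  emit <- function(hap, seq, pos, self, other, type) {
    i <- length(acc$hap) + 1L
    acc$hap[[i]] <- hap; acc$seq[[i]] <- seq; acc$pos[[i]] <- pos
    acc$self[[i]] <- self; acc$other[[i]] <- other; acc$type[[i]] <- type
  }
  for (i in seq_len(nrow(segs))) {
    seg <- segs[i, ]
    t_name <- seg$target_seq; q_name <- seg$query
    pair_ok <- any(bench$pairing$hap1 == t_name & bench$pairing$hap2 == q_name)
    if (!pair_ok) {
      warning("alignment ", q_name, " -> ", t_name,
              " is not between paired sequences; skipped")
      next
    }
    tseq <- bench$hap1[[t_name]]
    qseq <- bench$hap2[[q_name]]
    if (seg$strand == "-") qseq <- revcomp(qseq)
    ops <- cig_ops(seg$cigar)
    ti <- seg$t_start; qi <- seg$q_start
    for (j in seq_len(nrow(ops))) {
      len <- ops$len[j]; op <- ops$op[j]
      if (op %in% c("M", "=", "X")) {
        if (op != "=") {
          tb <- utf8ToInt(substr(tseq, ti + 1, ti + len))
          qb <- utf8ToInt(substr(qseq, qi + 1, qi + len))
          d <- which(tb != qb)
          if (length(d) > 0) {
            a1 <- strsplit(intToUtf8(tb[d]), "")[[1]]
            a2 <- strsplit(intToUtf8(qb[d]), "")[[1]]
            ok <- a1 != "N" & a2 != "N"
            if (any(ok)) {
              emit(rep(c("hap1", "hap2"), each = sum(ok)),
                   rep(c(t_name, q_name), each = sum(ok)),
                   c(ti + d[ok] - 1L, qi + d[ok] - 1L),
                   c(a1[ok], a2[ok]), c(a2[ok], a1[ok]),
                   rep("snv", 2L * sum(ok)))
            }
          }
        }
        ti <- ti + len; qi <- qi + len
      } else if (op == "I") { # present in hap2, absent in hap1
        ins <- substr(qseq, qi + 1, qi + len)
        anchor1 <- substr(tseq, ti, ti); anchor2 <- substr(qseq, qi, qi)
        emit(c("hap1", "hap2"), c(t_name, q_name), c(ti - 1L, qi - 1L),
             c(anchor1, paste0(anchor2, ins)),
             c(paste0(anchor1, ins), anchor2), c("ins", "del"))
        qi <- qi + len
      } else if (op == "D") { # present in hap1, absent in hap2
        del <- substr(tseq, ti + 1, ti + len)
        anchor1 <- substr(tseq, ti, ti); anchor2 <- substr(qseq, qi, qi)
        emit(c("hap1", "hap2"), c(t_name, q_name), c(ti - 1L, qi - 1L),
             c(paste0(anchor1, del), anchor2),
             c(anchor1, paste0(anchor2, del)), c("del", "ins"))
        ti <- ti + len
      } else if (op %in% c("S", "H")) {
        qi <- qi + ifelse(op == "S", len, 0L)
      }
    }
  }
  hets <- data.frame(
    hap = unlist(acc$hap) %||% character(),
    seq = unlist(acc$seq) %||% character(),
    pos = as.integer(unlist(acc$pos) %||% integer()),
    allele_self = unlist(acc$self) %||% character(),
    allele_other = unlist(acc$other) %||% character(),
    type = unlist(acc$type) %||% character(), stringsAsFactors = FALSE)
  hets$lowconf <- iv_contains_points(bench$lowconf, hets$seq, hets$pos)
  hets <- hets[order(hets$hap, hets$seq, hets$pos), , drop = FALSE]
  rownames(hets) <- NULL
  hets
}

#' Extract haplotype-specific k-mer markers
#'
#' A marker is a canonical k-mer present at least once in one haplotype and
#' zero times in the other.  k-mers spanning N are excluded.  Occurrence
#' counts within the owning haplotype are retained so the phasing HMM can
#' optionally down-weight multi-copy markers.
#'
#' @param bench a `DiploidBenchmark`
#' @param k odd k-mer size, 15..31 (default 31)
#' @return a `MarkerSet`: list(k, hap1_markers, hap2_markers, hap1_counts,
#'   hap2_counts)
#' @export
extract_markers <- function(bench, k = 31L) {
  k <- as.integer(k)
  if (k %% 2 == 0) stop("k must be odd so canonicalization is unambiguous")
  if (k < 15 || k > 31) stop("k must be between 15 and 31")
  res <- cpp_hap_specific_kmers(unname(bench$hap1), unname(bench$hap2), k)
  structure(list(k = k,
                 hap1_markers = res$hap1_markers, hap1_counts = res$hap1_counts,
                 hap2_markers = res$hap2_markers, hap2_counts = res$hap2_counts),
            class = "MarkerSet")
}

#' @export
print.MarkerSet <- function(x, ...) {
  cat("MarkerSet: k =", x$k, ";", length(x$hap1_markers), "hap1 markers,",
      length(x$hap2_markers), "hap2 markers\n")
  invisible(x)
}

#' Annotate homopolymer and short tandem runs
#'
#' Finds maximal perfect runs of 1-4 bp units in each sequence.  A run is
#' recorded only if its unit is primitive (so `AAAA` is a homopolymer, never
#' a dinucleotide) and it reaches the per-unit-size minimum copy number.
#' Runs never span N.
#'
#' @param seqs named character vector of sequences (or a `DiploidBenchmark`,
#'   in which case both haplotypes are annotated)
#' @param unit_sizes unit sizes to scan (subset of 1:4)
#' @param min_copies minimum complete copies per unit size (parallel to
#'   `unit_sizes`); defaults: homopolymer >= 2 copies, larger units >= 3
#' @return data.frame (seq, start, end, unit, unit_len, run_len_bp), class
#'   `RunCatalog`
#' @export
annotate_runs <- function(seqs, unit_sizes = 1:4,
                          min_copies = ifelse(unit_sizes == 1, 2L, 3L)) {
  if (inherits(seqs, "DiploidBenchmark")) seqs <- c(seqs$hap1, seqs$hap2)
  stopifnot(all(unit_sizes %in% 1:4), length(min_copies) == length(unit_sizes))
  out <- lapply(names(seqs), function(nm) {
    r <- cpp_find_runs(seqs[[nm]], as.integer(unit_sizes), as.integer(min_copies))
    if (length(r$start) == 0) return(NULL)
    data.frame(seq = nm, start = r$start, end = r$end, unit = r$unit,
               unit_len = r$unit_len, run_len_bp = r$end - r$start,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(seq = character(), start = integer(), end = integer(),
                      unit = character(), unit_len = integer(),
                      run_len_bp = integer(), stringsAsFactors = FALSE)
  out <- out[order(out$seq, out$start, out$unit_len), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("RunCatalog", "data.frame")
  out
}

# ---- index serialization ---------------------------------------------------

#' Serialize a benchmark index to a directory
#'
#' Writes markers (TSV with a header line recording k), het sites (TSV),
#' runs (BED + unit columns), low-confidence BED, and a config JSON.
#' @param dir output directory
#' @param bench DiploidBenchmark
#' @param markers MarkerSet (optional)
#' @param hets het catalog (optional)
#' @param runs RunCatalog (optional)
#' @export
write_benchmark_index <- function(dir, bench, markers = NULL, hets = NULL,
                                  runs = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(bench$hap1, file.path(dir, "hap1.fasta"))
  write_fasta(bench$hap2, file.path(dir, "hap2.fasta"))
  utils::write.table(bench$pairing, file.path(dir, "pairing.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(bench$lowconf) > 0)
    write_bed(bench$lowconf, file.path(dir, "lowconf.bed"))
  if (!is.null(markers)) {
    con <- file(file.path(dir, "markers.tsv"), "w")
    writeLines(paste0("#k=", markers$k, "\tcanonical=lexmin"), con)
    df <- rbind(
      data.frame(kmer = markers$hap1_markers, hap = "hap1",
                 count = markers$hap1_counts, stringsAsFactors = FALSE),
      data.frame(kmer = markers$hap2_markers, hap = "hap2",
                 count = markers$hap2_counts, stringsAsFactors = FALSE))
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  if (!is.null(hets))
    utils::write.table(hets, file.path(dir, "hets.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(runs))
    write_bed(as.data.frame(runs)[, c("seq", "start", "end", "unit", "unit_len")],
              file.path(dir, "runs.bed"))
  cfg <- list(total_diploid_bp = bench$total_diploid_bp,
              k = if (!is.null(markers)) markers$k else NULL,
              checksum = index_checksum(bench))
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Load a serialized benchmark index
#' @param dir directory written by [write_benchmark_index()]
#' @return list(bench, markers, hets, runs) (missing pieces NULL)
#' @export
read_benchmark_index <- function(dir) {
  lc <- file.path(dir, "lowconf.bed")
  bench <- load_benchmark(file.path(dir, "hap1.fasta"),
                          file.path(dir, "hap2.fasta"),
                          lowconf_bed = if (file.exists(lc)) lc else NULL,
                          pairing = utils::read.table(
                            file.path(dir, "pairing.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE))
  markers <- NULL
  mf <- file.path(dir, "markers.tsv")
  if (file.exists(mf)) {
    hdr <- readLines(mf, n = 1)
    k <- as.integer(sub("^#k=([0-9]+).*$", "\\1", hdr))
    df <- utils::read.table(mf, header = TRUE, sep = "\t", skip = 1,
                            stringsAsFactors = FALSE)
    markers <- structure(list(
      k = k,
      hap1_markers = df$kmer[df$hap == "hap1"],
      hap1_counts = df$count[df$hap == "hap1"],
      hap2_markers = df$kmer[df$hap == "hap2"],
      hap2_counts = df$count[df$hap == "hap2"]), class = "MarkerSet")
  }
  hets <- NULL
  hf <- file.path(dir, "hets.tsv")
  if (file.exists(hf))
    hets <- utils::read.table(hf, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  runs <- NULL
  rf <- file.path(dir, "runs.bed")
  if (file.exists(rf)) {
    runs <- read_bed(rf)
    names(runs) <- c("seq", "start", "end", "unit", "unit_len")
    runs$run_len_bp <- runs$end - runs$start
    class(runs) <- c("RunCatalog", "data.frame")
  }
  list(bench = bench, markers = markers, hets = hets, runs = runs)
}

# checksum identifying a benchmark (used to refuse mixed-index reports)
index_checksum <- function(bench) {
  sizes <- c(vapply(bench$hap1, nchar, 0L), vapply(bench$hap2, nchar, 0L))
  paste0(format(bench$total_diploid_bp, scientific = FALSE), "-",
         sum(as.numeric(sizes) * seq_along(sizes)) %% 1e9)
}
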