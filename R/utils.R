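#' @useDynLib dibench, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

# ---- sequence I/O ----------------------------------------------------------

#' Read a FASTA file into a named character vector (uppercase)
#' @param path FASTA file
#' @return named character vector of sequences
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write a named character vector of sequences as FASTA
#' @param seqs named character vector
#' @param path output file
#' @param width line width
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  ss <- Biostrings::DNAStringSet(unlist(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# ---- BED -------------------------------------------------------------------

#' Read a BED file (0-based half-open)
#' @param path BED file
#' @return data.frame with seq, start, end and any further columns
#' @export
read_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  names(bed)[1:3] <- c("seq", "start", "end")
  bed$start <- as.integer(bed$start)
  bed$end <- as.integer(bed$end)
  bed
}

#' Write intervals as BED
#' @param df data.frame with seq, start, end (+ extra columns kept in order)
#' @param path output file
#' @export
write_bed <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- interval sets ---------------------------------------------------------
# Interval sets are data.frames (seq, start, end), 0-based half-open.

empty_iv <- function() {
  data.frame(seq = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

iv_validate <- function(iv) {
  stopifnot(all(c("seq", "start", "end") %in% names(iv)))
  iv[iv$end > iv$start, c("seq", "start", "end"), drop = FALSE]
}

iv_to_irl <- function(iv) {
  if (nrow(iv) == 0) return(IRanges::IRangesList())
  # IRanges are 1-based closed
  S4Vectors::split(IRanges::IRanges(start = iv$start + 1L, end = iv$end),
                   iv$seq)
}

irl_to_iv <- function(irl) {
  if (length(irl) == 0) return(empty_iv())
  lens <- S4Vectors::elementNROWS(irl)
  data.frame(seq = rep(names(irl), lens),
             start = unlist(lapply(irl, IRanges::start), use.names = FALSE) - 1L,
             end = unlist(lapply(irl, IRanges::end), use.names = FALSE),
             stringsAsFactors = FALSE, row.names = NULL)
}

iv_reduce <- function(iv) {
  iv <- iv_validate(iv)
  if (nrow(iv) == 0) return(empty_iv())
  irl_to_iv(IRanges::reduce(iv_to_irl(iv)))
}

iv_width <- function(iv) {
  iv <- iv_reduce(iv)
  if (nrow(iv) == 0) return(0)
  sum(as.numeric(iv$end - iv$start))
}

iv_binop <- function(a, b, fun) {
  a <- iv_reduce(a); b <- iv_reduce(b)
  seqs <- union(a$seq, b$seq)
  out <- lapply(seqs, function(s) {
    ra <- a[a$seq == s, , drop = FALSE]
    rb <- b[b$seq == s, , drop = FALSE]
    ia <- IRanges::IRanges(start = ra$start + 1L, end = ra$end)
    ib <- IRanges::IRanges(start = rb$start + 1L, end = rb$end)
    r <- fun(ia, ib)
    if (length(r) == 0) return(NULL)
    data.frame(seq = s, start = IRanges::start(r) - 1L, end = IRanges::end(r),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty_iv() else out
}

iv_intersect <- function(a, b) iv_binop(a, b, IRanges::intersect)
iv_setdiff <- function(a, b) iv_binop(a, b, IRanges::setdiff)
iv_union <- function(a, b) iv_reduce(rbind(a[c("seq", "start", "end")],
                                           b[c("seq", "start", "end")]))

# membership of 0-based points in an interval set (same seq)
iv_contains_points <- function(iv, seqs, pos) {
  if (length(pos) == 0) return(logical(0))
  iv <- iv_reduce(iv)
  out <- logical(length(pos))
  for (s in unique(seqs)) {
    sel <- seqs == s
    rs <- iv[iv$seq == s, , drop = FALSE]
    if (nrow(rs) == 0) next
    ir <- IRanges::IRanges(start = rs$start + 1L, end = rs$end)
    pq <- IRanges::IRanges(start = pos[sel] + 1L, width = 1L)
    out[sel] <- IRanges::overlapsAny(pq, ir)
  }
  out
}

# ---- Phred -----------------------------------------------------------------

#' Phred-scaled quality from an error fraction
#'
#' Computes -10*log10(errors/total).  Zero errors are reported as the cap
#' (a lower bound) with attribute `capped = TRUE`.
#' @param errors error count
#' @param total denominator count
#' @param cap value reported when errors == 0
#' @return numeric Phred value with attribute "capped"
#' @export
phred <- function(errors, total, cap = 90) {
  if (total <= 0) return(structure(NA_real_, capped = NA))
  if (errors <= 0) return(structure(as.numeric(cap), capped = TRUE))
  structure(-10 * log10(errors / total), capped = FALSE)
}

# ---- CIGAR -----------------------------------------------------------------

cig_ops <- function(cigar) {
  if (is.na(cigar) || !nzchar(cigar)) {
    return(data.frame(len = integer(), op = character(), stringsAsFactors = FALSE))
  }
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(cigar)) stop("malformed CIGAR: ", cigar)
  data.frame(len = as.integer(sub("[MIDNSHP=X]$", "", toks)),
             op = sub("^[0-9]+", "", toks), stringsAsFactors = FALSE)
}

cig_build <- function(lens, ops) {
  keep <- lens > 0
  lens <- lens[keep]; ops <- ops[keep]
  if (length(ops) == 0) return("")
  # merge adjacent identical ops
  r <- rle(ops)
  if (any(r$lengths > 1)) {
    grp <- rep(seq_along(r$lengths), r$lengths)
    lens <- as.integer(tapply(lens, grp, sum))
    ops <- r$values
  }
  paste0(lens, ops, collapse = "")
}

cig_qlen <- function(ops) sum(ops$len[ops$op %in% c("M", "=", "X", "I", "S")])
cig_tlen <- function(ops) sum(ops$len[ops$op %in% c("M", "=", "X", "D", "N")])

# ---- RNG substreams --------------------------------------------------------

# Deterministic derived seed for a named substream; < 2^31.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_len(nchar(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# random DNA of length n as a single string
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
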