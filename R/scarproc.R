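# Read classification by tailed-scar motifs.
#
# Cleavage scars appear in read space as GCG followed by the poly(dA)
# tail (3' scar) or the poly(dT) tail followed by CGC (5' scar); the two
# 9-mer motifs are reverse complements of each other, so a read
# sequenced from the opposite strand of a scarred end simply swaps
# class.

MOTIF_SCAR3 <- "GCGAAAAAA"
MOTIF_SCAR5 <- "TTTTTTCGC"

# Hamming distances of equal-length strings against one reference.
mismatch_count_ <- function(strs, ref) {
  if (!length(strs)) return(integer())
  w <- nchar(ref)
  m <- matrix(utf8ToInt(paste(strs, collapse = "")), nrow = w)
  as.integer(colSums(m != utf8ToInt(ref)))
}

#' Find approximate occurrences of a motif in a sequence
#'
#' All offsets at which the motif matches with at most `max_mismatch`
#' substitutions (Hamming distance); `max_mismatch = 0` is exact
#' substring search.
#'
#' @param seq a single sequence.
#' @param motif the motif (non-empty).
#' @param max_mismatch maximum Hamming distance.
#' @return integer vector of 0-based match offsets.
#' @examples
#' hamming_find("TTGAGCGAAAAAA", "GCGAAAAAA", 1)  # 4
#' @export
hamming_find <- function(seq, motif, max_mismatch = 1L) {
  if (!nzchar(motif)) stop("motif must be non-empty")
  if (nchar(seq) < nchar(motif)) return(integer())
  m <- Biostrings::matchPattern(motif, Biostrings::DNAString(seq),
                                max.mismatch = max_mismatch)
  st <- Biostrings::start(m)
  st <- st[st >= 1L & st + nchar(motif) - 1L <= nchar(seq)]  # in-bounds only
  st - 1L
}

#' Trim the constant adapter from read ends
#'
#' Removes a leading or trailing adapter occurrence (Hamming distance
#' <= 1) in either orientation — a read sequenced from the opposite
#' strand carries the reverse complement of the adapter — including
#' partial occurrences of at least `min_partial` bp at the read ends (a
#' read window that starts inside the adapter sees only its tail).
#' Internal occurrences are left untouched.
#'
#' @param seqs character vector of read sequences.
#' @param adapter adapter sequence.
#' @param min_partial minimum length of a partial terminal match.
#' @return data.frame with `seq` (trimmed), `pre` and `suf` (number of
#'   bases removed from each end of the original read).
#' @export
trim_adapter <- function(seqs, adapter = DEFAULT_ADAPTER, min_partial = 8L) {
  la <- nchar(adapter)
  rc <- revcomp_(adapter)
  n <- length(seqs)
  pre <- integer(n)
  suf <- integer(n)
  for (l in seq(la, min_partial)) {
    # adapter tail at read start: suffix of either orientation
    for (ref in c(substr(adapter, la - l + 1L, la), substr(rc, la - l + 1L, la))) {
      cand <- which(pre == 0L & nchar(seqs) >= l)
      if (length(cand)) {
        mm <- mismatch_count_(substr(seqs[cand], 1L, l), ref)
        pre[cand[mm <= 1L]] <- l
      }
    }
    # adapter head at read end: prefix of either orientation
    for (ref in c(substr(adapter, 1L, l), substr(rc, 1L, l))) {
      cand <- which(suf == 0L & nchar(seqs) - pre >= l)
      if (length(cand)) {
        mm <- mismatch_count_(substr(seqs[cand], nchar(seqs[cand]) - l + 1L,
                                     nchar(seqs[cand])), ref)
        suf[cand[mm <= 1L]] <- l
      }
    }
  }
  data.frame(seq = substr(seqs, pre + 1L, nchar(seqs) - suf),
             pre = pre, suf = suf, stringsAsFactors = FALSE)
}

# Fraction of character `ch` within s[from..to] (1-based, inclusive).
frac_char_ <- function(s, from, to, ch) {
  w <- to - from + 1L
  seg <- substr(s, from, to)
  hits <- nchar(seg) - nchar(gsub(ch, "", seg, fixed = TRUE))
  ifelse(w > 0L, hits / w, 1)
}

# Candidate motif offsets (1-based starts) per sequence via Biostrings.
# Matches overhanging the sequence ends (allowed by Biostrings when
# mismatches are permitted) are discarded: the full 9-mer must be read.
motif_hits_ <- function(seqs, motif, max_mismatch = 1L) {
  x <- Biostrings::DNAStringSet(seqs)
  m <- Biostrings::vmatchPattern(motif, x, max.mismatch = max_mismatch)
  idx <- Biostrings::startIndex(m)
  w <- nchar(motif)
  lens <- nchar(seqs)
  lapply(seq_along(idx), function(i) {
    h <- idx[[i]]
    if (is.null(h)) return(NULL)
    h[h >= 1L & h + w - 1L <= lens[i]]
  })
}

#' Classify reads into 5'-scar, 3'-scar and all-read streams
#'
#' Adapter trimming is applied first. A 3'-scar motif match
#' (`GCGAAAAAA`, Hamming distance <= 1) is valid when its GCG core is
#' exact, the single mismatch does not recreate the full GCGC
#' recognition sequence next to the core (such a match is an intact
#' site followed by a genomic A-run, not a scar), and the sequence from
#' the core to the read end is at least `run_purity` A. The 5'-scar rule
#' (`TTTTTTCGC`) is the mirror image. A read matching both motifs is
#' routed to the class whose motif is closer to its corresponding read
#' end; ties are dropped from the scar streams. Every read also enters
#' the all-read stream with terminal poly(T)/poly(A) runs of at least
#' `min_tail` removed.
#'
#' @param seqs character vector of read sequences (or a data.frame from
#'   [read_fastq()]).
#' @param qnames read names (defaults to names or index).
#' @param adapter constant adapter sequence.
#' @param min_tail minimum terminal homopolymer run removed in the
#'   all-read stream.
#' @param run_purity minimum A (resp. T) fraction between the scar core
#'   and the read end.
#' @return data.frame with per-read `qname`, `class`
#'   (`scar3`/`scar5`/`none`), scar payload `trimmed` and its 0-based
#'   coordinates in the original read (`keep_start`, `keep_end`), the
#'   all-read payload `all_trimmed` with `keep_all_start`,
#'   `keep_all_end`.
#' @export
classify_reads <- function(seqs, qnames = NULL, adapter = DEFAULT_ADAPTER,
                           min_tail = 6L, run_purity = 0.8) {
  if (is.data.frame(seqs)) {
    if (is.null(qnames)) qnames <- seqs$qname
    seqs <- seqs$seq
  }
  n <- length(seqs)
  if (is.null(qnames)) qnames <- as.character(seq_len(n))
  if (n == 0L) {
    return(data.frame(qname = character(), class = character(),
                      trimmed = character(), keep_start = integer(),
                      keep_end = integer(), all_trimmed = character(),
                      keep_all_start = integer(), keep_all_end = integer(),
                      stringsAsFactors = FALSE))
  }
  ad <- trim_adapter(seqs, adapter)
  s <- ad$seq
  len <- nchar(s)

  hits3 <- motif_hits_(s, MOTIF_SCAR3)
  hits5 <- motif_hits_(s, MOTIF_SCAR5)

  off3 <- rep(NA_integer_, n)
  off5 <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    h <- hits3[[i]]
    if (!is.null(h) && length(h)) {
      ok <- substr(rep(s[i], length(h)), h, h + 2L) == "GCG" &
        substr(rep(s[i], length(h)), h + 3L, h + 3L) != "C" &
        frac_char_(rep(s[i], length(h)), h + 3L, len[i], "A") >= run_purity
      if (any(ok)) off3[i] <- max(h[ok])
    }
    h <- hits5[[i]]
    if (!is.null(h) && length(h)) {
      ok <- substr(rep(s[i], length(h)), h + 6L, h + 8L) == "CGC" &
        substr(rep(s[i], length(h)), h + 5L, h + 5L) != "G" &
        frac_char_(rep(s[i], length(h)), 1L, h + 5L, "T") >= run_purity
      if (any(ok)) off5[i] <- min(h[ok])
    }
  }

  d3 <- len - (off3 + 8L)       # distance from motif end to 3' read end
  d5 <- off5 - 1L               # distance from read start to motif
  cls <- rep("none", n)
  cls[!is.na(off3) & is.na(off5)] <- "scar3"
  cls[is.na(off3) & !is.na(off5)] <- "scar5"
  both <- !is.na(off3) & !is.na(off5)
  cls[both & d3 < d5] <- "scar3"
  cls[both & d5 < d3] <- "scar5"   # ties stay "none" (kept in all-read)

  trimmed <- rep(NA_character_, n)
  keep_start <- rep(NA_integer_, n)
  keep_end <- rep(NA_integer_, n)
  i3 <- cls == "scar3"
  trimmed[i3] <- substr(s[i3], 1L, off3[i3] + 2L)
  keep_start[i3] <- ad$pre[i3]
  keep_end[i3] <- ad$pre[i3] + off3[i3] + 2L
  i5 <- cls == "scar5"
  trimmed[i5] <- substr(s[i5], off5[i5] + 6L, len[i5])
  keep_start[i5] <- ad$pre[i5] + off5[i5] + 5L
  keep_end[i5] <- ad$pre[i5] + len[i5]

  lead <- attr(regexpr(sprintf("^T{%d,}", min_tail), s), "match.length")
  lead[lead < 0L] <- 0L
  tail_ <- attr(regexpr(sprintf("A{%d,}$", min_tail), s), "match.length")
  tail_[tail_ < 0L] <- 0L
  all_trimmed <- substr(s, lead + 1L, len - tail_)

  data.frame(qname = qnames, class = cls, trimmed = trimmed,
             keep_start = keep_start, keep_end = keep_end,
             all_trimmed = all_trimmed,
             keep_all_start = ad$pre + lead,
             keep_all_end = ad$pre + len - tail_,
             stringsAsFactors = FALSE)
}

#' Classification stream counts
#' @param classified output of [classify_reads()].
#' @return named integer vector of stream sizes.
#' @export
stream_counts <- function(classified) {
  c(total = nrow(classified),
    scar5 = sum(classified$class == "scar5"),
    scar3 = sum(classified$class == "scar3"),
    none = sum(classified$class == "none"),
    allread = nrow(classified))
}

#' Write the classified streams as FASTQ files plus a TSV log
#'
#' @param classified output of [classify_reads()].
#' @param dir output directory.
#' @export
write_streams <- function(classified, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s3 <- classified[classified$class == "scar3", ]
  s5 <- classified[classified$class == "scar5", ]
  write_fastq(data.frame(qname = s3$qname, seq = s3$trimmed),
              file.path(dir, "scar3.fastq"))
  write_fastq(data.frame(qname = s5$qname, seq = s5$trimmed),
              file.path(dir, "scar5.fastq"))
  keep <- nzchar(classified$all_trimmed)
  write_fastq(data.frame(qname = classified$qname[keep],
                         seq = classified$all_trimmed[keep]),
              file.path(dir, "allread.fastq"))
  write.table(classified[, c("qname", "class")],
              file.path(dir, "classification.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  # full table (trim coordinates included) for downstream calling
  write.table(classified, file.path(dir, "classification_full.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
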