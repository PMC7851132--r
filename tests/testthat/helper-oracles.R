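# Independent brute-force oracles used to freeze expected values.

# Naive O(L) sliding-window motif scan (0-based starts).
naive_scan <- function(seq, motif = "GCGC") {
  L <- nchar(seq); w <- nchar(motif)
  if (L < w) return(integer())
  starts <- which(vapply(seq_len(L - w + 1L), function(i) {
    substr(seq, i, i + w - 1L) == motif
  }, logical(1)))
  starts - 1L
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Gini by the explicit mean-absolute-difference double sum.
gini_mad <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

# Pearson from the direct covariance/sd formula.
pearson_direct <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# A deterministic truth table for a site index with given allele bits.
make_truth <- function(sites, a1, a2) {
  structure(
    data.frame(contig = sites$contig, start = sites$start,
               allele1 = a1, allele2 = a2,
               blocked1 = a1 == 1L, blocked2 = a2 == 1L,
               state = (a1 + a2) / 2, stringsAsFactors = FALSE),
    cell_id = "truth", contig_lengths = attr(sites, "contig_lengths"),
    class = c("cell_truth", "data.frame"))
}

# Minimal cell_methylome constructor for aggregation tests.
make_methylome <- function(states, starts = seq_along(states) * 10L,
                           contig = "chr1", cell_id = "cell") {
  structure(
    data.frame(contig = rep_len(contig, length(states)), site_start = starts,
               cut = ifelse(states == 1, 0L, 1L),
               uncut = ifelse(states == 0, 0L, 1L),
               state = states, stringsAsFactors = FALSE),
    cell_id = cell_id, class = c("cell_methylome", "data.frame"))
}
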