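#' scarmeth: single-cell methylation from restriction-scar sequencing
#'
#' Core workflow: [find_sites()] enumerates HhaI recognition sites in a
#' reference, [simulate_cell()] generates a synthetic single-cell library
#' with ground truth, [classify_reads()] splits reads into 5'/3' scar and
#' all-read streams, [call_cell()] produces per-cell three-state
#' methylation calls, and the aggregation functions ([pseudo_bulk()],
#' [pairwise_concordance()], [window_matrix()], [correlation_cluster()])
#' combine cells. QC and genotyping live in [digestion_efficiency()] and
#' [ado_estimate()].
#'
#' All genomic coordinates are 0-based half-open internally; BED and
#' bedGraph conventions are used on disk.
#'
#' @keywords internal
#' @importFrom methods is
#' @importFrom stats cor hclust as.dist rbinom rbeta rpois runif rlnorm
#' @importFrom utils write.table read.table
"_PACKAGE"

# The HhaI recognition sequence. GCGC is its own reverse complement, so a
# single forward-strand scan enumerates all sites on both strands.
HHAI_MOTIF <- "GCGC"

#' Run code with a fixed, local RNG seed
#'
#' @param seed integer seed or NULL (use current RNG stream).
#' @param code expression to evaluate.
#' @noRd
with_seed_ <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' Read a reference genome from FASTA
#'
#' Sequences are uppercased so that soft-masked (lowercase) bases are
#' scanned like any other; `N` never matches the recognition motif.
#'
#' @param path path to a (optionally gzipped) FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  g <- toupper(as.character(x))
  names(g) <- sub("\\s.*$", "", names(x))
  as_genome(g)
}

#' Validate/normalise a genome object
#' @noRd
as_genome <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    g <- as.character(genome)
    names(g) <- names(genome)
    genome <- g
  }
  if (!is.character(genome) || is.null(names(genome)) ||
      anyDuplicated(names(genome)) || any(!nzchar(genome))) {
    stop("genome must be a named character vector (or DNAStringSet) of ",
         "non-empty sequences with unique contig names")
  }
  toupper(genome)
}

contig_lengths <- function(genome) {
  vapply(genome, nchar, integer(1))
}

#' Enumerate HhaI recognition sites (GCGC) in a genome
#'
#' Every occurrence of GCGC is indexed, including overlapping occurrences
#' (GCGCGC yields two sites). Because the motif is palindromic a forward
#' scan is complete. The internal CpG of a site starting at `p` occupies
#' `[p+1, p+3)`.
#'
#' @param genome named character vector (see [read_genome()]).
#' @return a `scar_sites` data.frame with columns `contig`, `start`
#'   (0-based site start), `informative` (logical, all `TRUE` until
#'   [annotate_informative()] is applied). Carries contig lengths as an
#'   attribute.
#' @examples
#' find_sites(c(chr1 = "AAGCGCTT"))
#' @export
find_sites <- function(genome) {
  genome <- as_genome(genome)
  hits <- lapply(names(genome), function(ctg) {
    m <- Biostrings::matchPattern(HHAI_MOTIF, Biostrings::DNAString(genome[[ctg]]))
    st <- Biostrings::start(m) - 1L  # to 0-based
    if (length(st) == 0L) return(NULL)
    data.frame(contig = ctg, start = st, stringsAsFactors = FALSE)
  })
  hits <- Filter(Negate(is.null), hits)
  out <- if (length(hits)) do.call(rbind, hits) else {
    data.frame(contig = character(), start = integer(),
               stringsAsFactors = FALSE)
  }
  out$informative <- rep(TRUE, nrow(out))
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            contig_lengths = contig_lengths(genome),
            informative_annotated = FALSE,
            class = c("scar_sites", "data.frame"))
}

#' @export
print.scar_sites <- function(x, ...) {
  cat(sprintf("HhaI site index: %d sites on %d contig(s); informative: %d%s\n",
              nrow(x), length(unique(x$contig)), sum(x$informative),
              if (isTRUE(attr(x, "informative_annotated"))) " (annotated)" else ""))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Count recognition-site occurrences with and without overlap
#'
#' Reports both the full count (overlapping GCGC occurrences as separate
#' sites, as indexed by [find_sites()]) and the count after collapsing
#' overlapping runs (greedy non-overlapping scan), since published genome
#' totals may use either convention.
#'
#' @param sites a `scar_sites` index.
#' @return list with `n_all` and `n_nonoverlapping`.
#' @export
count_sites <- function(sites) {
  n_all <- nrow(sites)
  n_no <- 0L
  for (ctg in unique(sites$contig)) {
    st <- sites$start[sites$contig == ctg]
    last <- -4L
    for (p in st) {
      if (p >= last + 4L) { n_no <- n_no + 1L; last <- p }
    }
  }
  list(n_all = n_all, n_nonoverlapping = n_no)
}

#' Flag sites whose CpG is covered by a bulk methylome
#'
#' A site is informative when its internal CpG (interval `[p+1, p+3)`) is
#' present in the bulk CpG table; with no table every site is informative
#' by default and downstream calling emits all sites.
#'
#' @param sites a `scar_sites` index.
#' @param bulk_cpgs data.frame with columns `contig` and `cpg_start`
#'   (0-based start of the covered CpG dinucleotide), or `NULL`.
#' @return the index with `informative` updated.
#' @export
annotate_informative <- function(sites, bulk_cpgs = NULL) {
  if (is.null(bulk_cpgs)) {
    sites$informative <- rep(TRUE, nrow(sites))
    attr(sites, "informative_annotated") <- FALSE
    return(sites)
  }
  stopifnot(all(c("contig", "cpg_start") %in% names(bulk_cpgs)))
  known <- unique(sites$contig)
  bad <- setdiff(unique(bulk_cpgs$contig), known)
  if (length(bad) && nrow(sites)) {
    stop("bulk CpG table names contig(s) absent from the site index: ",
         paste(bad, collapse = ", "))
  }
  key <- paste(sites$contig, sites$start + 1L)
  sites$informative <- key %in% paste(bulk_cpgs$contig, bulk_cpgs$cpg_start)
  attr(sites, "informative_annotated") <- TRUE
  sites
}

#' Site-density profile around anchor features
#'
#' Counts recognition-site starts in fixed windows tiled across
#' `[anchor - flank, anchor + flank)`, summed over anchors. The anchor
#' point is the feature start for `+`/unstranded features and the feature
#' end for `-` features, whose window order is flipped so that upstream
#' windows come first.
#'
#' @param sites a `scar_sites` index.
#' @param anchors data.frame with `contig`, `start`, `end` (0-based
#'   half-open) and optional `strand` (`+`, `-`, `.`).
#' @param window_bp window width in bp.
#' @param flank_bp flank on each side; must be a multiple of `window_bp`.
#' @return integer vector of length `2*flank_bp/window_bp` with one count
#'   per window, upstream first.
#' @export
site_density_profile <- function(sites, anchors, window_bp = 100L,
                                 flank_bp = 3000L) {
  if (is.null(anchors) || nrow(anchors) == 0L) stop("no anchor features supplied")
  if (flank_bp %% window_bp != 0L) stop("flank_bp must be a multiple of window_bp")
  nw <- as.integer(2L * flank_bp / window_bp)
  strand <- if ("strand" %in% names(anchors)) as.character(anchors$strand) else rep(".", nrow(anchors))
  counts <- integer(nw)
  for (i in seq_len(nrow(anchors))) {
    neg <- identical(strand[i], "-")
    point <- if (neg) anchors$end[i] else anchors$start[i]
    st <- sites$start[sites$contig == anchors$contig[i]]
    rel <- st - (point - flank_bp)
    w <- floor(rel / window_bp)
    w <- w[w >= 0L & w < nw] + 1L
    tab <- tabulate(w, nbins = nw)
    if (neg) tab <- rev(tab)
    counts <- counts + tab
  }
  counts
}

#' Write a site index as 6-column BED
#'
#' Name is the site ordinal, score encodes the informative flag (0/1).
#'
#' @param sites a `scar_sites` index.
#' @param path output path.
#' @export
write_sites_bed <- function(sites, path) {
  gr <- GenomicRanges::GRanges(
    sites$contig,
    IRanges::IRanges(start = sites$start + 1L, width = 4L),
    strand = "*",
    name = paste0("site", seq_len(nrow(sites))),
    score = as.integer(sites$informative))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read feature intervals from a BED file
#'
#' @param path BED path.
#' @return data.frame with 0-based half-open `contig`, `start`, `end`,
#'   `strand`.
#' @export
read_features_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Sites overlapping a query interval
#'
#' @param sites a `scar_sites` index.
#' @param contig,start,end query interval (0-based half-open).
#' @return subset of the index whose `[p, p+4)` interval intersects the
#'   query.
#' @export
sites_overlapping <- function(sites, contig, start, end) {
  keep <- sites$contig == contig & sites$start < end & (sites$start + 4L) > start
  sites[keep, , drop = FALSE]
}
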