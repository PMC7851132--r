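# Per-cell three-state methylation calling.
#
# Cut evidence: a scar read's alignment, reduced to the outermost three
# nucleotides on its scar side, must coincide nucleotide-precisely with
# the scar geometry of a recognition site. A cut at site start p leaves
# GCG at [p, p+3) on the upstream product and CGC at [p+1, p+4) on the
# downstream product, so the expected anchor depends on which end is
# observed; reads sequenced from the opposite strand swap motif class,
# which makes the matching rule a function of (class, strand):
#   scar3/+ and scar5/-  ->  anchor [p, p+3)
#   scar5/+ and scar3/-  ->  anchor [p+1, p+4)
# Intact (uncut) evidence: an all-read alignment completely covering the
# site expanded by 1 bp on each side, [p-1, p+5).

#' Read alignments from a SAM file
#'
#' The SAM is converted to BAM internally and parsed with the standard
#' Bioconductor machinery; a missing header is an error.
#'
#' @param path SAM (or BAM) path.
#' @return data.frame with `qname`, `contig`, `g_start`/`g_end`
#'   (0-based half-open reference span), `strand`, `mapq`, `flag`,
#'   soft-clip lengths `lclip`/`rclip` (reference orientation) and
#'   `readlen` (query width including clips).
#' @export
read_alignments <- function(path) {
  bam <- if (grepl("\\.bam$", path, ignore.case = TRUE)) path else {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  }
  ga <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(what = c("qname", "flag", "mapq")))
  cig <- GenomicAlignments::cigar(ga)
  lclip <- rep(0L, length(cig))
  has <- grepl("^[0-9]+S", cig)
  lclip[has] <- as.integer(sub("^([0-9]+)S.*", "\\1", cig[has]))
  rclip <- rep(0L, length(cig))
  has <- grepl("[A-Z][0-9]+S$", cig)
  rclip[has] <- as.integer(sub(".*[A-Z]([0-9]+)S$", "\\1", cig[has]))
  mc <- S4Vectors::mcols(ga)
  data.frame(qname = mc$qname,
             contig = as.character(GenomicAlignments::seqnames(ga)),
             g_start = GenomicAlignments::start(ga) - 1L,
             g_end = GenomicAlignments::end(ga),
             strand = as.character(GenomicAlignments::strand(ga)),
             mapq = mc$mapq, flag = mc$flag,
             lclip = lclip, rclip = rclip,
             readlen = GenomicAlignments::qwidth(ga),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter alignments for calling
#'
#' Keeps primary mapped alignments with MAPQ >= 10 (threshold is
#' exclusive below: MAPQ 10 is kept, 9 is removed); secondary and
#' supplementary alignments are dropped.
#'
#' @param aln alignment data.frame (see [read_alignments()]).
#' @param min_mapq MAPQ cutoff.
#' @return filtered data.frame.
#' @export
filter_alignments <- function(aln, min_mapq = 10L) {
  keep <- aln$mapq >= min_mapq &
    bitwAnd(aln$flag, 4L) == 0L &
    bitwAnd(aln$flag, 256L) == 0L &
    bitwAnd(aln$flag, 2048L) == 0L
  aln[keep, , drop = FALSE]
}

#' Reduce alignments to their outermost three nucleotides
#'
#' The read's biological 5' or 3' end in reference coordinates: on the
#' `+` strand the 3' end is at the reference end, on the `-` strand at
#' the reference start.
#'
#' @param aln alignment data.frame with `contig`, `g_start`, `g_end`,
#'   `strand`.
#' @param side `"5prime"` or `"3prime"`.
#' @return data.frame of 3-bp anchor intervals (`contig`, `start`,
#'   `end`, `strand`, plus any `qname`/`class` columns carried along);
#'   alignments spanning fewer than 3 bp are dropped with a warning.
#' @export
anchor_interval <- function(aln, side = c("3prime", "5prime")) {
  side <- match.arg(side)
  short <- (aln$g_end - aln$g_start) < 3L
  if (any(short)) {
    warning(sum(short), " alignment(s) shorter than 3 bp skipped")
    aln <- aln[!short, , drop = FALSE]
  }
  at_start <- (side == "5prime") == (aln$strand == "+")
  start <- ifelse(at_start, aln$g_start, aln$g_end - 3L)
  out <- data.frame(contig = aln$contig, start = start, end = start + 3L,
                    strand = aln$strand, stringsAsFactors = FALSE)
  for (col in intersect(c("qname", "class"), names(aln))) out[[col]] <- aln[[col]]
  out
}

# Expected site start implied by a scar anchor, given class and strand.
anchor_site_start_ <- function(start, class, strand) {
  ifelse((class == "scar3") == (strand == "+"), start, start - 1L)
}

#' Call cut sites from scar anchors
#'
#' Each anchor votes for the unique site start consistent with the scar
#' geometry for its (class, strand) combination; anchors matching no
#' recognition site are discarded.
#'
#' @param anchors5 anchor data.frame for the 5'-scar stream (side
#'   `5prime`), with a `strand` column.
#' @param anchors3 anchor data.frame for the 3'-scar stream (side
#'   `3prime`).
#' @param sites a `scar_sites` index.
#' @return data.frame `contig`, `site_start`, `cut` (evidence count).
#' @export
call_cut_sites <- function(anchors5, anchors3, sites) {
  an <- rbind(
    if (!is.null(anchors3) && nrow(anchors3)) {
      data.frame(contig = anchors3$contig,
                 p = anchor_site_start_(anchors3$start, "scar3", anchors3$strand))
    },
    if (!is.null(anchors5) && nrow(anchors5)) {
      data.frame(contig = anchors5$contig,
                 p = anchor_site_start_(anchors5$start, "scar5", anchors5$strand))
    })
  empty <- data.frame(contig = character(), site_start = integer(),
                      cut = integer(), stringsAsFactors = FALSE)
  if (is.null(an) || nrow(an) == 0L) return(empty)
  hit <- match(paste(an$contig, an$p), paste(sites$contig, sites$start))
  an <- an[!is.na(hit), , drop = FALSE]
  if (nrow(an) == 0L) return(empty)
  agg <- stats::aggregate(list(cut = rep(1L, nrow(an))),
                          by = list(contig = an$contig, site_start = an$p),
                          FUN = sum)
  agg[order(agg$contig, agg$site_start), , drop = FALSE]
}

#' Call uncut (intact) sites from all-read alignments
#'
#' A site gains intact evidence from every all-read alignment completely
#' containing its 1-bp-expanded interval `[p-1, p+5)`. Sites at contig
#' boundaries (margin undefined) are skipped. A candidate intact site is
#' excluded when a different, genomically overlapping site carries cut
#' evidence in the same cell (the `GCGCG(A)n` configuration), since
#' complete digestion next to a fresh DNA end cannot be guaranteed;
#' intact evidence at the cut site itself is kept and resolved by
#' [call_state()] as heterozygous.
#'
#' @param aln all-read alignment data.frame (`contig`, `g_start`,
#'   `g_end`).
#' @param sites a `scar_sites` index (contig lengths attribute is used
#'   for the boundary check).
#' @param cut_calls output of [call_cut_sites()] for the same cell.
#' @return data.frame `contig`, `site_start`, `uncut` (evidence count).
#' @export
call_uncut_sites <- function(aln, sites, cut_calls = NULL) {
  lens <- attr(sites, "contig_lengths")
  p <- sites$start
  ok <- p - 1L >= 0L
  if (!is.null(lens)) ok <- ok & (p + 5L) <= lens[sites$contig]
  cand <- sites[ok, , drop = FALSE]
  empty <- data.frame(contig = character(), site_start = integer(),
                      uncut = integer(), stringsAsFactors = FALSE)
  if (nrow(cand) == 0L || is.null(aln) || nrow(aln) == 0L) return(empty)
  qry <- GenomicRanges::GRanges(cand$contig,
                                IRanges::IRanges(cand$start, width = 6L))
  sbj <- GenomicRanges::GRanges(aln$contig,
                                IRanges::IRanges(aln$g_start + 1L, aln$g_end))
  n <- GenomicRanges::countOverlaps(qry, sbj, type = "within")
  out <- data.frame(contig = cand$contig, site_start = cand$start,
                    uncut = as.integer(n), stringsAsFactors = FALSE)
  out <- out[out$uncut > 0L, , drop = FALSE]
  if (!is.null(cut_calls) && nrow(cut_calls) && nrow(out)) {
    cutkey <- paste(cut_calls$contig, cut_calls$site_start)
    excluded <- vapply(seq_len(nrow(out)), function(i) {
      nb <- out$site_start[i] + c(-3L, -2L, -1L, 1L, 2L, 3L)
      any(paste(out$contig[i], nb) %in% cutkey)
    }, logical(1))
    out <- out[!excluded, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Combine cut and intact evidence into three-state methylation calls
#'
#' Only cut evidence gives state 0 (unmethylated), only intact evidence
#' state 1 (methylated), both at the same site state 0.5 (heterozygous
#' methylation). Sites with total evidence below `min_evidence` are
#' absent; when the site index carries an informative annotation, only
#' informative sites are emitted.
#'
#' @param cut_calls,uncut_calls outputs of [call_cut_sites()] and
#'   [call_uncut_sites()] for one cell.
#' @param sites a `scar_sites` index.
#' @param min_evidence minimum total evidence per site.
#' @param cell_id cell identifier.
#' @return a `cell_methylome` data.frame with `contig`, `site_start`,
#'   `cut`, `uncut`, `state`.
#' @export
call_state <- function(cut_calls, uncut_calls, sites, min_evidence = 1L,
                       cell_id = "cell1") {
  m <- merge(cut_calls, uncut_calls, by = c("contig", "site_start"),
             all = TRUE)
  m$cut[is.na(m$cut)] <- 0L
  m$uncut[is.na(m$uncut)] <- 0L
  m <- m[m$cut + m$uncut >= min_evidence, , drop = FALSE]
  m$state <- ifelse(m$cut > 0L & m$uncut > 0L, 0.5,
                    ifelse(m$cut > 0L, 0, 1))
  if (isTRUE(attr(sites, "informative_annotated"))) {
    key <- paste(sites$contig, sites$start)[sites$informative]
    m <- m[paste(m$contig, m$site_start) %in% key, , drop = FALSE]
  }
  m <- m[order(m$contig, m$site_start), , drop = FALSE]
  rownames(m) <- NULL
  structure(m, cell_id = cell_id,
            class = c("cell_methylome", "data.frame"))
}

#' @export
print.cell_methylome <- function(x, ...) {
  cat(sprintf("cell methylome '%s': %d sites (0: %d, 0.5: %d, 1: %d)\n",
              attr(x, "cell_id") %||% "?", nrow(x),
              sum(x$state == 0), sum(x$state == 0.5), sum(x$state == 1)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reference span of the retained read region after trimming.
#
# keep_start/keep_end are 0-based coordinates in the read as sequenced
# (FASTQ orientation); the alignment gives the reference span of the
# genomic portion with soft clips lclip/rclip in reference orientation.
# Assumes gap-free alignments, which is what the simulator emits.
trimmed_span_ <- function(aln, keep_start, keep_end) {
  ks <- ifelse(aln$strand == "+", keep_start, aln$readlen - keep_end)
  ke <- ifelse(aln$strand == "+", keep_end, aln$readlen - keep_start)
  a <- pmax(ks, aln$lclip)
  b <- pmin(ke, aln$lclip + (aln$g_end - aln$g_start))
  data.frame(contig = aln$contig,
             g_start = aln$g_start + (a - aln$lclip),
             g_end = aln$g_start + (b - aln$lclip),
             strand = aln$strand,
             ok = b - a >= 3L,
             stringsAsFactors = FALSE)
}

#' Call one cell's methylome from alignments plus read classes
#'
#' Joins an alignment table with the classification table by read name,
#' applies alignment filtering, restricts every alignment to the
#' retained (trimmed) read region, derives scar anchors and intact
#' coverage, and combines them with [call_state()].
#'
#' @param aln alignment data.frame from [read_alignments()] (or the
#'   simulator truth table).
#' @param classified output of [classify_reads()] for the same reads.
#' @param sites a `scar_sites` index.
#' @param min_evidence minimum total evidence per site.
#' @param min_mapq MAPQ cutoff.
#' @param cell_id cell identifier.
#' @return a `cell_methylome`.
#' @export
call_cell <- function(aln, classified, sites, min_evidence = 1L,
                      min_mapq = 10L, cell_id = "cell1") {
  aln <- filter_alignments(aln, min_mapq)
  idx <- match(aln$qname, classified$qname)
  aln <- aln[!is.na(idx), , drop = FALSE]
  cl <- classified[idx[!is.na(idx)], , drop = FALSE]

  anchors <- list(scar5 = NULL, scar3 = NULL)
  for (klass in c("scar5", "scar3")) {
    sel <- cl$class == klass
    if (!any(sel)) next
    sp <- trimmed_span_(aln[sel, , drop = FALSE],
                        cl$keep_start[sel], cl$keep_end[sel])
    sp <- sp[sp$ok, , drop = FALSE]
    if (nrow(sp)) {
      anchors[[klass]] <- anchor_interval(
        sp, side = if (klass == "scar3") "3prime" else "5prime")
    }
  }
  cut_calls <- call_cut_sites(anchors$scar5, anchors$scar3, sites)

  keep <- nzchar(cl$all_trimmed)
  spa <- trimmed_span_(aln[keep, , drop = FALSE],
                       cl$keep_all_start[keep], cl$keep_all_end[keep])
  spa <- spa[spa$ok, , drop = FALSE]
  uncut_calls <- call_uncut_sites(spa, sites, cut_calls)

  call_state(cut_calls, uncut_calls, sites, min_evidence, cell_id)
}

#' Write a cell methylome as bedGraph
#'
#' One record per called site over its CpG dinucleotide interval
#' `[p+1, p+3)` with value in `{0, 0.5, 1}`, sorted; an empty methylome
#' yields a file with only the track header.
#'
#' @param methylome a `cell_methylome`.
#' @param path output path.
#' @export
write_bedgraph <- function(methylome, path) {
  header <- sprintf("track type=bedGraph name=\"%s\"",
                    attr(methylome, "cell_id") %||% "cell")
  if (nrow(methylome) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  m <- methylome[order(methylome$contig, methylome$site_start), ]
  writeLines(c(header,
               sprintf("%s\t%d\t%d\t%s", m$contig, m$site_start + 1L,
                       m$site_start + 3L, format(m$state, trim = TRUE))),
             path)
  invisible(path)
}

#' Read a per-cell bedGraph back into a methylome
#'
#' Evidence counts are not stored in bedGraph and come back as `NA`.
#'
#' @param path bedGraph path.
#' @param cell_id cell identifier.
#' @return a `cell_methylome`.
#' @export
read_cell_bedgraph <- function(path, cell_id = basename(path)) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  m <- data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
                  site_start = GenomicRanges::start(gr) - 2L,
                  cut = NA_integer_, uncut = NA_integer_,
                  state = as.numeric(gr$score),
                  stringsAsFactors = FALSE)
  structure(m[order(m$contig, m$site_start), , drop = FALSE],
            cell_id = cell_id, class = c("cell_methylome", "data.frame"))
}
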