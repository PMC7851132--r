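# Spike-in digestion-efficiency QC and coverage uniformity.

# Assign reads to a control amplicon by exact 21-mer containment and
# infer the gap-free span of each read on the control. Returns NA rows
# for unassigned reads.
assign_to_control_ <- function(seqs, control_seq, k = 21L, n_probes = 5L) {
  L <- nchar(control_seq)
  kmers <- substring(control_seq, seq_len(L - k + 1L), seq(k, L))
  locate <- function(ss) {
    n <- length(ss)
    start <- rep(NA_integer_, n)
    len <- nchar(ss)
    todo <- which(len >= k)
    for (j in seq_len(n_probes)) {
      if (!length(todo)) break
      off <- pmax(1L, pmin(len[todo] - k + 1L,
                           1L + round((j - 1L) / max(1L, n_probes - 1L) *
                                        (len[todo] - k))))
      probe <- substr(ss[todo], off, off + k - 1L)
      hit <- match(probe, kmers)
      found <- !is.na(hit)
      start[todo[found]] <- hit[found] - off[found]  # 0-based read start
      todo <- todo[!found]
    }
    start
  }
  fwd <- locate(seqs)
  need_rc <- is.na(fwd)
  rc_seq <- seqs
  rc_seq[need_rc] <- revcomp_(seqs[need_rc])
  rc <- rep(NA_integer_, length(seqs))
  rc[need_rc] <- locate(rc_seq[need_rc])
  strand <- ifelse(!is.na(fwd), "+", ifelse(!is.na(rc), "-", NA))
  start <- ifelse(!is.na(fwd), fwd, rc)
  data.frame(g_start = start, g_end = start + nchar(seqs),
             strand = strand, stringsAsFactors = FALSE)
}

#' Estimate digestion efficiency from spike-in control reads
#'
#' Classified reads are assigned to the control amplicon by exact 21-mer
#' containment, and the control's single recognition site is then
#' genotyped with the standard calling rules: scar-classified reads
#' whose anchors match the site's scar geometry are cleaved-end
#' coverage, and all-reads completely covering the 1-bp-expanded site
#' are intact coverage. Because every cleavage event exposes two
#' scarred ends while an intact site is a single locus, the scar
#' coverage is halved before forming
#' `efficiency = scar / (scar + intact)`.
#'
#' @param classified output of [classify_reads()] on the cell's reads.
#' @param control a spike-in control (see [spikein_control()]).
#' @param k k-mer length for read assignment.
#' @return a `spikein_report` list: `name`, `scar` (per-cleavage scar
#'   coverage), `scar3_reads`, `scar5_reads`, `intact` (intact read
#'   count), `efficiency` (`NA` when no spike-in read is detected) and
#'   `complete_digestion`.
#' @export
digestion_efficiency <- function(classified, control, k = 21L) {
  p <- control$site_start
  sites <- structure(
    data.frame(contig = control$name, start = p, informative = TRUE,
               stringsAsFactors = FALSE),
    contig_lengths = stats::setNames(nchar(control$seq), control$name),
    informative_annotated = FALSE,
    class = c("scar_sites", "data.frame"))

  n3 <- 0L; n5 <- 0L
  for (klass in c("scar3", "scar5")) {
    sel <- which(classified$class == klass)
    if (!length(sel)) next
    asg <- assign_to_control_(classified$trimmed[sel], control$seq, k)
    ok <- !is.na(asg$strand) & asg$g_start >= 0L &
      asg$g_end <= nchar(control$seq)
    if (!any(ok)) next
    an <- anchor_interval(
      cbind(asg[ok, , drop = FALSE],
            contig = control$name, stringsAsFactors = FALSE),
      side = if (klass == "scar3") "3prime" else "5prime")
    hit <- anchor_site_start_(an$start, klass, an$strand) == p
    if (klass == "scar3") n3 <- sum(hit) else n5 <- sum(hit)
  }

  all_sel <- which(nzchar(classified$all_trimmed))
  intact <- 0L
  if (length(all_sel)) {
    asg <- assign_to_control_(classified$all_trimmed[all_sel], control$seq, k)
    ok <- !is.na(asg$strand)
    intact <- sum(ok & asg$g_start <= p - 1L & asg$g_end >= p + 5L)
  }

  scar <- (n3 + n5) / 2
  eff <- if (scar + intact == 0) NA_real_ else scar / (scar + intact)
  if (is.na(eff)) message("no spike-in detected for control '",
                          control$name, "'")
  structure(list(name = control$name, scar = scar, scar3_reads = n3,
                 scar5_reads = n5, intact = intact, efficiency = eff,
                 complete_digestion = intact == 0L && scar > 0),
            class = "spikein_report")
}

#' @export
print.spikein_report <- function(x, ...) {
  cat(sprintf("spike-in '%s': scar %.1f, intact %d -> efficiency %s%s\n",
              x$name, x$scar, x$intact,
              if (is.na(x$efficiency)) "undetected"
              else sprintf("%.4f", x$efficiency),
              if (isTRUE(x$complete_digestion)) " (complete digestion)" else ""))
  invisible(x)
}

#' Coverage uniformity as a Gini coefficient with Lorenz points
#'
#' Gini via the mean-absolute-difference formula (computed through the
#' sorted-weights identity); 0 for constant positive depth, approaching
#' 1 as coverage concentrates.
#'
#' @param depth nonnegative depth vector, length >= 2, not all zero.
#' @return list with `gini` and `lorenz` (data.frame of cumulative
#'   population and coverage fractions).
#' @export
coverage_uniformity <- function(depth) {
  if (length(depth) < 2L) stop("depth vector must have length >= 2")
  if (any(depth < 0)) stop("depths must be nonnegative")
  if (all(depth == 0)) stop("all-zero depth vector: Gini undefined")
  x <- sort(depth)
  n <- length(x)
  gini <- 2 * sum(seq_len(n) * x) / (n * sum(x)) - (n + 1) / n
  lorenz <- data.frame(p = seq_len(n) / n, L = cumsum(x) / sum(x))
  list(gini = gini, lorenz = lorenz)
}

#' Assemble a per-cell QC report and write it as JSON
#'
#' @param spikein_reports list of `spikein_report` objects (possibly
#'   empty).
#' @param stream_counts named counts from [stream_counts()].
#' @param gini optional Gini coefficient from [coverage_uniformity()].
#' @param path output JSON path.
#' @return the report list, invisibly.
#' @export
write_qc_report <- function(spikein_reports, stream_counts, gini = NULL,
                            path) {
  rep <- list(
    streams = as.list(stream_counts),
    spikeins = lapply(spikein_reports, function(x) x[names(x) != "class"]),
    gini = gini)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(rep)
}
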