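# Truth-based evaluation of a called methylome against simulator ground
# truth. The simulator's truth bundle knows, read by read, which scarred
# ends and which intact site intervals were cleanly observable, so
# recovery can be scored over the sites where the library actually
# carries full evidence.

#' Score a called methylome against simulator truth
#'
#' A site has *full evidence coverage* when the emitted reads cleanly
#' observe every piece of evidence its truth state implies:
#' \itemize{
#'   \item an unmethylated (cut) allele needs at least one read that
#'     covers one of its scarred ends together with >= 6 tail bases,
#'     ending either inside the tail or far enough into the adapter
#'     that adapter trimming applies, and covering exactly one scar end
#'     (reads spanning both ends of a short molecule can be discarded
#'     by the chimera tie-break);
#'   \item a methylated (intact) allele needs at least one all-read
#'     whose genomic span covers the 1-bp-expanded site with an extra
#'     `margin` on both sides (so that partial-adapter and terminal-run
#'     trimming cannot shorten the span into the site).
#' }
#' Sites overlapping another recognition site (GCGCGC runs) are
#' excluded from the denominator: the calling rules deliberately
#' abstain there. False heterozygous calls are counted over all called
#' sites, not only fully covered ones.
#'
#' @param sim output of [simulate_cell()].
#' @param methylome the `cell_methylome` called from the same library.
#' @param margin extra clean-span margin in bp for intact evidence.
#' @return list with `per_site` (truth state, called state, coverage
#'   flag per site), `n_full`, `n_called_full`, `accuracy` (fraction of
#'   fully covered sites called with the true state), `het_total`,
#'   `het_detected` (fully covered discordant sites called 0.5) and
#'   `false_het` (called 0.5 at truth-concordant sites).
#' @export
evaluate_recovery <- function(sim, methylome, margin = 8L) {
  truth <- sim$truth
  mols <- sim$molecules
  aln <- sim$aln
  m <- mols[aln$mol_id, , drop = FALSE]

  # clean scar-end observations per read
  end3 <- m$goff + m$glen
  c3 <- m$right == "scar3" & aln$ws <= end3 - 3L & aln$we >= end3 + 6L &
    (aln$we <= end3 + m$tail_right |
       aln$we >= end3 + m$tail_right + margin)
  c5 <- m$left == "scar5" & aln$we >= m$goff + 3L &
    aln$ws <= m$goff - 6L &
    (aln$ws >= m$goff - m$tail_left |
       aln$ws <= m$goff - m$tail_left - margin)
  clean3 <- c3 & !c5
  clean5 <- c5 & !c3

  key <- function(ctg, p) paste(ctg, p)
  scar_seen <- unique(c(
    key(m$contig[clean3], paste(m$g_end[clean3] - 3L, m$allele[clean3])),
    key(m$contig[clean5], paste(m$g_start[clean5] - 1L, m$allele[clean5]))))

  # clean intact spans per (site, allele)
  intact_seen <- character()
  mapped <- !is.na(aln$g_start)
  if (any(mapped)) {
    am <- aln[mapped, , drop = FALSE]
    for (i in seq_len(nrow(truth))) {
      p <- truth$start[i]
      hit <- am$contig == truth$contig[i] &
        am$g_start <= p - 1L - margin & am$g_end >= p + 5L + margin
      if (any(hit)) {
        intact_seen <- c(intact_seen,
                         key(truth$contig[i], paste(p, unique(am$allele[hit]))))
      }
    }
  }

  has_scar <- function(i, allele) {
    key(truth$contig[i], paste(truth$start[i], allele)) %in% scar_seen
  }
  has_intact <- function(i, allele) {
    key(truth$contig[i], paste(truth$start[i], allele)) %in% intact_seen
  }

  overlapping <- vapply(seq_len(nrow(truth)), function(i) {
    any(truth$contig == truth$contig[i] &
          truth$start != truth$start[i] &
          abs(truth$start - truth$start[i]) < 4L)
  }, logical(1))

  full <- vapply(seq_len(nrow(truth)), function(i) {
    a <- c(truth$allele1[i], truth$allele2[i])
    ok <- TRUE
    for (al in 1:2) {
      need <- if (a[al] == 0L) has_scar(i, al) else has_intact(i, al)
      ok <- ok && need
    }
    ok
  }, logical(1)) & !overlapping

  called <- rep(NA_real_, nrow(truth))
  i <- match(key(methylome$contig, methylome$site_start),
             key(truth$contig, truth$start))
  called[i[!is.na(i)]] <- methylome$state[!is.na(i)]

  per_site <- data.frame(contig = truth$contig, start = truth$start,
                         truth = truth$state, called = called,
                         full_coverage = full,
                         stringsAsFactors = FALSE)
  n_full <- sum(full)
  acc <- if (n_full) mean(!is.na(called[full]) &
                            called[full] == truth$state[full]) else NA_real_
  het_full <- full & truth$state == 0.5
  list(per_site = per_site,
       n_full = n_full,
       n_called_full = sum(full & !is.na(called)),
       accuracy = acc,
       het_total = sum(het_full),
       het_detected = sum(het_full & !is.na(called) & called == 0.5),
       false_het = sum(!is.na(called) & called == 0.5 & truth$state != 0.5))
}
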