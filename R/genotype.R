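# Naive per-cell genotyping and allelic-dropout estimation.

#' Define heterozygous truth loci from variant allele frequencies
#'
#' Loci with bulk VAF between 0.45 and 0.55 (inclusive) are taken as
#' heterozygous.
#'
#' @param table data.frame with `contig`, `pos` and `vaf` in `[0, 1]`.
#' @param band inclusive VAF bounds.
#' @return data.frame of heterozygous loci (`contig`, `pos`).
#' @export
het_truth_from_vaf <- function(table, band = c(0.45, 0.55)) {
  stopifnot(all(table$vaf >= 0), all(table$vaf <= 1))
  keep <- table$vaf >= band[1] & table$vaf <= band[2]
  out <- unique(table[keep, c("contig", "pos"), drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Naive pileup genotyper
#'
#' Loci below `min_depth` are no-calls; otherwise the alternate-allele
#' fraction decides: below the band, homozygous reference; above it,
#' homozygous alternate; inside, heterozygous.
#'
#' @param pileup data.frame with `contig`, `pos`, `ref_count`,
#'   `alt_count` (and optionally `other_count`).
#' @param min_depth minimum depth for a call.
#' @param het_band exclusive lower/upper alt-fraction bounds of the
#'   heterozygous call.
#' @return data.frame with `contig`, `pos`, `depth`, `alt_fraction`,
#'   `call` in `{hom_ref, het, hom_alt, no_call}`.
#' @export
naive_genotype <- function(pileup, min_depth = 10L,
                           het_band = c(0.1, 0.9)) {
  stopifnot(all(pileup$ref_count >= 0), all(pileup$alt_count >= 0))
  other <- pileup$other_count %||% 0L
  depth <- pileup$ref_count + pileup$alt_count + other
  af <- ifelse(depth > 0L, pileup$alt_count / depth, NA_real_)
  call <- ifelse(depth < min_depth, "no_call",
          ifelse(af < het_band[1], "hom_ref",
          ifelse(af > het_band[2], "hom_alt", "het")))
  data.frame(contig = pileup$contig, pos = pileup$pos, depth = depth,
             alt_fraction = af, call = call, stringsAsFactors = FALSE)
}

#' Allelic-dropout estimate against a heterozygous truth set
#'
#' Eligible loci are truth-heterozygous loci genotyped (not no-call) at
#' depth >= `min_depth`; the ADO fraction is the share of eligible loci
#' called homozygous (either allele).
#'
#' @param truth data.frame of heterozygous truth loci (`contig`, `pos`).
#' @param calls output of [naive_genotype()].
#' @param min_depth coverage cutoff.
#' @return list with `ado` (`NA` when no locus is eligible) and
#'   `n_eligible`.
#' @export
ado_estimate <- function(truth, calls, min_depth = 10L) {
  i <- match(paste(truth$contig, truth$pos),
             paste(calls$contig, calls$pos))
  cc <- calls[i[!is.na(i)], , drop = FALSE]
  elig <- cc$depth >= min_depth & cc$call != "no_call"
  n <- sum(elig)
  ado <- if (n == 0L) NA_real_ else {
    mean(cc$call[elig] %in% c("hom_ref", "hom_alt"))
  }
  list(ado = ado, n_eligible = n)
}

#' ADO estimates across several depth cutoffs
#'
#' @param truth heterozygous truth loci.
#' @param pileup pileup table (see [naive_genotype()]).
#' @param min_depths depth cutoffs to evaluate.
#' @param het_band heterozygous call band.
#' @return data.frame `min_depth`, `ado`, `n_eligible`.
#' @export
ado_by_depth <- function(truth, pileup, min_depths = c(3L, 6L, 10L),
                         het_band = c(0.1, 0.9)) {
  rows <- lapply(min_depths, function(d) {
    est <- ado_estimate(truth, naive_genotype(pileup, d, het_band), d)
    data.frame(min_depth = d, ado = est$ado, n_eligible = est$n_eligible)
  })
  do.call(rbind, rows)
}
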