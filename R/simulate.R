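# Synthetic epi-scar library simulator.
#
# Fragments are represented in top-strand space: a cut at site start p
# splits the duplex into an upstream product ending at p+3 (right end a
# 3' scar, top strand terminating ...GCG) and a downstream product
# beginning at p+1 (left end a 5' scar, bottom strand terminating in the
# complementary CG overhang). The shared [p+1, p+3) is the 2-nt 3'CG
# overhang rendered as a 2-bp overlap between adjacent fragments.

DEFAULT_ADAPTER <- "ACACGACGCTCTTCCG"

revcomp_ <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate a uniform random reference sequence
#'
#' @param length sequence length in bp.
#' @param seed RNG seed.
#' @param contig contig name.
#' @return named character vector usable as a genome.
#' @export
random_genome <- function(length, seed = NULL, contig = "chr1") {
  with_seed_(seed, {
    s <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
               collapse = "")
    stats::setNames(s, contig)
  })
}

#' Draw a site-level methylation-probability profile for a cell group
#'
#' Cells belonging to one line share a methylome: per-site methylation
#' probabilities are drawn once per group from a bimodal Beta
#' distribution with the requested mean, and individual cells then draw
#' their allele states against this shared profile. A small
#' `concentration` gives the U-shaped (mostly-0 / mostly-1) site
#' distribution typical of real methylomes.
#'
#' @param sites a `scar_sites` index.
#' @param mean_meth mean methylation level of the group in `[0, 1]`.
#' @param concentration Beta concentration (alpha + beta); smaller is
#'   more bimodal.
#' @param seed RNG seed.
#' @return numeric vector of per-site probabilities aligned with `sites`.
#' @export
group_profile <- function(sites, mean_meth, concentration = 0.6, seed = NULL) {
  stopifnot(mean_meth >= 0, mean_meth <= 1, concentration > 0)
  with_seed_(seed, {
    rbeta(nrow(sites), concentration * mean_meth,
          concentration * (1 - mean_meth))
  })
}

#' Simulate a single cell's true methylome
#'
#' Each site carries one methylation bit per allele. With probability
#' `p_allelic_discord` the two alleles disagree (truth state 0.5); the
#' concordant remainder is methylated so that the expected mean state
#' equals `p_meth`. The truth state is the mean of the two allele bits.
#' Digestion blocking follows the hemimethylation rule: an allele is
#' blocked if either strand is methylated, so optionally an unmethylated
#' allele can be hemimethylated (blocked but truth state unchanged) with
#' probability `p_hemi`.
#'
#' @param sites a `scar_sites` index.
#' @param p_meth scalar methylation probability, or per-site vector (see
#'   [group_profile()]).
#' @param p_allelic_discord probability that a site is allele-discordant.
#' @param p_hemi probability that an unmethylated allele is nevertheless
#'   blocked by hemimethylation.
#' @param allele_mode `"discord"` (default): the heterozygous-site
#'   fraction is controlled explicitly by `p_allelic_discord`;
#'   `"independent"`: the two allele bits are drawn i.i.d.
#'   Bernoulli(`p_meth`) so allelic discord arises naturally at
#'   intermediate per-site probabilities (`p_allelic_discord` is
#'   ignored) — the natural mode for [group_profile()] inputs.
#' @param seed RNG seed.
#' @param cell_id cell identifier.
#' @return `cell_truth` data.frame with `contig`, `start`, `allele1`,
#'   `allele2` (methylation bits), `blocked1`, `blocked2` (digestion
#'   blocking) and `state` in `{0, 0.5, 1}`.
#' @export
simulate_methylome <- function(sites, p_meth, p_allelic_discord = 0,
                               p_hemi = 0,
                               allele_mode = c("discord", "independent"),
                               seed = NULL, cell_id = "cell1") {
  allele_mode <- match.arg(allele_mode)
  n <- nrow(sites)
  d <- p_allelic_discord
  stopifnot(all(p_meth >= 0), all(p_meth <= 1), d >= 0, d <= 1,
            p_hemi >= 0, p_hemi <= 1)
  p <- rep_len(p_meth, n)
  if (allele_mode == "discord" && d < 1) {
    q <- (p - d / 2) / (1 - d)
    if (any(q < -1e-9 | q > 1 + 1e-9)) {
      stop("p_meth and p_allelic_discord are incompatible: implied ",
           "concordant methylation probability outside [0, 1]")
    }
    q <- pmin(pmax(q, 0), 1)
  } else {
    q <- rep(0.5, n)
  }
  with_seed_(seed, {
    if (allele_mode == "independent") {
      a1 <- as.integer(runif(n) < p)
      a2 <- as.integer(runif(n) < p)
    } else {
      disc <- runif(n) < d
      b <- as.integer(runif(n) < q)
      a1 <- ifelse(disc, as.integer(runif(n) < 0.5), b)
      a2 <- ifelse(disc, 1L - a1, b)
    }
    blocked1 <- a1 == 1L | (a1 == 0L & runif(n) < p_hemi)
    blocked2 <- a2 == 1L | (a2 == 0L & runif(n) < p_hemi)
    structure(
      data.frame(contig = sites$contig, start = sites$start,
                 allele1 = a1, allele2 = a2,
                 blocked1 = blocked1, blocked2 = blocked2,
                 state = (a1 + a2) / 2,
                 stringsAsFactors = FALSE),
      cell_id = cell_id,
      contig_lengths = attr(sites, "contig_lengths"),
      class = c("cell_truth", "data.frame"))
  })
}

#' Digest both alleles of a cell at its unblocked recognition sites
#'
#' Cleavage of a site is completely blocked by CpG methylation on either
#' strand of that allele; unblocked sites are cut independently with the
#' given efficiency. Cuts are applied left to right, and a site whose
#' duplex has been destroyed by an upstream overlapping cut (GCGCGC
#' runs: a cut at p leaves no intact duplex before p+3) cannot be cut.
#'
#' @param genome named character vector.
#' @param truth a `cell_truth` from [simulate_methylome()].
#' @param efficiency per-site cut probability in `(0, 1]`.
#' @param seed RNG seed.
#' @return data.frame of fragments in top-strand space: `allele`,
#'   `contig`, `start`, `end`, `left` (`genome`/`scar5`), `right`
#'   (`genome`/`scar3`); per-allele cut outcomes in attribute `cuts`.
#' @export
digest <- function(genome, truth, efficiency = 1, seed = NULL) {
  stopifnot(efficiency > 0, efficiency <= 1)
  genome <- as_genome(genome)
  lens <- contig_lengths(genome)
  with_seed_(seed, {
    frags <- list()
    cuts <- list()
    k <- 0L
    for (allele in 1:2) {
      blocked <- if (allele == 1L) truth$blocked1 else truth$blocked2
      for (ctg in names(genome)) {
        L <- lens[[ctg]]
        sel <- truth$contig == ctg
        st <- truth$start[sel]
        bl <- blocked[sel]
        ord <- order(st)
        st <- st[ord]; bl <- bl[ord]
        attempt <- !bl & runif(length(st)) < efficiency
        cut <- logical(length(st))
        last <- -4L
        for (i in seq_along(st)) {
          if (attempt[i] && st[i] >= last + 3L) {
            cut[i] <- TRUE
            last <- st[i]
          }
        }
        cp <- st[cut]
        starts <- c(0L, cp + 1L)
        ends <- c(cp + 3L, L)
        left <- c("genome", rep("scar5", length(cp)))
        right <- c(rep("scar3", length(cp)), "genome")
        k <- k + 1L
        frags[[k]] <- data.frame(allele = allele, contig = ctg,
                                 start = starts, end = ends,
                                 left = left, right = right,
                                 stringsAsFactors = FALSE)
        cuts[[k]] <- data.frame(allele = allele, contig = ctg,
                                start = st, cut = cut,
                                stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, c(frags, list(make.row.names = FALSE)))
    structure(out, cuts = do.call(rbind, c(cuts, list(make.row.names = FALSE))))
  })
}

#' Simulate heterozygous SNVs with allelic dropout
#'
#' Heterozygous loci are placed away from recognition sites (outside
#' every `[p-1, p+5)` margin) and the alternate base is chosen so the
#' substitution does not create a new GCGC occurrence. With probability
#' `ado_rate` one entire allele drops out at a locus, so the locus is
#' expected to genotype as homozygous.
#'
#' @param genome named character vector.
#' @param sites a `scar_sites` index of the same genome.
#' @param n_het_loci number of heterozygous loci to place.
#' @param ado_rate allele-level dropout probability per locus.
#' @param seed RNG seed.
#' @param loci optional data.frame (`contig`, `pos`) of user-fixed loci;
#'   an error is raised if any collides with a recognition-site margin.
#' @return data.frame with `contig`, `pos` (0-based), `ref`, `alt`,
#'   `alt_allele`, `dropped_allele` (0 = none) and `expected_zygosity`.
#' @export
simulate_snvs <- function(genome, sites, n_het_loci, ado_rate = 0,
                          seed = NULL, loci = NULL) {
  stopifnot(ado_rate >= 0, ado_rate <= 1)
  genome <- as_genome(genome)
  lens <- contig_lengths(genome)
  forbidden <- function(ctg) {
    st <- sites$start[sites$contig == ctg]
    if (!length(st)) return(integer())
    unique(unlist(lapply(st, function(p) seq(max(0L, p - 1L), p + 4L))))
  }
  creates_site <- function(seq, pos0, alt) {
    lo <- max(0L, pos0 - 3L); hi <- min(nchar(seq) - 1L, pos0 + 3L)
    win <- substr(seq, lo + 1L, hi + 1L)
    substr(win, pos0 - lo + 1L, pos0 - lo + 1L) <- alt
    grepl(HHAI_MOTIF, win, fixed = TRUE)
  }
  with_seed_(seed, {
    if (is.null(loci)) {
      ctgs <- names(genome)
      picks <- list()
      need <- n_het_loci
      bad_by_ctg <- lapply(stats::setNames(ctgs, ctgs), forbidden)
      avail <- lapply(ctgs, function(ctg) {
        setdiff(seq(0L, lens[[ctg]] - 1L), bad_by_ctg[[ctg]])
      })
      names(avail) <- ctgs
      total <- sum(lengths(avail))
      if (total < n_het_loci) stop("genome too small for requested het loci")
      pool <- data.frame(
        contig = rep(ctgs, lengths(avail)),
        pos = unlist(avail, use.names = FALSE), stringsAsFactors = FALSE)
      pick <- pool[sample(nrow(pool), n_het_loci), , drop = FALSE]
      loci <- pick[order(pick$contig, pick$pos), , drop = FALSE]
    } else {
      for (i in seq_len(nrow(loci))) {
        bad <- forbidden(loci$contig[i])
        if (loci$pos[i] %in% bad) {
          stop("locus ", loci$contig[i], ":", loci$pos[i],
               " collides with a recognition-site margin")
        }
      }
    }
    n <- nrow(loci)
    ref <- substring(genome[loci$contig], loci$pos + 1L, loci$pos + 1L)
    alt <- character(n)
    for (i in seq_len(n)) {
      cand <- sample(setdiff(c("A", "C", "G", "T"), ref[i]))
      ok <- !vapply(cand, function(a) {
        creates_site(genome[[loci$contig[i]]], loci$pos[i], a)
      }, logical(1))
      if (!any(ok)) stop("no valid alternate base at ",
                         loci$contig[i], ":", loci$pos[i])
      alt[i] <- cand[ok][1L]
    }
    alt_allele <- sample(1:2, n, replace = TRUE)
    dropped <- ifelse(runif(n) < ado_rate, sample(1:2, n, replace = TRUE), 0L)
    zyg <- ifelse(dropped == 0L, "het",
                  ifelse(dropped == alt_allele, "hom_ref", "hom_alt"))
    data.frame(contig = loci$contig, pos = loci$pos, ref = ref, alt = alt,
               alt_allele = alt_allele, dropped_allele = dropped,
               expected_zygosity = zyg, stringsAsFactors = FALSE,
               row.names = NULL)
  })
}

#' Remove fragments of a dropped allele over its SNV locus
#'
#' Allelic dropout is modelled at the fragment level: every fragment of
#' the dropped allele covering the locus is withheld from the library.
#'
#' @param fragments output of [digest()].
#' @param snvs output of [simulate_snvs()].
#' @return filtered fragments.
#' @export
drop_fragments <- function(fragments, snvs) {
  keep <- rep(TRUE, nrow(fragments))
  dropped <- snvs[snvs$dropped_allele > 0L, , drop = FALSE]
  for (i in seq_len(nrow(dropped))) {
    hit <- fragments$allele == dropped$dropped_allele[i] &
      fragments$contig == dropped$contig[i] &
      fragments$start <= dropped$pos[i] &
      fragments$end > dropped$pos[i]
    keep <- keep & !hit
  }
  out <- fragments[keep, , drop = FALSE]
  attr(out, "cuts") <- attr(fragments, "cuts")
  out
}

# Apply allele-specific alternate bases to a fragment sequence.
apply_snvs_ <- function(gseq, g_start, allele, contig, snvs) {
  hit <- snvs$alt_allele == allele & snvs$contig == contig &
    snvs$pos >= g_start & snvs$pos < g_start + nchar(gseq)
  for (i in which(hit)) {
    off <- snvs$pos[i] - g_start + 1L
    substr(gseq, off, off) <- snvs$alt[i]
  }
  gseq
}

#' Build tailed, adapter-flanked library molecules from fragments
#'
#' Scar ends receive a poly(dA) tail (rendered in top-strand space as a
#' 3' poly(A) at 3' scars and a 5' poly(T) at 5' scars); genome ends get
#' no tail. The constant adapter flanks both ends. Each molecule carries
#' a log-normal amplification factor approximating quasilinear
#' whole-genome preamplification; `amp_sigma = 0` gives uniform
#' representation.
#'
#' @param fragments output of [digest()] (optionally after
#'   [drop_fragments()]).
#' @param genome named character vector.
#' @param tail_lens integer vector of tail lengths to sample from;
#'   minimum must be >= 6 so that the 9-mer scar motifs are observable.
#' @param adapter constant adapter sequence.
#' @param amp_sigma log-normal sigma of the amplification factor.
#' @param seed RNG seed.
#' @param snvs optional SNV table from [simulate_snvs()].
#' @return data.frame of molecules with top-strand sequence and layout
#'   bookkeeping (`goff` = offset of the genomic portion, `glen` = its
#'   length).
#' @export
build_molecules <- function(fragments, genome, tail_lens = 8:16,
                            adapter = DEFAULT_ADAPTER, amp_sigma = 0,
                            seed = NULL, snvs = NULL) {
  if (min(tail_lens) < 6L) {
    stop("minimum tail length must be >= 6: shorter tails make the ",
         "9-mer scar motifs undetectable")
  }
  stopifnot(amp_sigma >= 0)
  genome <- as_genome(genome)
  n <- nrow(fragments)
  draw_tail <- function(n) {
    if (length(tail_lens) == 1L) rep(as.integer(tail_lens), n)
    else sample(tail_lens, n, replace = TRUE)
  }
  with_seed_(seed, {
    tl <- ifelse(fragments$left == "scar5", draw_tail(n), 0L)
    tr <- ifelse(fragments$right == "scar3", draw_tail(n), 0L)
    amp <- if (amp_sigma == 0) rep(1, n) else rlnorm(n, 0, amp_sigma)
    gseq <- substring(genome[fragments$contig], fragments$start + 1L,
                      fragments$end)
    if (!is.null(snvs) && nrow(snvs)) {
      for (i in seq_len(n)) {
        gseq[i] <- apply_snvs_(gseq[i], fragments$start[i],
                               fragments$allele[i], fragments$contig[i],
                               snvs)
      }
    }
    seq <- paste0(adapter,
                  strrep("T", tl), gseq, strrep("A", tr),
                  adapter)
    data.frame(mol_id = seq_len(n),
               allele = fragments$allele,
               contig = fragments$contig,
               g_start = fragments$start, g_end = fragments$end,
               left = fragments$left, right = fragments$right,
               tail_left = tl, tail_right = tr,
               goff = nchar(adapter) + tl,
               glen = fragments$end - fragments$start,
               amp = amp, seq = seq,
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

# Introduce uniform substitution errors into a character vector of reads.
add_errors_ <- function(seqs, err_rate) {
  if (err_rate <= 0) return(seqs)
  nerr <- rbinom(length(seqs), nchar(seqs), err_rate)
  for (i in which(nerr > 0L)) {
    pos <- sample(nchar(seqs[i]), nerr[i])
    for (p in pos) {
      cur <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
    }
  }
  seqs
}

#' Emit sequencing reads and a truth alignment table from molecules
#'
#' Reads model merged single-end amplicon reads: each read is one
#' sampled molecule (sampling probability proportional to the
#' amplification factor), taken whole when shorter than `read_len` or as
#' a uniform window otherwise, in random orientation. The truth table
#' records the genomic alignment of the genomic portion of each read
#' (tails and adapters soft-clipped), the expected scar class given the
#' covered molecule ends, and the source molecule.
#'
#' @param molecules output of [build_molecules()].
#' @param read_len read length (>= 30).
#' @param err_rate per-base substitution error rate.
#' @param n_reads number of reads to emit.
#' @param seed RNG seed.
#' @param both_orientations emit reads from both strands of the
#'   amplicon (default) or only in top-strand orientation.
#' @return list with `reads` (data.frame `qname`, `seq` in sequencing
#'   orientation) and `aln` (truth alignments with SAM-style fields plus
#'   layout bookkeeping).
#' @export
emit_reads <- function(molecules, read_len = 100L, err_rate = 0,
                       n_reads, seed = NULL, both_orientations = TRUE) {
  stopifnot(read_len >= 30L, err_rate >= 0, err_rate < 1, n_reads >= 0)
  empty <- list(
    reads = data.frame(qname = character(), seq = character(),
                       stringsAsFactors = FALSE),
    aln = data.frame(qname = character(), contig = character(),
                     flag = integer(), pos = integer(), mapq = integer(),
                     cigar = character(), g_start = integer(),
                     g_end = integer(), strand = character(),
                     lclip = integer(), rclip = integer(),
                     readlen = integer(), expected_class = character(),
                     mol_id = integer(), allele = integer(),
                     seq_ref = character(), stringsAsFactors = FALSE))
  if (n_reads == 0L || nrow(molecules) == 0L) return(empty)
  with_seed_(seed, {
    idx <- sample(nrow(molecules), n_reads, replace = TRUE,
                  prob = molecules$amp)
    L <- nchar(molecules$seq[idx])
    ws <- ifelse(L <= read_len, 0L,
                 floor(runif(n_reads) * (L - read_len + 1L)))
    we <- pmin(ws + read_len, L)
    strand <- if (both_orientations) {
      ifelse(runif(n_reads) < 0.5, "+", "-")
    } else rep("+", n_reads)
    seq_ref <- substring(molecules$seq[idx], ws + 1L, we)
    seq_ref <- add_errors_(seq_ref, err_rate)
    fastq_seq <- ifelse(strand == "+", seq_ref, revcomp_(seq_ref))

    goff <- molecules$goff[idx]
    glen <- molecules$glen[idx]
    gs_m <- pmax(ws, goff)
    ge_m <- pmin(we, goff + glen)
    mapped <- ge_m > gs_m
    g_start <- ifelse(mapped, molecules$g_start[idx] + (gs_m - goff), NA_integer_)
    g_end <- ifelse(mapped, molecules$g_start[idx] + (ge_m - goff), NA_integer_)
    lclip <- ifelse(mapped, gs_m - ws, 0L)
    rclip <- ifelse(mapped, we - ge_m, 0L)
    cigar <- ifelse(mapped,
                    paste0(ifelse(lclip > 0L, paste0(lclip, "S"), ""),
                           ge_m - gs_m, "M",
                           ifelse(rclip > 0L, paste0(rclip, "S"), "")),
                    "*")
    flag <- ifelse(!mapped, 4L, ifelse(strand == "-", 16L, 0L))

    c3 <- molecules$right[idx] == "scar3" &
      ws <= goff + glen - 3L & we >= goff + glen + 6L
    c5 <- molecules$left[idx] == "scar5" &
      ws <= goff - 6L & we >= goff + 3L
    expected <- ifelse(c3 & c5, "both",
                ifelse(c3, ifelse(strand == "+", "scar3", "scar5"),
                ifelse(c5, ifelse(strand == "+", "scar5", "scar3"),
                       "none")))
    qname <- sprintf("r%07d", seq_len(n_reads))
    list(
      reads = data.frame(qname = qname, seq = fastq_seq,
                         stringsAsFactors = FALSE),
      aln = data.frame(qname = qname, ws = ws, we = we,
                       contig = molecules$contig[idx],
                       flag = flag, pos = g_start + 1L, mapq = 60L,
                       cigar = cigar, g_start = g_start, g_end = g_end,
                       strand = ifelse(mapped, strand, "*"),
                       lclip = lclip, rclip = rclip,
                       readlen = we - ws,
                       expected_class = expected,
                       mol_id = molecules$mol_id[idx],
                       allele = molecules$allele[idx],
                       seq_ref = seq_ref,
                       stringsAsFactors = FALSE))
  })
}

#' Write reads as FASTQ
#' @param reads data.frame with `qname` and `seq`.
#' @param path output path (may end in .gz).
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$qname
  q <- Biostrings::BStringSet(strrep("I", nchar(reads$seq)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTQ file into a reads data.frame
#' @param path FASTQ path.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(qname = sub("\\s.*$", "", names(x)), seq = as.character(x),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write the simulator truth alignments as SAM
#'
#' Emits a valid headered SAM file with one record per read; tails and
#' adapters appear as soft clips, sequences are stored in reference
#' orientation per SAM convention.
#'
#' @param aln truth alignment table from [emit_reads()].
#' @param contig_lens named integer vector of contig lengths.
#' @param path output path.
#' @export
write_truth_sam <- function(aln, contig_lens, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lens),
                   as.integer(contig_lens)))
  mapped <- aln$flag != 4L
  lines <- character(nrow(aln))
  if (nrow(aln)) {
    lines <- paste(aln$qname, aln$flag,
                   ifelse(mapped, aln$contig, "*"),
                   ifelse(mapped, aln$pos, 0L),
                   ifelse(mapped, aln$mapq, 0L),
                   aln$cigar, "*", 0L, 0L,
                   aln$seq_ref,
                   strrep("I", nchar(aln$seq_ref)),
                   sep = "\t")
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Simulate one complete single-cell library
#'
#' Convenience wrapper chaining [simulate_methylome()], [digest()],
#' optional SNV dropout, [build_molecules()] and [emit_reads()].
#'
#' @inheritParams simulate_methylome
#' @inheritParams digest
#' @inheritParams build_molecules
#' @inheritParams emit_reads
#' @param genome named character vector.
#' @param sites a `scar_sites` index.
#' @param snvs optional SNV truth from [simulate_snvs()].
#' @return list with `truth`, `fragments`, `molecules`, `reads`, `aln`.
#' @export
simulate_cell <- function(genome, sites, p_meth = 0.7,
                          p_allelic_discord = 0.05, p_hemi = 0,
                          allele_mode = c("discord", "independent"),
                          efficiency = 1, tail_lens = 8:16,
                          adapter = DEFAULT_ADAPTER, amp_sigma = 0.5,
                          read_len = 100L, err_rate = 0.002,
                          n_reads = 10000L, seed = NULL, snvs = NULL,
                          cell_id = "cell1") {
  seeds <- if (is.null(seed)) rep(list(NULL), 4L) else as.list(seed + 0:3)
  truth <- simulate_methylome(sites, p_meth, p_allelic_discord, p_hemi,
                              allele_mode = allele_mode,
                              seed = seeds[[1]], cell_id = cell_id)
  frags <- digest(genome, truth, efficiency, seed = seeds[[2]])
  if (!is.null(snvs)) frags <- drop_fragments(frags, snvs)
  mols <- build_molecules(frags, genome, tail_lens, adapter, amp_sigma,
                          seed = seeds[[3]], snvs = snvs)
  rd <- emit_reads(mols, read_len, err_rate, n_reads, seed = seeds[[4]])
  list(truth = truth, fragments = frags, molecules = mols,
       reads = rd$reads, aln = rd$aln)
}

#' Simulate per-locus pileup counts with allelic dropout
#'
#' Deep-coverage shortcut for genotyping studies: each retained allele
#' contributes Poisson(`mean_depth`/2) reads at its locus; a dropped
#' allele contributes none, so dropout loci run at half the expected
#' depth (which is why apparent dropout shrinks as the depth cutoff
#' rises). Sequencing errors redistribute a fraction of reads uniformly
#' over the three non-template bases.
#'
#' @param snvs output of [simulate_snvs()].
#' @param mean_depth expected total depth at a locus with both alleles.
#' @param err_rate per-read substitution error rate.
#' @param seed RNG seed.
#' @return data.frame with `contig`, `pos`, `ref`, `alt`, `ref_count`,
#'   `alt_count`, `other_count`, `depth`.
#' @export
simulate_pileup <- function(snvs, mean_depth = 40, err_rate = 0,
                            seed = NULL) {
  stopifnot(mean_depth > 0, err_rate >= 0, err_rate < 1)
  n <- nrow(snvs)
  with_seed_(seed, {
    d1 <- ifelse(snvs$dropped_allele == 1L, 0L, rpois(n, mean_depth / 2))
    d2 <- ifelse(snvs$dropped_allele == 2L, 0L, rpois(n, mean_depth / 2))
    dref <- ifelse(snvs$alt_allele == 2L, d1, d2)
    dalt <- ifelse(snvs$alt_allele == 2L, d2, d1)
    ref_ok <- rbinom(n, dref, 1 - err_rate)
    alt_ok <- rbinom(n, dalt, 1 - err_rate)
    ref_to_alt <- rbinom(n, dref - ref_ok, 1 / 3)
    alt_to_ref <- rbinom(n, dalt - alt_ok, 1 / 3)
    ref_count <- ref_ok + alt_to_ref
    alt_count <- alt_ok + ref_to_alt
    other <- (dref - ref_ok - ref_to_alt) + (dalt - alt_ok - alt_to_ref)
    data.frame(contig = snvs$contig, pos = snvs$pos, ref = snvs$ref,
               alt = snvs$alt, ref_count = ref_count,
               alt_count = alt_count, other_count = other,
               depth = ref_count + alt_count + other,
               stringsAsFactors = FALSE)
  })
}

#' Generate a spike-in control amplicon
#'
#' A random sequence containing exactly one GCGC recognition site and no
#' homopolymer run of 6+ that could be mistaken for a tail. Methylated
#' controls are never cut during library simulation.
#'
#' @param name control name.
#' @param length amplicon length in bp.
#' @param methylated logical.
#' @param seed RNG seed.
#' @return list with `name`, `seq`, `methylated`, `site_start` (0-based).
#' @export
spikein_control <- function(name = "spike1", length = 300L,
                            methylated = FALSE, seed = NULL) {
  stopifnot(length >= 50L)
  with_seed_(seed, {
    repeat {
      s <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                 collapse = "")
      mid <- as.integer(length / 2L)
      substr(s, mid + 1L, mid + 4L) <- HHAI_MOTIF
      n_sites <- length(Biostrings::matchPattern(HHAI_MOTIF,
                                                 Biostrings::DNAString(s)))
      runs <- grepl("A{6,}|T{6,}", s)
      if (n_sites == 1L && !runs) break
    }
    list(name = name, seq = s, methylated = methylated, site_start = mid)
  })
}

#' Simulate a spike-in library and reads
#'
#' Each template copy of an unmethylated control is cut at its single
#' site with the given efficiency; methylated controls are never cut.
#' Cut copies yield two scar-tailed fragments, intact copies one
#' untailed fragment; reads are emitted with the standard machinery.
#'
#' @param control output of [spikein_control()].
#' @param n_molecules template copies.
#' @param efficiency per-copy cut probability.
#' @param reads_per_molecule mean read count per template copy.
#' @inheritParams build_molecules
#' @inheritParams emit_reads
#' @return list with `n_cut`, `n_uncut`, `reads`, `aln`, `molecules`.
#' @export
simulate_spikein_library <- function(control, n_molecules = 30L,
                                     efficiency = 0.95,
                                     reads_per_molecule = 50L,
                                     read_len = 100L, tail_lens = 8:16,
                                     adapter = DEFAULT_ADAPTER,
                                     err_rate = 0, seed = NULL) {
  stopifnot(efficiency > 0, efficiency <= 1, n_molecules >= 1)
  genome <- stats::setNames(control$seq, control$name)
  L <- nchar(control$seq)
  p <- control$site_start
  seeds <- if (is.null(seed)) list(NULL, NULL, NULL) else as.list(seed + 0:2)
  cut <- with_seed_(seeds[[1]], {
    if (control$methylated) rep(FALSE, n_molecules)
    else runif(n_molecules) < efficiency
  })
  frag_list <- lapply(seq_len(n_molecules), function(i) {
    if (cut[i]) {
      data.frame(allele = i, contig = control$name,
                 start = c(0L, p + 1L), end = c(p + 3L, L),
                 left = c("genome", "scar5"), right = c("scar3", "genome"),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(allele = i, contig = control$name, start = 0L, end = L,
                 left = "genome", right = "genome",
                 stringsAsFactors = FALSE)
    }
  })
  frags <- do.call(rbind, frag_list)
  mols <- build_molecules(frags, genome, tail_lens, adapter,
                          amp_sigma = 0, seed = seeds[[2]])
  rd <- emit_reads(mols, read_len, err_rate,
                   n_reads = n_molecules * reads_per_molecule,
                   seed = seeds[[3]])
  list(n_cut = sum(cut), n_uncut = sum(!cut), reads = rd$reads,
       aln = rd$aln, molecules = mols, control = control)
}
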