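genome8 <- c(chr1 = "AAGCGCTT")
sites8 <- find_sites(genome8)

test_that("simulate_methylome honours forced probabilities and seeds", {
  g <- random_genome(3000, seed = 2)
  s <- find_sites(g)
  all1 <- simulate_methylome(s, p_meth = 1, p_allelic_discord = 0, seed = 1)
  expect_true(all(all1$state == 1))
  all0 <- simulate_methylome(s, p_meth = 0, p_allelic_discord = 0, seed = 1)
  expect_true(all(all0$state == 0))
  a <- simulate_methylome(s, 0.5, 0.2, seed = 99)
  b <- simulate_methylome(s, 0.5, 0.2, seed = 99)
  expect_identical(a, b)
  expect_error(simulate_methylome(s, p_meth = 0.01, p_allelic_discord = 0.5),
               "incompatible")
})

test_that("heterozygous fraction matches p_allelic_discord in expectation", {
  g <- random_genome(60000, seed = 4)
  s <- find_sites(g)
  tr <- simulate_methylome(s, 0.6, 0.25, seed = 11)
  expect_equal(mean(tr$state == 0.5), 0.25, tolerance = 0.12)
  expect_equal(mean(tr$state), 0.6, tolerance = 0.1)
  # independent mode: discord arises as 2p(1-p)
  tri <- simulate_methylome(s, 0.5, allele_mode = "independent", seed = 12)
  expect_equal(mean(tri$state == 0.5), 0.5, tolerance = 0.15)
})

test_that("digest reproduces the cleavage geometry on a single site", {
  tr <- make_truth(sites8, 0L, 0L)
  fr <- digest(genome8, tr, efficiency = 1, seed = 1)
  for (al in 1:2) {
    f <- fr[fr$allele == al, ]
    expect_equal(f$start, c(0L, 3L))
    expect_equal(f$end, c(5L, 8L))
    expect_equal(f$left, c("genome", "scar5"))
    expect_equal(f$right, c("scar3", "genome"))
  }
  # fully methylated: blocked, single fragment
  frm <- digest(genome8, make_truth(sites8, 1L, 1L), 1, seed = 1)
  expect_equal(nrow(frm), 2L)
  expect_true(all(frm$start == 0L & frm$end == 8L &
                    frm$left == "genome" & frm$right == "genome"))
  # heterozygous: exactly one allele yields scar fragments
  trh <- make_truth(sites8, 0L, 1L)
  expect_equal(trh$state, 0.5)
  frh <- digest(genome8, trh, 1, seed = 1)
  expect_equal(sum(frh$right == "scar3"), 1L)
  expect_equal(sum(frh$allele == 2 & frh$right == "genome"), 1L)
})

test_that("fragments tile each allele with the 2-bp overhang overlap", {
  g <- random_genome(20000, seed = 8)
  s <- find_sites(g)
  tr <- simulate_methylome(s, 0.5, 0.1, seed = 3)
  fr <- digest(g, tr, efficiency = 1, seed = 4)
  for (al in 1:2) {
    f <- fr[fr$allele == al, ]
    f <- f[order(f$start), ]
    expect_equal(f$start[1], 0L)
    expect_equal(f$end[nrow(f)], nchar(g[[1]]))
    if (nrow(f) > 1L) {
      expect_true(all(f$start[-1] == f$end[-nrow(f)] - 2L))
    }
  }
})

test_that("overlapping sites cannot both be cut on one allele", {
  g <- c(chr1 = "AAAAGCGCGCTTTTAAAA")
  s <- find_sites(g)
  expect_equal(s$start, c(4L, 6L))
  hits <- replicate(20, {
    tr <- make_truth(s, c(0L, 0L), c(0L, 0L))
    fr <- digest(g, tr, efficiency = 1, seed = sample.int(1e6, 1))
    cuts <- attr(fr, "cuts")
    max(tapply(cuts$cut, cuts$allele, sum))
  })
  expect_true(all(hits <= 1))
})

test_that("molecules carry tails and adapters with correct end sequences", {
  tr <- make_truth(sites8, 0L, 0L)
  fr <- digest(genome8, tr, 1, seed = 1)
  m <- build_molecules(fr, genome8, tail_lens = 8L, adapter = "ACGTACGTACGTACGT",
                       amp_sigma = 0, seed = 2)
  s3 <- m[m$right == "scar3", ][1, ]
  core <- substr(s3$seq, 17L, nchar(s3$seq) - 16L)
  expect_true(grepl("GCGAAAAAAAA$", core))   # ...GCG + 8 x A
  s5 <- m[m$left == "scar5", ][1, ]
  core5 <- substr(s5$seq, 17L, nchar(s5$seq) - 16L)
  expect_true(grepl("^TTTTTTTTCGC", core5))  # 8 x T + CGC...
  expect_true(all(m$tail_left[m$left != "scar5"] == 0L))
  expect_true(all(m$tail_right[m$right != "scar3"] == 0L))
  expect_true(all(m$amp == 1))
  expect_error(build_molecules(fr, genome8, tail_lens = 4:5),
               "tail length")
})

test_that("emit_reads is deterministic and exact at zero error rate", {
  g <- random_genome(8000, seed = 5)
  s <- find_sites(g)
  sim1 <- simulate_cell(g, s, p_meth = 0.5, p_allelic_discord = 0,
                        amp_sigma = 0, err_rate = 0, n_reads = 500, seed = 6)
  sim2 <- simulate_cell(g, s, p_meth = 0.5, p_allelic_discord = 0,
                        amp_sigma = 0, err_rate = 0, n_reads = 500, seed = 6)
  expect_identical(sim1$reads, sim2$reads)

  aln <- sim1$aln
  mapped <- aln$flag != 4L
  gl <- aln$g_end[mapped] - aln$g_start[mapped]
  genomic <- substr(aln$seq_ref[mapped], aln$lclip[mapped] + 1L,
                    aln$lclip[mapped] + gl)
  ref <- substring(g[aln$contig[mapped]], aln$g_start[mapped] + 1L,
                   aln$g_end[mapped])
  expect_true(all(genomic == ref))

  empty <- emit_reads(sim1$molecules, n_reads = 0L, seed = 1)
  expect_equal(nrow(empty$reads), 0L)
  expect_equal(nrow(empty$aln), 0L)
})

test_that("FASTQ and truth SAM round-trip through standard parsers", {
  g <- random_genome(6000, seed = 9)
  s <- find_sites(g)
  sim <- simulate_cell(g, s, amp_sigma = 0, err_rate = 0, n_reads = 300,
                       seed = 10)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(sim$reads, fq)
  back <- read_fastq(fq)
  expect_equal(back$seq, sim$reads$seq)

  sam <- tempfile(fileext = ".sam")
  write_truth_sam(sim$aln, attr(s, "contig_lengths"), sam)
  aln <- read_alignments(sam)
  i <- match(aln$qname, sim$aln$qname)
  expect_equal(aln$g_start, sim$aln$g_start[i])
  expect_equal(aln$g_end, sim$aln$g_end[i])
  expect_equal(aln$strand, sim$aln$strand[i])
  expect_true(all(aln$mapq == 60L))
})

test_that("simulate_snvs places loci away from sites and tracks dropout", {
  g <- random_genome(30000, seed = 13)
  s <- find_sites(g)
  snv <- simulate_snvs(g, s, n_het_loci = 200, ado_rate = 0, seed = 14)
  margins <- unlist(lapply(s$start, function(p) (p - 1L):(p + 4L)))
  expect_false(any(snv$pos %in% margins))
  expect_true(all(snv$expected_zygosity == "het"))
  # substituting the alt base never creates a new recognition site
  for (i in seq_len(50)) {
    seq <- g[[1]]
    substr(seq, snv$pos[i] + 1L, snv$pos[i] + 1L) <- snv$alt[i]
    expect_equal(length(naive_scan(substr(seq, max(1, snv$pos[i] - 2),
                                          snv$pos[i] + 4))), 0L)
  }
  snv1 <- simulate_snvs(g, s, 100, ado_rate = 1, seed = 15)
  expect_true(all(snv1$expected_zygosity %in% c("hom_ref", "hom_alt")))
  expect_identical(simulate_snvs(g, s, 50, 0.3, seed = 16),
                   simulate_snvs(g, s, 50, 0.3, seed = 16))
  expect_error(
    simulate_snvs(g, s, 1, loci = data.frame(contig = "chr1",
                                             pos = s$start[1])),
    "collides")
})

test_that("simulate_pileup reflects allele-level dropout", {
  g <- random_genome(30000, seed = 17)
  s <- find_sites(g)
  snv <- simulate_snvs(g, s, 300, ado_rate = 0.5, seed = 18)
  pu <- simulate_pileup(snv, mean_depth = 60, err_rate = 0, seed = 19)
  ref_dropped <- snv$dropped_allele > 0L & snv$dropped_allele != snv$alt_allele
  alt_dropped <- snv$dropped_allele == snv$alt_allele & snv$dropped_allele > 0L
  expect_true(all(pu$ref_count[ref_dropped] == 0L))
  expect_true(all(pu$alt_count[alt_dropped] == 0L))
  both <- snv$dropped_allele == 0L
  expect_true(all(pu$ref_count[both] + pu$alt_count[both] > 0L))
})

test_that("spike-in controls have one site and methylated ones never cut", {
  ctl <- spikein_control(seed = 21, length = 100)
  expect_equal(length(naive_scan(ctl$seq)), 1L)
  expect_equal(naive_scan(ctl$seq), ctl$site_start)
  mlib <- simulate_spikein_library(
    spikein_control(seed = 22, length = 100, methylated = TRUE),
    n_molecules = 20, efficiency = 0.95, reads_per_molecule = 5,
    read_len = 150, seed = 23)
  expect_equal(mlib$n_cut, 0L)
})
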