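sites_1 <- structure(
  data.frame(contig = "chr1", start = 2L, informative = TRUE,
             stringsAsFactors = FALSE),
  contig_lengths = c(chr1 = 100L), informative_annotated = FALSE,
  class = c("scar_sites", "data.frame"))

aln_row <- function(g_start, g_end, strand = "+", mapq = 60L, flag = 0L,
                    qname = "r1") {
  data.frame(qname = qname, contig = "chr1", g_start = g_start,
             g_end = g_end, strand = strand, mapq = mapq, flag = flag,
             lclip = 0L, rclip = 0L, readlen = g_end - g_start,
             stringsAsFactors = FALSE)
}

test_that("alignment filtering keeps primary mapped reads at MAPQ >= 10", {
  aln <- rbind(aln_row(0, 50, mapq = 10L),
               aln_row(0, 50, mapq = 9L),
               aln_row(0, 50, mapq = 60L, flag = 256L),
               aln_row(0, 50, mapq = 60L, flag = 2048L),
               aln_row(0, 50, mapq = 60L, flag = 4L))
  kept <- filter_alignments(aln)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$mapq, 10L)
})

test_that("anchors are the outermost three nucleotides, strand-aware", {
  a <- anchor_interval(aln_row(0, 5), side = "3prime")
  expect_equal(c(a$start, a$end), c(2L, 5L))
  b <- anchor_interval(aln_row(3, 8), side = "5prime")
  expect_equal(c(b$start, b$end), c(3L, 6L))
  d <- anchor_interval(aln_row(3, 8, strand = "-"), side = "3prime")
  expect_equal(c(d$start, d$end), c(3L, 6L))
  e <- anchor_interval(aln_row(3, 8, strand = "-"), side = "5prime")
  expect_equal(c(e$start, e$end), c(5L, 8L))
  expect_warning(res <- anchor_interval(aln_row(0, 2), side = "3prime"),
                 "shorter than 3")
  expect_equal(nrow(res), 0L)
})

test_that("cut calls require nucleotide-precise scar geometry", {
  anc <- function(start, strand = "+") {
    data.frame(contig = "chr1", start = start, end = start + 3L,
               strand = strand, stringsAsFactors = FALSE)
  }
  # 3' scar anchor [p, p+3) on + strand
  cc <- call_cut_sites(NULL, anc(2L), sites_1)
  expect_equal(cc$site_start, 2L)
  expect_equal(cc$cut, 1L)
  # 5' scar anchor [p+1, p+4) on + strand
  cc5 <- call_cut_sites(anc(3L), NULL, sites_1)
  expect_equal(cc5$site_start, 2L)
  # opposite-strand reads carry the mirrored motif class
  expect_equal(call_cut_sites(anc(2L, "-"), NULL, sites_1)$site_start, 2L)
  expect_equal(call_cut_sites(NULL, anc(3L, "-"), sites_1)$site_start, 2L)
  # anchors matching no site are discarded
  expect_equal(nrow(call_cut_sites(NULL, anc(1L), sites_1)), 0L)
})

test_that("uncut calls need complete coverage of the expanded site", {
  aln <- aln_row(0, 8)
  uc <- call_uncut_sites(aln, sites_1)
  expect_equal(uc$site_start, 2L)
  expect_equal(uc$uncut, 1L)
  expect_equal(nrow(call_uncut_sites(aln_row(0, 6), sites_1)), 0L)
  # boundary sites have no defined margin
  s0 <- structure(
    data.frame(contig = "chr1", start = 0L, informative = TRUE),
    contig_lengths = c(chr1 = 100L), class = c("scar_sites", "data.frame"))
  expect_equal(nrow(call_uncut_sites(aln_row(0, 50), s0)), 0L)
})

test_that("intact evidence is excluded next to a cut overlapping site", {
  s2 <- structure(
    data.frame(contig = "chr1", start = c(0L, 2L), informative = TRUE,
               stringsAsFactors = FALSE),
    contig_lengths = c(chr1 = 100L), class = c("scar_sites", "data.frame"))
  # both sites would pass the containment test if margins allowed
  aln <- aln_row(0, 20)
  cut0 <- data.frame(contig = "chr1", site_start = 0L, cut = 2L)
  uc <- call_uncut_sites(aln, s2, cut0)
  expect_false(2L %in% uc$site_start)
  # without the overlapping cut the evidence stands
  uc2 <- call_uncut_sites(aln, s2, NULL)
  expect_true(2L %in% uc2$site_start)
})

test_that("states combine cut and intact evidence into {0, 0.5, 1}", {
  cut <- data.frame(contig = "chr1", site_start = c(2L, 10L),
                    cut = c(3L, 1L))
  uncut <- data.frame(contig = "chr1", site_start = c(10L, 20L),
                      uncut = c(1L, 2L))
  st <- call_state(cut, uncut, sites_1)
  expect_equal(st$state[st$site_start == 2L], 0)
  expect_equal(st$state[st$site_start == 10L], 0.5)
  expect_equal(st$state[st$site_start == 20L], 1)
  expect_true(all(st$state %in% c(0, 0.5, 1)))
  # evidence threshold: sites with total evidence below it are absent
  st2 <- call_state(cut, uncut, sites_1, min_evidence = 3L)
  expect_equal(st2$site_start, 2L)
  # informative filtering applies only when annotated
  s_ann <- annotate_informative(sites_1,
                                data.frame(contig = "chr1", cpg_start = 999L))
  st3 <- call_state(cut, uncut, s_ann)
  expect_equal(nrow(st3), 0L)
})

test_that("bedGraph output covers the CpG interval and round-trips", {
  m <- make_methylome(c(1, 0), starts = c(2L, 30L), cell_id = "k1")
  path <- tempfile(fileext = ".bedGraph")
  write_bedgraph(m, path)
  lines <- readLines(path)
  expect_match(lines[1], "^track type=bedGraph")
  expect_equal(lines[2], "chr1\t3\t5\t1")
  back <- read_cell_bedgraph(path, "k1")
  expect_equal(back$site_start, m$site_start)
  expect_equal(back$state, m$state)
  empty <- make_methylome(numeric(0), starts = integer(0))
  p2 <- tempfile(fileext = ".bedGraph")
  write_bedgraph(empty, p2)
  expect_equal(length(readLines(p2)), 1L)
})

test_that("calling recovers simulated truth at fully covered sites", {
  g <- random_genome(30000, seed = 41)
  s <- find_sites(g)
  sim <- simulate_cell(g, s, p_meth = 0.7, p_allelic_discord = 0.1,
                       efficiency = 1, amp_sigma = 0, err_rate = 0,
                       n_reads = 8000, seed = 42)
  cm <- call_cell(sim$aln, classify_reads(sim$reads), s)
  ev <- evaluate_recovery(sim, cm)
  expect_gt(ev$n_full, 50L)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$false_het, 0L)
  expect_true(all(cm$state %in% c(0, 0.5, 1)))
})

test_that("lower digestion efficiency yields fewer unmethylated calls", {
  g <- random_genome(30000, seed = 43)
  s <- find_sites(g)
  frac0 <- vapply(c(1, 0.6), function(eff) {
    sim <- simulate_cell(g, s, p_meth = 0.5, p_allelic_discord = 0,
                         efficiency = eff, amp_sigma = 0, err_rate = 0,
                         n_reads = 8000, seed = 44)
    cm <- call_cell(sim$aln, classify_reads(sim$reads), s)
    tr <- sim$truth
    unmeth <- paste(tr$contig, tr$start)[tr$state == 0]
    called0 <- paste(cm$contig, cm$site_start)[cm$state == 0]
    mean(unmeth %in% called0)
  }, numeric(1))
  expect_gt(frac0[1], frac0[2])
})
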