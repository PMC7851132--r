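test_that("pseudo-bulk averages states over covering cells", {
  cells <- list(make_methylome(c(1, 1), starts = c(10L, 20L)),
                make_methylome(c(1, 0), starts = c(10L, 20L)),
                make_methylome(0, starts = 10L))
  pb <- pseudo_bulk(cells, min_cells = 3L)
  expect_equal(pb$site_start, 10L)
  expect_equal(pb$mean_state, 2 / 3)
  # under-covered sites are dropped
  expect_false(20L %in% pb$site_start)
  # identity: pseudo-bulk of one cell at min_cells = 1
  one <- pseudo_bulk(cells[1], min_cells = 1L)
  expect_equal(one$mean_state, cells[[1]]$state)
  expect_warning(pseudo_bulk(cells, min_cells = 5L), "min_cells")
  # n copies of one cell reproduce that cell exactly
  pb3 <- pseudo_bulk(rep(cells[1], 3), min_cells = 1L)
  expect_equal(pb3$mean_state, cells[[1]]$state)
})

test_that("pairwise concordance is exact-state agreement on the overlap", {
  a <- make_methylome(c(1, 0, 0.5), starts = c(1L, 2L, 3L))
  b <- make_methylome(c(1, 0.5, 0), starts = c(1L, 2L, 4L))
  r <- pairwise_concordance(a, b)
  expect_equal(r$n_overlap, 2L)
  expect_equal(r$concordance, 0.5)
  expect_equal(pairwise_concordance(b, a)$concordance, 0.5)
  expect_equal(pairwise_concordance(a, a)$concordance, 1)
  disjoint <- make_methylome(1, starts = 99L)
  expect_true(is.na(pairwise_concordance(a, disjoint)$concordance))
  cm <- concordance_matrix(list(a = a, b = b))
  expect_equal(cm["a", "b"], cm["b", "a"])
  expect_equal(diag(cm), c(a = 1, b = 1))
})

test_that("global mean is the unweighted mean of states", {
  expect_equal(global_mean(make_methylome(c(1, 0, 0.5, 1))), 0.625)
  expect_equal(global_mean(make_methylome(c(1, 1))), 1)
  expect_equal(global_mean(make_methylome(c(0, 0))), 0)
  expect_error(global_mean(make_methylome(numeric(0), integer(0))),
               "no called sites")
})

test_that("bulk correlation matches the direct Pearson formula", {
  pb <- data.frame(contig = "chr1", site_start = c(10L, 20L, 30L, 40L),
                   mean_state = c(0, 0.5, 1, 1), n_cells = 20L)
  bulk <- data.frame(contig = "chr1", cpg_start = c(11L, 21L, 31L, 41L),
                     beta = c(0.1, 0.4, 0.9, 0.8))
  r <- correlate_with_bulk(pb, bulk, min_cells = 15L)
  expect_equal(r$n, 4L)
  expect_equal(r$r, pearson_direct(c(0, 0.5, 1, 1), c(0.1, 0.4, 0.9, 0.8)),
               tolerance = 1e-12)
  bulk$beta <- 1 - c(0, 0.5, 1, 1)
  expect_equal(correlate_with_bulk(pb, bulk, 15L)$r, -1, tolerance = 1e-12)
  expect_error(correlate_with_bulk(pb[1:2, ], bulk[1:2, ], 15L),
               "fewer than 3")
  pb$mean_state <- 0.5
  expect_error(correlate_with_bulk(pb, bulk, 15L), "variance")
  withr::with_seed(61, {
    for (i in 1:5) {
      x <- runif(30); y <- x + rnorm(30, 0, 0.3)
      expect_equal(stats::cor(x, y), pearson_direct(x, y),
                   tolerance = 1e-12)
    }
  })
})

test_that("metaprofiles place sites into anchor-relative windows", {
  m <- make_methylome(1, starts = 1020L)  # CpG midpoint 1022
  feat <- data.frame(contig = "chr1", start = 1000L, end = 1001L,
                     strand = "+")
  pr <- meta_profile(m, feat, window_bp = 50L, flank_bp = 100L)
  expect_equal(nrow(pr), 4L)
  expect_equal(pr$mean_state[3], 1)
  expect_true(all(is.na(pr$mean_state[-3])))
  # all-zero states give zero (not missing) windows
  m0 <- make_methylome(c(0, 0), starts = c(1010L, 1030L))
  pr0 <- meta_profile(m0, feat, window_bp = 50L, flank_bp = 100L)
  expect_equal(pr0$mean_state[3], 0)
  # minus-strand feature mirrors the profile
  featm <- data.frame(contig = "chr1", start = 1000L, end = 1001L,
                      strand = "-")
  prm <- meta_profile(m, featm, window_bp = 50L, flank_bp = 100L)
  expect_equal(prm$mean_state[2], 1)
  # scaled-body mode bins the feature interior
  featb <- data.frame(contig = "chr1", start = 1000L, end = 1200L,
                      strand = "+")
  prb <- meta_profile(m, featb, window_bp = 50L, flank_bp = 100L,
                      body_mode = "scaled", body_bins = 4L)
  expect_equal(nrow(prb), 8L)
  expect_equal(prb$mean_state[3], 1)  # midpoint 1022 -> first body bin
})

test_that("window matrices hold per-cell window means", {
  a <- make_methylome(c(1, 1), starts = c(100L, 9000L))
  b <- make_methylome(c(0, 1), starts = c(100L, 9000L))
  onecov <- make_methylome(1, starts = 100L)
  lens <- c(chr1 = 10000L)
  m <- window_matrix(list(a = a, b = b), lens, window_bp = 5000L)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(unname(m[, "chr1:0"]), c(1, 0))
  # window covered in one of two cells is dropped when required in all
  m2 <- window_matrix(list(a = a, b = onecov), lens, window_bp = 5000L,
                      require_all_cells = TRUE)
  expect_equal(colnames(m2), "chr1:0")
  m3 <- window_matrix(list(a = a, b = onecov), lens, window_bp = 5000L,
                      require_all_cells = FALSE)
  expect_equal(ncol(m3), 2L)
  empty <- window_matrix(list(a = make_methylome(numeric(0), integer(0))),
                         lens, window_bp = 5000L)
  expect_equal(ncol(empty), 0L)
})

test_that("correlation clustering recovers simulated cell groups", {
  g <- random_genome(40000, seed = 62)
  s <- find_sites(g)
  cells <- list(); grp <- integer()
  for (k in 1:2) {
    prof <- group_profile(s, c(0.8, 0.4)[k], seed = 70 + k)
    for (j in 1:4) {
      tr <- simulate_methylome(s, prof, allele_mode = "independent",
                               seed = 700 + 10 * k + j)
      cells[[sprintf("g%d_%d", k, j)]] <-
        make_methylome(tr$state, starts = tr$start)
      grp <- c(grp, k)
    }
  }
  wm <- window_matrix(cells, attr(s, "contig_lengths"), window_bp = 4000L)
  cc <- correlation_cluster(wm)
  cl <- stats::cutree(cc$hc, 2)
  expect_equal(length(unique(cl[grp == 1])), 1L)
  expect_equal(length(unique(cl[grp == 2])), 1L)
  expect_false(cl[grp == 1][1] == cl[grp == 2][1])
  # identical cells merge at distance ~0
  twin <- correlation_cluster(wm[c(1, 1, 5), ])
  expect_equal(twin$R[1, 2], 1)
  expect_error(correlation_cluster(wm[1, , drop = FALSE]), "at least 2")
})
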