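# Multi-cell aggregation: pseudo-bulk, concordance, profiles, windows.

meth_key_ <- function(m) paste(m$contig, m$site_start)

#' Pseudo-bulk methylation from single cells
#'
#' Per site, the unweighted mean of the states of all cells calling it,
#' retained when at least `min_cells` cells cover the site.
#'
#' @param cells list of `cell_methylome` objects.
#' @param min_cells minimum number of covering cells per site.
#' @return data.frame `contig`, `site_start`, `mean_state`, `n_cells`.
#' @export
pseudo_bulk <- function(cells, min_cells = 5L) {
  stopifnot(length(cells) >= 1L)
  if (min_cells > length(cells)) {
    warning("min_cells exceeds the number of cells; empty pseudo-bulk")
  }
  all <- do.call(rbind, lapply(cells, function(m) {
    data.frame(contig = m$contig, site_start = m$site_start,
               state = m$state, stringsAsFactors = FALSE)
  }))
  if (is.null(all) || nrow(all) == 0L) {
    return(data.frame(contig = character(), site_start = integer(),
                      mean_state = numeric(), n_cells = integer()))
  }
  agg <- stats::aggregate(state ~ contig + site_start, data = all,
                          FUN = function(x) c(mean(x), length(x)))
  out <- data.frame(contig = agg$contig, site_start = agg$site_start,
                    mean_state = agg$state[, 1],
                    n_cells = as.integer(agg$state[, 2]),
                    stringsAsFactors = FALSE)
  out <- out[out$n_cells >= min_cells, , drop = FALSE]
  out <- out[order(out$contig, out$site_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise CpG concordance between two cells
#'
#' Over the sites called in both cells, the fraction with exactly equal
#' three-state methylation (0, 0.5 or 1). Symmetric; `NA` when the cells
#' share no sites.
#'
#' @param a,b `cell_methylome` objects.
#' @return list with `concordance` and `n_overlap`.
#' @export
pairwise_concordance <- function(a, b) {
  i <- match(meth_key_(a), meth_key_(b))
  ov <- !is.na(i)
  n <- sum(ov)
  conc <- if (n == 0L) NA_real_ else mean(a$state[ov] == b$state[i[ov]])
  list(concordance = conc, n_overlap = n)
}

#' All pairwise concordances among cells
#'
#' @param cells named list of `cell_methylome` objects.
#' @return symmetric matrix of concordances (diagonal 1).
#' @export
concordance_matrix <- function(cells) {
  n <- length(cells)
  ids <- names(cells) %||% as.character(seq_len(n))
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(m) <- 1
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      m[i, j] <- m[j, i] <- pairwise_concordance(cells[[i]],
                                                 cells[[j]])$concordance
    }
  }
  m
}

#' Global methylation level of one cell
#'
#' @param cell a `cell_methylome` with at least one called site.
#' @return unweighted mean state.
#' @export
global_mean <- function(cell) {
  if (nrow(cell) == 0L) stop("cell methylome has no called sites")
  mean(cell$state)
}

#' Pearson correlation of pseudo-bulk with a bulk methylome
#'
#' @param pb pseudo-bulk table from [pseudo_bulk()].
#' @param bulk data.frame `contig`, `cpg_start` (0-based CpG start,
#'   i.e. site start + 1) and `beta`.
#' @param min_cells pseudo-bulk coverage filter applied before pairing.
#' @return list with `r` (Pearson R) and `n` (paired sites).
#' @export
correlate_with_bulk <- function(pb, bulk, min_cells = 15L) {
  pb <- pb[pb$n_cells >= min_cells, , drop = FALSE]
  i <- match(paste(pb$contig, pb$site_start + 1L),
             paste(bulk$contig, bulk$cpg_start))
  ok <- !is.na(i)
  x <- pb$mean_state[ok]
  y <- bulk$beta[i[ok]]
  if (length(x) < 3L) stop("fewer than 3 shared sites after filtering")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in paired methylation vectors")
  }
  list(r = stats::cor(x, y), n = length(x))
}

#' Methylation metaprofile across features
#'
#' Sites are placed by their CpG midpoint. In `point` mode the profile
#' tiles `[anchor - flank, anchor + flank)` in `window_bp` windows
#' around the feature start (feature end for `-` strand features, with
#' window order flipped so upstream is first). In `scaled` mode the
#' flanks are tiled the same way and the variable-length feature body is
#' scaled into `body_bins` bins between them.
#'
#' @param meth a per-cell methylome or pseudo-bulk table (column `state`
#'   or `mean_state`).
#' @param features data.frame `contig`, `start`, `end`, optional
#'   `strand`.
#' @param window_bp flank window width.
#' @param flank_bp flank size on each side.
#' @param body_mode `"point"` or `"scaled"`.
#' @param body_bins number of body bins in scaled mode.
#' @return data.frame `bin`, `rel` (bin label), `mean_state`, `n_sites`;
#'   windows without sites carry `NA`.
#' @export
meta_profile <- function(meth, features, window_bp = 150L,
                         flank_bp = 3000L,
                         body_mode = c("point", "scaled"),
                         body_bins = 20L) {
  body_mode <- match.arg(body_mode)
  if (flank_bp %% window_bp != 0L) stop("flank_bp must be a multiple of window_bp")
  if (nrow(features) == 0L) stop("no features supplied")
  state <- meth$state %||% meth$mean_state
  pos <- meth$site_start + 2L  # CpG midpoint
  nf <- as.integer(flank_bp / window_bp)
  nb <- if (body_mode == "scaled") as.integer(body_bins) else 0L
  ntot <- 2L * nf + nb
  strand <- if ("strand" %in% names(features)) as.character(features$strand)
            else rep(".", nrow(features))
  sums <- numeric(ntot)
  counts <- integer(ntot)
  for (i in seq_len(nrow(features))) {
    neg <- identical(strand[i], "-")
    sel <- meth$contig == features$contig[i]
    if (!any(sel)) next
    p <- pos[sel]; st <- state[sel]
    if (body_mode == "point") {
      anchor <- if (neg) features$end[i] else features$start[i]
      bin <- floor((p - (anchor - flank_bp)) / window_bp)
      ok <- bin >= 0L & bin < ntot
      bin <- bin[ok]; stv <- st[ok]
      if (neg) bin <- ntot - 1L - bin
    } else {
      fs <- features$start[i]; fe <- features$end[i]
      bin <- integer(length(p)); ok <- logical(length(p))
      up <- p < fs; dn <- p >= fe; body <- !up & !dn
      bin[up] <- floor((p[up] - (fs - flank_bp)) / window_bp)
      ok[up] <- bin[up] >= 0L
      bin[body] <- nf + pmin(nb - 1L,
                             floor((p[body] - fs) / (fe - fs) * nb))
      ok[body] <- TRUE
      bin[dn] <- nf + nb + floor((p[dn] - fe) / window_bp)
      ok[dn] <- bin[dn] < ntot
      bin <- bin[ok]; stv <- st[ok]
      if (neg) bin <- ntot - 1L - bin
    }
    if (length(bin)) {
      sums <- sums + vapply(seq_len(ntot) - 1L,
                            function(b) sum(stv[bin == b]), numeric(1))
      counts <- counts + vapply(seq_len(ntot) - 1L,
                                function(b) sum(bin == b), integer(1))
    }
  }
  rel <- c(sprintf("flank5_%d", seq_len(nf)),
           if (nb > 0L) sprintf("body_%d", seq_len(nb)),
           sprintf("flank3_%d", seq_len(nf)))
  data.frame(bin = seq_len(ntot), rel = rel,
             mean_state = ifelse(counts > 0L, sums / pmax(counts, 1L), NA),
             n_sites = counts, stringsAsFactors = FALSE)
}

#' Per-cell mean methylation over fixed genomic windows
#'
#' Windows tile each contig; a cell's window value is the mean of its
#' called states with CpG midpoint inside the window, present only when
#' at least one called site falls inside. With `require_all_cells` only
#' windows covered in every cell are kept.
#'
#' @param cells named list of `cell_methylome` objects.
#' @param contig_lens named integer vector of contig lengths.
#' @param window_bp window size (default 200 kb).
#' @param require_all_cells keep only windows with a value in every
#'   cell.
#' @return numeric matrix, cells x windows (column names
#'   `contig:windowindex`).
#' @export
window_matrix <- function(cells, contig_lens, window_bp = 200000L,
                          require_all_cells = TRUE) {
  ids <- names(cells) %||% as.character(seq_along(cells))
  wins <- unlist(lapply(names(contig_lens), function(ctg) {
    nw <- ceiling(contig_lens[[ctg]] / window_bp)
    sprintf("%s:%d", ctg, seq_len(nw) - 1L)
  }))
  m <- matrix(NA_real_, length(cells), length(wins),
              dimnames = list(ids, wins))
  for (i in seq_along(cells)) {
    cm <- cells[[i]]
    if (nrow(cm) == 0L) next
    w <- sprintf("%s:%d", cm$contig, (cm$site_start + 2L) %/% window_bp)
    agg <- tapply(cm$state, w, mean)
    m[i, names(agg)] <- agg
  }
  if (require_all_cells && length(cells)) {
    m <- m[, colSums(is.na(m)) == 0L, drop = FALSE]
  } else {
    m <- m[, colSums(!is.na(m)) > 0L, drop = FALSE]
  }
  m
}

#' Correlation-based hierarchical clustering of cells
#'
#' Pairwise Pearson correlation over shared windows, average-linkage
#' clustering on the distance 1 - R.
#'
#' @param mat window matrix from [window_matrix()] (>= 2 cells, >= 2
#'   shared windows).
#' @return list with `R` (correlation matrix), `hc` (`hclust` object)
#'   and `order` (dendrogram leaf order).
#' @export
correlation_cluster <- function(mat) {
  if (nrow(mat) < 2L || ncol(mat) < 2L) {
    stop("need at least 2 cells and 2 windows")
  }
  R <- suppressWarnings(stats::cor(t(mat), use = "pairwise.complete.obs"))
  D <- 1 - R
  D[is.na(D)] <- max(D, 2, na.rm = TRUE)  # degenerate pairs: maximal distance
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  list(R = R, hc = hc, order = rownames(mat)[hc$order])
}
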