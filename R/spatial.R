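#' Coding-lncRNA pairs with expression correlation and TSS distance
#'
#' Enumerates all protein-coding x lncRNA pairs on the same chromosome whose
#' TSS separation is at most `max_distance_bp` (strand-agnostic, many-to-many
#' pairing) and attaches the Pearson correlation of their z-scored region
#' profiles. Genes whose profile is degenerate (constant) or absent are
#' excluded.
#'
#' @param gene_tbl Gene table from [gene_table()] (columns `gene_id`,
#'   `chrom`, `tss`, `biotype`), or a `gene_set`.
#' @param profiles Wide profile table (normalized counts).
#' @param max_distance_bp Maximum TSS separation (default 5e5).
#' @param region Region class whose profiles are correlated (default
#'   `"intron5p"`, the activation-timing signal).
#' @param bin_width_bp Width of the display distance bins (default 25 kb).
#' @return Data frame: `coding_id`, `lnc_id`, `chrom`, `tss_distance`,
#'   `pearson_r`, `distance_bin`.
#' @export
make_pairs <- function(gene_tbl, profiles, max_distance_bp = 5e5,
                       region = "intron5p", bin_width_bp = 25000) {
  if (inherits(gene_tbl, "gene_set")) gene_tbl <- gene_table(gene_tbl)
  z <- zscore_rows(region_matrix(profiles, region))
  z <- z[!apply(is.na(z), 1L, any), , drop = FALSE]
  tbl <- gene_tbl[gene_tbl$gene_id %in% rownames(z), , drop = FALSE]
  pairs <- .enumerate_pairs(tbl, max_distance_bp)
  if (nrow(pairs) > 0L) {
    pairs$pearson_r <- rowMeans(z[pairs$coding_id, , drop = FALSE] *
                                  z[pairs$lnc_id, , drop = FALSE])
  } else {
    pairs$pearson_r <- numeric(0)
  }
  pairs$distance_bin <- distance_bins(pairs$tss_distance, max_distance_bp,
                                      bin_width_bp)
  pairs
}

# all intra-chromosomal coding x lncRNA pairs within max_dist
.enumerate_pairs <- function(tbl, max_dist) {
  out <- list()
  for (ch in unique(tbl$chrom)) {
    sub <- tbl[tbl$chrom == ch, , drop = FALSE]
    cod <- sub[sub$biotype == "protein_coding", , drop = FALSE]
    lnc <- sub[sub$biotype == "lncRNA", , drop = FALSE]
    if (nrow(cod) == 0L || nrow(lnc) == 0L) next
    idx <- expand.grid(ci = seq_len(nrow(cod)), li = seq_len(nrow(lnc)))
    d <- abs(cod$tss[idx$ci] - lnc$tss[idx$li])
    keep <- d <= max_dist
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      coding_id = cod$gene_id[idx$ci[keep]],
      lnc_id = lnc$gene_id[idx$li[keep]],
      chrom = ch, tss_distance = d[keep], stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(coding_id = character(0), lnc_id = character(0),
                      chrom = character(0), tss_distance = numeric(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Label distances with display bins
#' @param d Distances in bp.
#' @param max_bp Upper bound of the last bin.
#' @param width_bp Bin width (default 25 kb).
#' @return Factor of bin labels.
#' @export
distance_bins <- function(d, max_bp = 5e5, width_bp = 25000) {
  breaks <- seq(0, max_bp, by = width_bp)
  if (breaks[length(breaks)] < max_bp) breaks <- c(breaks, max_bp)
  cut(d, breaks = breaks, include.lowest = TRUE, right = TRUE)
}

#' GAM trend of correlation versus separation distance
#'
#' Penalized-spline smooth (basis dimension `k`, smoothness chosen by GCV) of
#' pairwise Pearson correlation against unbinned TSS distance.
#'
#' @param pairs Pair table from [make_pairs()].
#' @param k Spline basis dimension (default 10).
#' @param min_pairs Minimum pairs required (default 50, spanning >= 3
#'   distance bins).
#' @return List of class `gam_trend`: `model` (the mgcv fit), `edf`
#'   (effective degrees of freedom of the smooth) and `predict(d)`.
#' @export
gam_trend <- function(pairs, k = 10, min_pairs = 50) {
  if (nrow(pairs) < min_pairs)
    stop2("too_few_pairs", "need at least %d pairs (got %d)",
          min_pairs, nrow(pairs))
  if (length(unique(distance_bins(pairs$tss_distance))) < 3L)
    stop2("too_few_pairs", "pairs must span at least 3 distance bins")
  fit <- .gam_fit(pairs$tss_distance, pairs$pearson_r, k)
  structure(list(
    model = fit,
    edf = sum(fit$edf) - 1,
    predict = function(d)
      as.numeric(mgcv::predict.gam(fit, newdata = data.frame(d = d)))
  ), class = "gam_trend")
}

.gam_fit <- function(d, r, k = 10) {
  kk <- min(k, max(3L, length(unique(d)) - 1L))
  mgcv::gam(r ~ s(d, k = kk, bs = "ps"), data = data.frame(d = d, r = r),
            method = "GCV.Cp")
}

# trend values on a fixed evaluation grid, refitting the GAM on (d, r)
.trend_on_grid <- function(d, r, grid, k = 10) {
  fit <- .gam_fit(d, r, k)
  as.numeric(mgcv::predict.gam(fit, newdata = data.frame(d = grid)))
}

# default evaluation grid over the observed distance range
.eval_grid <- function(d, n = 50L) {
  seq(min(d), max(d), length.out = n)
}

#' Choose the block size for the block bootstrap
#'
#' Shuffles separation distances `n_perm` times (keeping the correlations),
#' refits the GAM trend to each shuffle, and takes the pointwise 99th
#' quantile of the shuffled trends as the null band. The block size is the
#' largest evaluation distance at which the unpermuted trend still exceeds
#' that quantile — the spatial extent over which profiles cannot be treated
#' as independent. If the observed trend never exceeds the null band the
#' configured minimum block size is returned with `flagged = TRUE`.
#'
#' @param pairs Pair table from [make_pairs()].
#' @param n_perm Number of shuffles (>= 100; default 1000).
#' @param seed Integer seed.
#' @param min_block_bp Fallback/minimum block size; the default (500 kb, the
#'   maximum pairing distance) keeps blocks large enough to preserve the
#'   gene-neighborhood clustering that generates pairs.
#' @param k,grid_n GAM basis dimension and evaluation-grid size.
#' @return List of class `block_size_choice`: `block_size` (bp), `flagged`,
#'   `eval_distances`, `observed`, `q99`.
#' @export
choose_block_size <- function(pairs, n_perm = 1000L, seed = 1L,
                              min_block_bp = 5e5, k = 10, grid_n = 50L) {
  if (n_perm < 100L)
    stop2("bad_nperm", "n_perm must be at least 100 for a stable 99th quantile")
  grid <- .eval_grid(pairs$tss_distance, grid_n)
  obs <- .trend_on_grid(pairs$tss_distance, pairs$pearson_r, grid, k)
  perm <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(i) {
      .trend_on_grid(sample(pairs$tss_distance), pairs$pearson_r, grid, k)
    }, numeric(length(grid)))
  })
  q99 <- apply(perm, 1L, stats::quantile, probs = 0.99, names = FALSE)
  exceed <- obs > q99
  if (!any(exceed)) {
    block <- min_block_bp
    flagged <- TRUE
  } else {
    block <- max(grid[exceed])
    flagged <- FALSE
  }
  structure(list(block_size = block, flagged = flagged,
                 eval_distances = grid, observed = obs, q99 = q99),
            class = "block_size_choice")
}

# Resample chromosome blocks with replacement and re-anchor gene TSS
# positions to the sampled block offsets (pseudochromosomes). Genes are
# assigned to blocks by TSS; a block drawn twice duplicates its genes.
.pseudochromosome <- function(gene_tbl, block_size) {
  out <- list()
  for (ch in unique(gene_tbl$chrom)) {
    sub <- gene_tbl[gene_tbl$chrom == ch, , drop = FALSE]
    L <- max(sub$tss) + 1
    nb <- max(1L, ceiling(L / block_size))
    drawn <- sample.int(nb, nb, replace = TRUE)
    blk <- floor(sub$tss / block_size)  # 0-based block index per gene
    for (s in seq_len(nb)) {
      b <- drawn[s] - 1L
      sel <- blk == b
      if (!any(sel)) next
      piece <- sub[sel, , drop = FALSE]
      piece$tss <- (s - 1L) * block_size + (piece$tss - b * block_size)
      out[[length(out) + 1L]] <- piece
    }
  }
  if (length(out) == 0L) return(gene_tbl[0, , drop = FALSE])
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Block-bootstrap simulation envelope for the distance-correlation trend
#'
#' Each iteration splits every chromosome into contiguous blocks of
#' `block_size` bp, resamples blocks with replacement to build
#' pseudochromosomes (gene positions re-anchored to the sampled block
#' offsets, so within-block adjacency — and hence local spatial
#' autocorrelation — is preserved), re-derives all coding/lncRNA pairs from
#' the resampled positions, and refits the GAM trend. The envelope is the
#' pointwise 1st/99th percentile band across iterations; an observed trend
#' outside the band indicates a distance-correlation relationship beyond
#' what chromosomal autocorrelation alone produces.
#'
#' @param gene_tbl Gene table (or `gene_set`).
#' @param profiles Wide profile table.
#' @param block_size Block size in bp (see [choose_block_size()]).
#' @param n_boot Bootstrap iterations (default 1000).
#' @param seed Integer seed (results are deterministic given the seed).
#' @param max_distance_bp,region As in [make_pairs()].
#' @param k,grid_n GAM basis dimension and evaluation-grid size.
#' @return List of class `envelope_result`: `eval_distances`, `trend`
#'   (observed), `lo`, `hi` (1st/99th percentile bounds), `exceeds_envelope`
#'   (logical per grid point), `n_boot`, `block_size`.
#' @export
block_bootstrap_envelope <- function(gene_tbl, profiles, block_size,
                                     n_boot = 1000L, seed = 1L,
                                     max_distance_bp = 5e5,
                                     region = "intron5p",
                                     k = 10, grid_n = 50L) {
  if (block_size <= 0) stop2("bad_block", "block_size must be positive")
  if (inherits(gene_tbl, "gene_set")) gene_tbl <- gene_table(gene_tbl)
  z <- zscore_rows(region_matrix(profiles, region))
  z <- z[!apply(is.na(z), 1L, any), , drop = FALSE]
  tbl <- gene_tbl[gene_tbl$gene_id %in% rownames(z), , drop = FALSE]
  for (ch in unique(tbl$chrom)) {
    if (block_size > max(tbl$tss[tbl$chrom == ch]) + 1)
      warning(sprintf("block size exceeds chromosome %s: single-block", ch))
  }
  obs_pairs <- .enumerate_pairs(tbl, max_distance_bp)
  obs_pairs$pearson_r <- rowMeans(z[obs_pairs$coding_id, , drop = FALSE] *
                                    z[obs_pairs$lnc_id, , drop = FALSE])
  grid <- .eval_grid(obs_pairs$tss_distance, grid_n)
  obs <- .trend_on_grid(obs_pairs$tss_distance, obs_pairs$pearson_r, grid, k)
  boot <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(i) {
      ps <- .pseudochromosome(tbl, block_size)
      pp <- .enumerate_pairs(ps, max_distance_bp)
      if (nrow(pp) < 10L) return(rep(NA_real_, length(grid)))
      r <- rowMeans(z[pp$coding_id, , drop = FALSE] *
                      z[pp$lnc_id, , drop = FALSE])
      tryCatch(.trend_on_grid(pp$tss_distance, r, grid, k),
               error = function(e) rep(NA_real_, length(grid)))
    }, numeric(length(grid)))
  })
  lo <- apply(boot, 1L, stats::quantile, probs = 0.01, na.rm = TRUE,
              names = FALSE)
  hi <- apply(boot, 1L, stats::quantile, probs = 0.99, na.rm = TRUE,
              names = FALSE)
  structure(list(eval_distances = grid, trend = obs, lo = lo, hi = hi,
                 exceeds_envelope = obs < lo | obs > hi,
                 n_boot = n_boot, block_size = block_size),
            class = "envelope_result")
}

#' @export
print.envelope_result <- function(x, ...) {
  cat(sprintf(
    "Block-bootstrap envelope: %d iterations, block %g bp; %d/%d grid points outside\n",
    x$n_boot, x$block_size, sum(x$exceeds_envelope),
    length(x$exceeds_envelope)))
  invisible(x)
}

#' Classify lncRNAs by proximity of candidate cis-regulatory elements
#'
#' Flags each lncRNA whose TSS lies within `within_bp` of any supplied
#' candidate cis-regulatory element (strand-agnostic interval query),
#' mirroring promoter/enhancer association calls based on a cCRE registry.
#'
#' @param gene_tbl Gene table (or `gene_set`).
#' @param elements A `GRanges` of candidate elements, or a path to a BED
#'   file.
#' @param within_bp Maximum TSS-to-element distance (default 300).
#' @return Data frame: `gene_id`, `biotype`, `ccre_associated`.
#' @export
classify_ccre_proximity <- function(gene_tbl, elements, within_bp = 300) {
  if (inherits(gene_tbl, "gene_set")) gene_tbl <- gene_table(gene_tbl)
  if (is.character(elements))
    elements <- rtracklayer::import(elements, format = "bed")
  tss <- GenomicRanges::GRanges(
    seqnames = gene_tbl$chrom,
    ranges = IRanges::IRanges(start = gene_tbl$tss + 1, width = 1))
  hit <- GenomicRanges::countOverlaps(tss, elements,
                                      maxgap = within_bp) > 0
  data.frame(gene_id = gene_tbl$gene_id, biotype = gene_tbl$biotype,
             ccre_associated = hit, stringsAsFactors = FALSE)
}
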