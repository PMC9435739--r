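#' Build a gene model
#'
#' A gene model records the genomic substrate used for region-restricted
#' quantification: coordinates (0-based, half-open; conversions to 1-based
#' happen only at file boundaries), strand, biotype and the exon/intron
#' structure. Introns are derived as the gaps between exons, so exons and
#' introns tile `[start, end)` without overlap.
#'
#' @param gene_id Character scalar.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param start,end Gene span, 0-based half-open.
#' @param biotype `"protein_coding"` or `"lncRNA"`.
#' @param exons Two-column matrix of exon `[start, end)` intervals, ascending
#'   and non-overlapping, with `exons[1,1] == start` and
#'   `exons[n,2] == end`.
#' @return A list of class `gene_model` with fields `gene_id`, `chrom`,
#'   `strand`, `start`, `end`, `tss`, `biotype`, `exons`, `introns`.
#' @export
gene_model <- function(gene_id, chrom, strand, start, end, biotype, exons) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L,
            strand %in% c("+", "-"),
            biotype %in% c("protein_coding", "lncRNA"),
            is.matrix(exons), ncol(exons) == 2L, nrow(exons) >= 1L)
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (exons[1L, 1L] != start || exons[nrow(exons), 2L] != end)
    stop2("bad_gene_model", "first/last exon must reach the gene boundaries")
  if (any(exons[, 2L] <= exons[, 1L]))
    stop2("bad_gene_model", "empty exon interval")
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop2("bad_gene_model", "overlapping exons")
  n <- nrow(exons)
  introns <- if (n > 1L) {
    cbind(exons[-n, 2L], exons[-1L, 1L], deparse.level = 0)
  } else {
    matrix(numeric(0), ncol = 2L)
  }
  introns <- introns[introns[, 2L] > introns[, 1L], , drop = FALSE]
  structure(list(
    gene_id = gene_id, chrom = chrom, strand = strand,
    start = start, end = end,
    tss = if (strand == "+") start else end - 1L,
    biotype = biotype, exons = exons, introns = introns
  ), class = "gene_model")
}

gene_length <- function(gene) gene$end - gene$start
intron_total <- function(gene) {
  if (nrow(gene$introns) == 0L) 0 else sum(gene$introns[, 2L] - gene$introns[, 1L])
}

#' First or last window of concatenated intronic sequence
#'
#' Walks a gene's introns in transcription order (strand-aware) and returns
#' the genomic intervals covering the first (`five_prime`) or last
#' (`three_prime`) `window_kb` kilobases of concatenated intronic sequence —
#' intron bases counted from the TSS, excluding exon sequence. If the gene's
#' total intron length is below the window, all introns are returned and the
#' result is flagged short (attribute `"short"`).
#'
#' @param gene A [gene_model].
#' @param window_kb Window size in kb (default 10).
#' @param end `"five_prime"` or `"three_prime"`.
#' @return Two-column matrix of 0-based half-open intervals, ascending by
#'   genomic coordinate; attribute `"short"` is `TRUE` when intron total <
#'   window.
#' @export
region_windows <- function(gene, window_kb = 10,
                           end = c("five_prime", "three_prime")) {
  end <- match.arg(end)
  stopifnot(inherits(gene, "gene_model"), window_kb > 0)
  if (nrow(gene$introns) == 0L)
    stop2("no_intron", "gene %s has no introns", gene$gene_id)
  introns <- gene$introns
  # take bases from the genomic-left side of each intron when walking in
  # ascending coordinate order; that holds for 5' windows of + genes and 3'
  # windows of - genes
  from_left <- (gene$strand == "+") == (end == "five_prime")
  ord <- if (from_left) seq_len(nrow(introns)) else rev(seq_len(nrow(introns)))
  remaining <- window_kb * 1000
  out <- list()
  for (i in ord) {
    if (remaining <= 0) break
    len <- introns[i, 2L] - introns[i, 1L]
    take <- min(len, remaining)
    out[[length(out) + 1L]] <- if (from_left) {
      c(introns[i, 1L], introns[i, 1L] + take)
    } else {
      c(introns[i, 2L] - take, introns[i, 2L])
    }
    remaining <- remaining - take
  }
  res <- do.call(rbind, out)
  res <- res[order(res[, 1L]), , drop = FALSE]
  attr(res, "short") <- remaining > 0
  res
}

#' 1-kb tiles of concatenated intronic sequence in transcription order
#'
#' Splits a gene's concatenated intronic sequence into consecutive tiles of
#' exactly `tile_kb` kilobases, ordered 5' to 3' in the direction of
#' transcription; the trailing partial tile is dropped. Used to visualize the
#' transcription wave moving across a gene body.
#'
#' @param gene A [gene_model] with >= 2 kb of intron.
#' @param tile_kb Tile size in kb (default 1).
#' @return Data frame with columns `tile` (1-based index in transcription
#'   order), `start`, `end` (0-based half-open genomic coordinates). Tiles
#'   never span an intron boundary gap: a tile may be represented by more
#'   than one row (same `tile` index) when it crosses exons.
#' @export
intron_tiles <- function(gene, tile_kb = 1) {
  stopifnot(inherits(gene, "gene_model"), tile_kb > 0)
  if (nrow(gene$introns) == 0L)
    stop2("no_intron", "gene %s has no introns", gene$gene_id)
  tile_bp <- tile_kb * 1000
  total <- intron_total(gene)
  n_tiles <- floor(total / tile_bp)
  if (n_tiles < 1L)
    stop2("no_intron", "gene %s has < %g kb of intron", gene$gene_id, tile_kb)
  introns <- gene$introns
  plus <- gene$strand == "+"
  ord <- if (plus) seq_len(nrow(introns)) else rev(seq_len(nrow(introns)))
  rows <- list()
  offset <- 0  # transcribed intronic bases consumed so far
  for (i in ord) {
    s <- introns[i, 1L]; e <- introns[i, 2L]
    len <- e - s
    pos <- 0
    while (pos < len) {
      tile_idx <- floor(offset / tile_bp) + 1
      if (tile_idx > n_tiles) break
      chunk <- min(len - pos, tile_bp - offset %% tile_bp)
      gs <- if (plus) s + pos else e - pos - chunk
      rows[[length(rows) + 1L]] <- data.frame(
        tile = tile_idx, start = gs, end = gs + chunk)
      pos <- pos + chunk
      offset <- offset + chunk
    }
    if (offset >= n_tiles * tile_bp) break
  }
  out <- do.call(rbind, rows)
  out[order(out$tile, out$start), , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Per-time-point scale factors computed by the median-of-ratios method:
#' each column's factor is the median, over genes with all-positive counts,
#' of that gene's count divided by its geometric mean across columns.
#' Dividing each column by its factor normalizes the matrix.
#'
#' @param count_matrix Numeric matrix, rows = gene/region features, columns =
#'   time points (>= 2).
#' @return Named positive numeric vector, one factor per column.
#' @examples
#' m <- cbind(a = c(10, 100, 4), b = c(20, 200, 8))
#' size_factors(m)  # c(1/sqrt(2), sqrt(2))
#' @export
size_factors <- function(count_matrix) {
  m <- as.matrix(count_matrix)
  if (ncol(m) < 2L)
    stop2("bad_counts", "need at least 2 time points")
  keep <- rowSums(m > 0) == ncol(m)
  if (!any(keep))
    stop2("unnormalizable",
          "no gene has all-positive counts; size factors undefined")
  mk <- m[keep, , drop = FALSE]
  geo <- exp(rowMeans(log(mk)))
  apply(mk / geo, 2L, stats::median)
}

#' Normalize a count table by size factors
#'
#' @param counts Wide count data frame (`gene_id`, `region`, time columns).
#' @param factors Size factors from [size_factors()]; computed from `counts`
#'   when omitted.
#' @return The table with each time column divided by its factor; attribute
#'   `"size_factors"` records the factors used.
#' @export
normalize_counts <- function(counts, factors = NULL) {
  m <- profile_matrix(counts)
  if (is.null(factors)) factors <- size_factors(m)
  stopifnot(length(factors) == ncol(m), all(factors > 0))
  norm <- sweep(m, 2L, factors, "/")
  out <- counts
  out[, setdiff(names(counts), c("gene_id", "region"))] <- norm
  attr(out, "size_factors") <- factors
  out
}

#' z-score a single expression profile
#'
#' Centers and scales by the population standard deviation (divisor n).
#'
#' @param x Numeric vector, non-constant.
#' @return z-scored vector with mean 0 and population sd 1.
#' @export
zscore <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2L)
  s <- sd_pop(x)
  if (s < 1e-12)
    stop2("degenerate_profile", "constant profile cannot be z-scored")
  (x - mean(x)) / s
}

#' z-score every profile in a wide table
#'
#' Constant (degenerate) rows cannot be z-scored; they are dropped and their
#' `gene_id:region` keys recorded in the `"degenerate"` attribute, mirroring
#' their exclusion from clustering and correlation analyses.
#'
#' @param profiles Wide profile data frame.
#' @return The table with each row z-scored (population sd); attribute
#'   `"degenerate"` lists dropped row keys.
#' @export
zscore_profiles <- function(profiles) {
  m <- profile_matrix(profiles)
  z <- zscore_rows(m)
  bad <- apply(is.na(z), 1L, any)
  out <- profiles[!bad, , drop = FALSE]
  out[, setdiff(names(profiles), c("gene_id", "region"))] <-
    z[!bad, , drop = FALSE]
  attr(out, "degenerate") <- rownames(m)[bad]
  out
}
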