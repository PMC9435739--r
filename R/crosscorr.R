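#' Lagged cross-correlation between two expression profiles
#'
#' For each lag (a multiple of the sampling step, within `±max_lag`),
#' computes the Pearson correlation between the lagged lncRNA profile and
#' the fixed coding profile over their truncated overlap (no padding).
#' Sign convention: the reported correlation at lag `l` is
#' `cor(lnc(t + l), coding(t))`, so a NEGATIVE peak lag means the lncRNA
#' profile precedes the coding profile (the lncRNA must be shifted later in
#' time to align with the coding gene).
#'
#' @param lnc_values,coding_values Profiles on the same evenly spaced grid.
#' @param times Time grid in minutes.
#' @param max_lag Maximum |lag| in minutes (default 200).
#' @param min_overlap Minimum overlapping points required at the extreme lag
#'   (default 8).
#' @return Data frame with columns `lag` (minutes) and `r`; `r` is `NA` where
#'   an overlap window is constant.
#' @export
ccf_pair <- function(lnc_values, coding_values, times, max_lag = 200,
                     min_overlap = 8L) {
  stopifnot(length(lnc_values) == length(times),
            length(coding_values) == length(times))
  step <- unique(round(diff(times), 9))
  if (length(step) != 1L)
    stop2("bad_series", "time grid must be evenly spaced")
  n <- length(times)
  k_max <- floor(max_lag / step)
  if (n - k_max < min_overlap)
    stop2("bad_series",
          "fewer than %d overlapping points at the maximum lag", min_overlap)
  r <- .ccf_matrix(matrix(lnc_values, nrow = 1L),
                   matrix(coding_values, nrow = 1L), k_max)
  data.frame(lag = seq(-k_max, k_max) * step, r = as.numeric(r))
}

# rows of A (lnc) cross-correlated with matched rows of B (coding) at all
# step lags in -k_max..k_max; returns pairs x lags matrix.
# r(+k): cor(A[, (1+k):n], B[, 1:(n-k)])  == cor(lnc(t + k*step), coding(t))
.ccf_matrix <- function(A, B, k_max) {
  n <- ncol(A)
  out <- matrix(NA_real_, nrow(A), 2L * k_max + 1L)
  trunc_cor <- function(X, Y) {
    mx <- rowMeans(X); my <- rowMeans(Y)
    sx <- sqrt(rowMeans(X^2) - mx^2)
    sy <- sqrt(rowMeans(Y^2) - my^2)
    r <- (rowMeans(X * Y) - mx * my) / (sx * sy)
    r[sx < 1e-12 | sy < 1e-12] <- NA_real_
    pmin(pmax(r, -1), 1)
  }
  for (k in seq.int(-k_max, k_max)) {
    j <- k + k_max + 1L
    out[, j] <- if (k >= 0) {
      trunc_cor(A[, (1L + k):n, drop = FALSE], B[, 1L:(n - k), drop = FALSE])
    } else {
      trunc_cor(A[, 1L:(n + k), drop = FALSE], B[, (1L - k):n, drop = FALSE])
    }
  }
  out
}

# peak lag with ties broken toward the smallest |lag|, then negative
.peak_lag <- function(lags, r, tol = 1e-12) {
  if (all(is.na(r))) return(NA_real_)
  top <- max(r, na.rm = TRUE)
  cand <- lags[!is.na(r) & r >= top - tol]
  cand[order(abs(cand), cand)][1L]
}

#' Distance-binned mean cross-correlation between paired profiles
#'
#' Computes the lagged cross-correlation of every coding/lncRNA pair (the
#' lncRNA profile lagged, the coding profile fixed) and averages the
#' correlation curves within TSS-distance bins. The per-bin peak lag is the
#' argmax of the mean curve; exact ties are broken toward the smallest
#' absolute lag (the synchrony null), then toward the negative lag.
#'
#' @param pairs Pair table (columns `coding_id`, `lnc_id`, `tss_distance`),
#'   e.g. from [make_pairs()].
#' @param profiles Wide profile table.
#' @param distance_breaks Bin edges in bp (default 0, 50 kb, 150 kb, 500 kb).
#' @param max_lag Maximum |lag| in minutes (default 200).
#' @param lnc_region Region used for lncRNA profiles (default `"intron5p"`).
#' @param coding_region Region used for coding profiles (default
#'   `"intron5p"`; use `"exon"` to measure coding genes by mature mRNA).
#' @return List of class `ccf_result`: `lags` (minutes), `bins`, `mean_ccf`
#'   (bins x lags matrix), `peak_lag` (per bin), `n_pairs` (per bin).
#' @export
binned_mean_ccf <- function(pairs, profiles,
                            distance_breaks = c(0, 5e4, 15e4, 5e5),
                            max_lag = 200,
                            lnc_region = "intron5p",
                            coding_region = "intron5p") {
  times <- profile_times(profiles)
  step <- diff(times)[1L]
  k_max <- floor(max_lag / step)
  lnc_m <- region_matrix(profiles, lnc_region)
  cod_m <- region_matrix(profiles, coding_region)
  keep <- pairs$lnc_id %in% rownames(lnc_m) &
    pairs$coding_id %in% rownames(cod_m)
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0L) stop2("too_few_pairs", "no usable pairs")
  cc <- .ccf_matrix(lnc_m[pairs$lnc_id, , drop = FALSE],
                    cod_m[pairs$coding_id, , drop = FALSE], k_max)
  lags <- seq(-k_max, k_max) * step
  bin <- cut(pairs$tss_distance, breaks = distance_breaks,
             include.lowest = TRUE, right = TRUE)
  mean_ccf <- do.call(rbind, lapply(levels(bin), function(b) {
    sel <- which(bin == b)
    if (length(sel) == 0L) return(rep(NA_real_, length(lags)))
    colMeans(cc[sel, , drop = FALSE], na.rm = TRUE)
  }))
  rownames(mean_ccf) <- levels(bin)
  colnames(mean_ccf) <- lags
  peak <- apply(mean_ccf, 1L, function(r) .peak_lag(lags, r))
  structure(list(lags = lags, bins = levels(bin), mean_ccf = mean_ccf,
                 peak_lag = peak,
                 n_pairs = as.integer(table(bin)[levels(bin)]),
                 convention = "negative peak lag: lncRNA precedes coding"),
            class = "ccf_result")
}

#' @export
print.ccf_result <- function(x, ...) {
  cat("Distance-binned mean cross-correlation\n")
  for (i in seq_along(x$bins)) {
    cat(sprintf("  %-18s n = %4d  peak lag = %+g min\n",
                x$bins[i], x$n_pairs[i], x$peak_lag[i]))
  }
  cat(sprintf("  (%s)\n", x$convention))
  invisible(x)
}

#' Block-bootstrap envelope for binned cross-correlation curves
#'
#' Reuses the pseudochromosome machinery of
#' [block_bootstrap_envelope()]: each iteration resamples chromosome blocks
#' with replacement, re-derives coding/lncRNA pairs from the resampled
#' positions, and recomputes the distance-binned mean cross-correlation.
#' The envelope is the pointwise (per bin, per lag) 1st/99th percentile band
#' across iterations.
#'
#' @param gene_tbl Gene table (or `gene_set`).
#' @param profiles Wide profile table.
#' @param block_size Block size in bp.
#' @param n_boot Iterations (default 1000).
#' @param seed Integer seed.
#' @param distance_breaks,max_lag,lnc_region,coding_region As in
#'   [binned_mean_ccf()].
#' @return List of class `ccf_envelope`: `observed` (a `ccf_result`), `lo`,
#'   `hi` (bins x lags matrices), `n_boot`, `block_size`.
#' @export
ccf_envelope <- function(gene_tbl, profiles, block_size, n_boot = 1000L,
                         seed = 1L, distance_breaks = c(0, 5e4, 15e4, 5e5),
                         max_lag = 200, lnc_region = "intron5p",
                         coding_region = "intron5p") {
  if (block_size <= 0) stop2("bad_block", "block_size must be positive")
  if (inherits(gene_tbl, "gene_set")) gene_tbl <- gene_table(gene_tbl)
  max_dist <- max(distance_breaks)
  obs_pairs <- make_pairs(gene_tbl, profiles, max_dist, region = lnc_region)
  observed <- binned_mean_ccf(obs_pairs, profiles, distance_breaks, max_lag,
                              lnc_region, coding_region)
  dims <- dim(observed$mean_ccf)
  boot <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_boot), function(i) {
      ps <- .pseudochromosome(gene_tbl, block_size)
      pp <- .enumerate_pairs(ps, max_dist)
      if (nrow(pp) == 0L) return(matrix(NA_real_, dims[1L], dims[2L]))
      tryCatch(
        binned_mean_ccf(pp, profiles, distance_breaks, max_lag,
                        lnc_region, coding_region)$mean_ccf,
        error = function(e) matrix(NA_real_, dims[1L], dims[2L]))
    })
  })
  arr <- array(unlist(boot), dim = c(dims, n_boot))
  lo <- apply(arr, c(1L, 2L), stats::quantile, probs = 0.01, na.rm = TRUE,
              names = FALSE)
  hi <- apply(arr, c(1L, 2L), stats::quantile, probs = 0.99, na.rm = TRUE,
              names = FALSE)
  dimnames(lo) <- dimnames(hi) <- dimnames(observed$mean_ccf)
  structure(list(observed = observed, lo = lo, hi = hi,
                 n_boot = n_boot, block_size = block_size),
            class = "ccf_envelope")
}
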