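#' Ljung-Box test for serial autocorrelation of one profile
#'
#' Computes \eqn{Q = n(n+2)\sum_{k=1}^{h} \hat\rho_k^2 / (n-k)} and the
#' chi-square p-value with `n_lags` degrees of freedom (via
#' [stats::Box.test()]). Time-structured (activated) genes show strong serial
#' autocorrelation; flat genes do not.
#'
#' @param values Numeric series, longer than `n_lags + 1`, non-constant.
#' @param n_lags Number of lags `h`; default `min(10, floor(n/4))`.
#' @return List with `Q` (statistic), `df` (lags used) and `p`.
#' @export
ljung_box <- function(values, n_lags = NULL) {
  stopifnot(is.numeric(values))
  n <- length(values)
  if (is.null(n_lags)) n_lags <- min(10L, floor(n / 4))
  if (n <= n_lags + 1L)
    stop2("bad_series", "series length must exceed n_lags + 1")
  if (sd_pop(values) < 1e-12)
    stop2("degenerate_profile", "constant series has no defined autocorrelation")
  bt <- stats::Box.test(values, lag = n_lags, type = "Ljung-Box")
  list(Q = unname(bt$statistic), df = n_lags, p = unname(bt$p.value))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (capped at 1, order-preserving), via
#' [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop2("bad_pvalues", "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Screen profiles for activated (time-structured) genes
#'
#' Applies the Ljung-Box test to every profile row, adjusts all p-values
#' jointly by Benjamini-Hochberg, and calls a row activated when its adjusted
#' p-value falls below `threshold`. A gene is considered activated when any
#' of its region profiles is (the union rule; use
#' [activated_gene_ids()] for the gene-level set). Constant profiles cannot
#' be tested and are reported as not activated with reason `"degenerate"`.
#'
#' @param profiles Wide profile data frame (normalized counts).
#' @param threshold Adjusted-p threshold (default 0.01).
#' @param n_lags Ljung-Box lags; default `min(10, floor(n/4))`.
#' @return Data frame with one row per (gene, region): `gene_id`, `region`,
#'   `ljung_box_Q`, `df`, `p`, `p_adj`, `activated`, `reason`.
#' @export
screen_genes <- function(profiles, threshold = 0.01, n_lags = NULL) {
  if (nrow(profiles) == 0L)
    stop2("nothing_to_screen", "no profiles to screen")
  m <- profile_matrix(profiles)
  res <- data.frame(gene_id = profiles$gene_id, region = profiles$region,
                    ljung_box_Q = NA_real_, df = NA_integer_,
                    p = NA_real_, p_adj = NA_real_,
                    activated = FALSE, reason = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    if (sd_pop(x) < 1e-12) {
      res$reason[i] <- "degenerate"
      next
    }
    lb <- ljung_box(x, n_lags)
    res$ljung_box_Q[i] <- lb$Q
    res$df[i] <- lb$df
    res$p[i] <- lb$p
  }
  ok <- !is.na(res$p)
  res$p_adj[ok] <- bh_adjust(res$p[ok])
  res$activated <- !is.na(res$p_adj) & res$p_adj < threshold
  res
}

#' Gene-level activated set from a screen result
#'
#' @param screen_result Output of [screen_genes()].
#' @return Character vector of gene ids with at least one activated region.
#' @export
activated_gene_ids <- function(screen_result) {
  sort(unique(screen_result$gene_id[screen_result$activated]))
}

#' Select one representative transcript per gene
#'
#' Picks the transcript with the highest length-adjusted counts (total counts
#' divided by transcript length). Ties on density are broken by the longest
#' transcript, then by lexicographic id.
#'
#' @param transcripts Data frame with columns `transcript_id`, `counts`
#'   (total counts) and `length` (bp, positive).
#' @return The selected `transcript_id`.
#' @export
select_transcript <- function(transcripts) {
  stopifnot(nrow(transcripts) >= 1L, all(transcripts$length > 0))
  dens <- transcripts$counts / transcripts$length
  ord <- order(-dens, -transcripts$length, transcripts$transcript_id)
  transcripts$transcript_id[ord[1L]]
}
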