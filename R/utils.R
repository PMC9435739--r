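# Internal helpers shared across modules.

# classed conditions so callers can distinguish failure modes
stop2 <- function(class, msg, ...) {
  stop(structure(class = c(paste0("introntime_", class), "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

# population standard deviation (divisor n, not n-1)
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Extract the time grid of a profile table
#'
#' Profile and count tables are wide data frames with columns `gene_id`,
#' `region`, then one numeric column per time point, labelled with minutes.
#'
#' @param profiles A wide profile/count data frame.
#' @return Numeric vector of time points in minutes.
#' @export
profile_times <- function(profiles) {
  cn <- setdiff(names(profiles), c("gene_id", "region"))
  tt <- suppressWarnings(as.numeric(cn))
  if (anyNA(tt))
    stop2("bad_profiles", "non-numeric time-point column labels: %s",
          paste(cn[is.na(tt)], collapse = ", "))
  tt
}

#' Convert a wide profile table to a numeric matrix
#'
#' @param profiles A wide profile/count data frame (`gene_id`, `region`,
#'   one column per time point).
#' @return Numeric matrix, rows named `"<gene_id>:<region>"`, one column per
#'   time point.
#' @export
profile_matrix <- function(profiles) {
  tt <- profile_times(profiles)
  m <- as.matrix(profiles[, setdiff(names(profiles), c("gene_id", "region")),
                          drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- paste(profiles$gene_id, profiles$region, sep = ":")
  colnames(m) <- as.character(tt)
  m
}

# rows of `profiles` for one region, as a gene_id-named matrix
region_matrix <- function(profiles, region) {
  sub <- profiles[profiles$region == region, , drop = FALSE]
  m <- profile_matrix(sub)
  rownames(m) <- sub$gene_id
  m
}

# row-wise population z-scoring of a matrix; constant rows -> NA rows
zscore_rows <- function(m) {
  mu <- rowMeans(m)
  s <- sqrt(rowMeans((m - mu)^2))
  z <- (m - mu) / s
  z[s < 1e-12, ] <- NA_real_
  z
}

# Pearson correlation between matched rows of two matrices (same dims)
rowwise_pearson <- function(a, b) {
  za <- zscore_rows(a)
  zb <- zscore_rows(b)
  rowMeans(za * zb)
}
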