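#' Configuration for the synthetic time-course generator
#'
#' Defines the study conditions the simulator emulates: a dense RNA-seq time
#' course (default 41 points at 10-minute intervals, 0-400 min) over a
#' synthetic genome in which activated protein-coding genes (mean length
#' 51.8 kb) are flanked by shorter lncRNAs (mean length 16.6 kb) placed
#' within `max_pair_distance_bp` of the coding TSS. Pre-mRNA activation is
#' impulse-shaped at the TSS and propagates across the gene body at the
#' elongation rate, mature mRNA follows the first-order balance
#' dM/dt = beta*P - alpha*M with half-lives spanning minutes to hours, and
#' counts are negative-binomial draws around depth-scaled expectations.
#'
#' @param n_coding Number of activated protein-coding genes.
#' @param n_lnc_per_coding lncRNAs placed near each activated coding gene
#'   (0 allowed).
#' @param n_background Non-activated (flat) genes, providing true negatives
#'   for the activation screen. Only background genes may be intronless.
#' @param coding_length_mean_kb,lnc_length_mean_kb Mean gene lengths in kb
#'   (defaults 51.8 and 16.6).
#' @param coding_length_sdlog,lnc_length_sdlog Log-scale sd of the log-normal
#'   length distributions; the defaults give simulated coding gene lengths
#'   ranging from under 1 kb to over 1 Mb at a few thousand genes.
#' @param elongation_rate_kb_per_min Pol II elongation rate (default 2.5).
#' @param time_start,time_stop,time_step Measurement grid in minutes
#'   (defaults 0, 400, 10; `time_step` must divide the span).
#' @param lnc_lag_min Activation offset of each lncRNA relative to its paired
#'   coding gene, in minutes (default 0 = synchronous). Must be a multiple of
#'   the 1-minute internal grid.
#' @param onset_range_min Length-2 range (minutes) of activation onset times
#'   (default 40-250). Narrow early ranges emulate immediate-early response
#'   cohorts whose peaks fall well inside the measurement window.
#' @param halflife_range_min Length-2 range (minutes) for log-uniform mRNA
#'   half-life draws (default 15-480).
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson noise.
#' @param depth_factors Optional per-time-point library scale factors; drawn
#'   log-normal(0, 0.1) when `NULL`.
#' @param max_pair_distance_bp Maximum lncRNA-to-coding TSS distance (bp).
#' @param n_chrom Number of synthetic chromosomes (>= 2).
#' @param window_kb Intron window size used for the simulated region signals.
#' @param spatial_autocorrelation If `TRUE` (default), activation onset times
#'   vary smoothly along each chromosome, giving within-class spatial
#'   autocorrelation of profiles.
#' @param pair_coupling If `TRUE` (default), each lncRNA shares its partner's
#'   activation profile (scaled, shifted by `lnc_lag_min`); `FALSE` draws
#'   lncRNA dynamics independently of position and partner (null fixture).
#' @param count_scale Global scale applied to expected counts.
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_coding = 200,
                       n_lnc_per_coding = 1,
                       n_background = 100,
                       coding_length_mean_kb = 51.8,
                       lnc_length_mean_kb = 16.6,
                       coding_length_sdlog = 1.0,
                       lnc_length_sdlog = 0.8,
                       elongation_rate_kb_per_min = 2.5,
                       time_start = 0, time_stop = 400, time_step = 10,
                       lnc_lag_min = 0,
                       onset_range_min = c(40, 250),
                       halflife_range_min = c(15, 480),
                       nb_dispersion = 0.05,
                       depth_factors = NULL,
                       max_pair_distance_bp = 5e5,
                       n_chrom = 2,
                       window_kb = 10,
                       spatial_autocorrelation = TRUE,
                       pair_coupling = TRUE,
                       count_scale = 1,
                       seed = 1) {
  cfg <- as.list(environment())
  if (n_coding < 1 || n_lnc_per_coding < 0 || n_background < 0)
    stop2("bad_config", "gene counts must be non-negative (n_coding >= 1)")
  if (coding_length_mean_kb <= 0 || lnc_length_mean_kb <= 0 ||
      elongation_rate_kb_per_min <= 0 || window_kb <= 0)
    stop2("bad_config", "lengths and rates must be positive")
  if (time_stop <= time_start || time_step <= 0)
    stop2("bad_config", "need time_stop > time_start and time_step > 0")
  if ((time_stop - time_start) %% time_step != 0)
    stop2("bad_config", "time_step must divide time_stop - time_start")
  if (length(onset_range_min) != 2L || diff(onset_range_min) < 0)
    stop2("bad_config", "onset_range_min must be an increasing pair")
  if (length(halflife_range_min) != 2L || any(halflife_range_min <= 0) ||
      diff(halflife_range_min) < 0)
    stop2("bad_config", "halflife_range_min must be an increasing positive pair")
  if (nb_dispersion < 0) stop2("bad_config", "nb_dispersion must be >= 0")
  if (max_pair_distance_bp <= 0)
    stop2("bad_config", "max_pair_distance_bp must be positive")
  if (n_chrom < 2) stop2("bad_config", "need at least 2 chromosomes")
  if (!is.null(depth_factors) &&
      (length(depth_factors) != length(sim_times(cfg)) ||
       any(depth_factors <= 0)))
    stop2("bad_config", "depth_factors must be positive, one per time point")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' Measurement time grid of a configuration
#' @param config A [sim_config].
#' @return Numeric vector of time points in minutes.
#' @export
sim_times <- function(config) {
  seq(config$time_start, config$time_stop, by = config$time_step)
}

# split `total` into k parts, each >= min_each (deterministic given RNG state)
rand_partition <- function(total, k, min_each) {
  if (total < k * min_each)
    stop2("bad_config", "cannot partition %g into %d parts of >= %g",
          total, k, min_each)
  w <- stats::runif(k)
  extra <- floor(w / sum(w) * (total - k * min_each))
  lens <- min_each + extra
  lens[1L] <- lens[1L] + (total - sum(lens))
  lens
}

# exon/intron layout for one gene, as offsets from gene start
.make_structure <- function(len, intronless = FALSE) {
  if (intronless)
    return(matrix(c(0, len), ncol = 2L))
  n_exon <- if (len >= 5000) sample(2:10, 1L) else sample(2:3, 1L)
  exon_total <- max(n_exon * 40, round(len * stats::runif(1L, 0.08, 0.18)))
  # keep the intron fraction high; shrink the exon budget if the gene is small
  while (len - exon_total < (n_exon - 1L) * 100 && n_exon > 2L) {
    n_exon <- n_exon - 1L
    exon_total <- max(n_exon * 40, round(len * 0.1))
  }
  exon_total <- min(exon_total, len - (n_exon - 1L) * 100)
  exon_lens <- rand_partition(exon_total, n_exon, 40)
  intron_lens <- rand_partition(len - exon_total, n_exon - 1L, 100)
  pos <- 0
  exons <- matrix(0, nrow = n_exon, ncol = 2L)
  for (i in seq_len(n_exon)) {
    exons[i, ] <- c(pos, pos + exon_lens[i])
    pos <- pos + exon_lens[i]
    if (i < n_exon) pos <- pos + intron_lens[i]
  }
  exons
}

.draw_length <- function(n, mean_kb, sdlog, min_bp) {
  meanlog <- log(mean_kb * 1000) - sdlog^2 / 2
  pmax(round(stats::rlnorm(n, meanlog, sdlog)), min_bp)
}

# impulse-shaped activation with a mostly transient response
.draw_activation <- function(onset) {
  h0 <- stats::runif(1L, 5, 20)
  amp <- exp(stats::runif(1L, log(50), log(300)))
  list(h0 = h0, h1 = h0 + amp, h2 = h0 + amp * stats::runif(1L, 0, 0.25),
       t1 = onset, t2 = onset + stats::runif(1L, 40, 120),
       lambda1 = exp(stats::runif(1L, log(0.05), log(0.3))),
       lambda2 = exp(stats::runif(1L, log(0.05), log(0.3))))
}

.draw_kinetics <- function(halflife_range) {
  halflife <- exp(stats::runif(1L, log(halflife_range[1L]),
                               log(halflife_range[2L])))
  alpha <- log(2) / halflife
  # steady-state mature:precursor abundance ratio between 2x and 20x
  beta <- alpha * exp(stats::runif(1L, log(2), log(20)))
  list(alpha = alpha, beta = beta, halflife = halflife)
}

#' Generate a synthetic genome and its ground-truth dynamics
#'
#' Places activated coding genes and background genes sequentially along
#' `n_chrom` synthetic chromosomes (lengths log-normal around the configured
#' means), then places `n_lnc_per_coding` lncRNAs near each coding gene with
#' TSS distances uniform in (0, `max_pair_distance_bp`], rejecting
#' overlapping placements with bounded retries. Every placed gene receives
#' ground-truth dynamics: impulse parameters of the TSS pre-mRNA signal,
#' first-order degradation/production rates (alpha, beta) and the derived
#' half-life. Coordinates are 0-based half-open.
#'
#' @param config A [sim_config].
#' @return List with elements `genes` (a `gene_set`: named list of
#'   [gene_model] objects), `truth` (one data frame row per gene: biotype,
#'   activation class, partner pairing, TSS distance, impulse parameters,
#'   alpha/beta/half-life) and `config`.
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, .make_genome_impl(config))
}

.make_genome_impl <- function(config) {
  n_lnc <- config$n_coding * config$n_lnc_per_coding
  chrom_names <- sprintf("chrS%d", seq_len(config$n_chrom))

  # --- anchor genes (coding + background), placed sequentially with gaps ---
  anchor <- data.frame(
    class = c(rep("coding_activated", config$n_coding),
              rep("background", config$n_background)),
    stringsAsFactors = FALSE)
  anchor$biotype <- ifelse(
    anchor$class == "coding_activated", "protein_coding",
    ifelse(stats::runif(nrow(anchor)) < 0.7, "protein_coding", "lncRNA"))
  anchor$intronless <- anchor$class == "background" &
    stats::runif(nrow(anchor)) < 0.15
  anchor$length <- ifelse(
    anchor$biotype == "protein_coding",
    .draw_length(nrow(anchor), config$coding_length_mean_kb,
                 config$coding_length_sdlog, 2000),
    .draw_length(nrow(anchor), config$lnc_length_mean_kb,
                 config$lnc_length_sdlog, 1000))
  ord <- sample.int(nrow(anchor))
  anchor <- anchor[ord, , drop = FALSE]
  anchor$chrom <- chrom_names[rep_len(seq_len(config$n_chrom), nrow(anchor))]
  anchor$strand <- sample(c("+", "-"), nrow(anchor), replace = TRUE)
  anchor$start <- NA_real_
  cursor <- stats::setNames(rep(50000, config$n_chrom), chrom_names)
  for (i in seq_len(nrow(anchor))) {
    ch <- anchor$chrom[i]
    anchor$start[i] <- cursor[ch]
    gap <- round(stats::runif(1L, 1.2, 2) * config$max_pair_distance_bp) + 20000
    cursor[ch] <- cursor[ch] + anchor$length[i] + gap
  }
  anchor$end <- anchor$start + anchor$length
  anchor$gene_id <- sprintf("G%04d", seq_len(nrow(anchor)))

  placed <- lapply(stats::setNames(nm = chrom_names), function(ch) {
    sel <- anchor$chrom == ch
    IRanges::IRanges(start = anchor$start[sel] + 1, end = anchor$end[sel])
  })

  # --- lncRNAs near each activated coding gene ---
  lnc_rows <- list()
  coding_idx <- which(anchor$class == "coding_activated")
  if (n_lnc > 0) {
    lnc_lengths <- .draw_length(n_lnc, config$lnc_length_mean_kb,
                                config$lnc_length_sdlog, 1000)
    li <- 0L
    for (ci in coding_idx) {
      ctss <- if (anchor$strand[ci] == "+") anchor$start[ci] else anchor$end[ci] - 1
      ch <- anchor$chrom[ci]
      for (j in seq_len(config$n_lnc_per_coding)) {
        li <- li + 1L
        len <- lnc_lengths[li]
        ok <- FALSE
        for (try in 1:50) {
          d <- round(stats::runif(1L, 1, config$max_pair_distance_bp))
          side <- sample(c(-1, 1), 1L)
          strand <- sample(c("+", "-"), 1L)
          tss <- ctss + side * d
          start <- if (strand == "+") tss else tss + 1 - len
          end <- start + len
          if (start < 1000) next
          if (any(IRanges::overlapsAny(IRanges::IRanges(start + 1, end),
                                       placed[[ch]]))) next
          placed[[ch]] <- c(placed[[ch]], IRanges::IRanges(start + 1, end))
          lnc_rows[[length(lnc_rows) + 1L]] <- data.frame(
            class = "lnc_activated", biotype = "lncRNA", intronless = FALSE,
            length = len, chrom = ch, strand = strand,
            start = start, end = end,
            gene_id = sprintf("L%04d", li),
            partner_id = anchor$gene_id[ci], tss_distance = d,
            stringsAsFactors = FALSE)
          ok <- TRUE
          break
        }
        if (!ok)
          stop2("placement_infeasible",
                "could not place lncRNA near %s without overlap",
                anchor$gene_id[ci])
      }
    }
  }
  anchor$partner_id <- NA_character_
  anchor$tss_distance <- NA_real_
  all_rows <- rbind(anchor[, c("class", "biotype", "intronless", "length",
                               "chrom", "strand", "start", "end", "gene_id",
                               "partner_id", "tss_distance")],
                    do.call(rbind, lnc_rows))

  # --- gene models ---
  models <- vector("list", nrow(all_rows))
  for (i in seq_len(nrow(all_rows))) {
    ex <- .make_structure(all_rows$length[i], all_rows$intronless[i])
    models[[i]] <- gene_model(
      gene_id = all_rows$gene_id[i], chrom = all_rows$chrom[i],
      strand = all_rows$strand[i], start = all_rows$start[i],
      end = all_rows$end[i], biotype = all_rows$biotype[i],
      exons = all_rows$start[i] + ex)
  }
  names(models) <- all_rows$gene_id
  genes <- structure(models, class = "gene_set")

  # --- ground-truth dynamics ---
  phases <- stats::runif(config$n_chrom, 0, 2 * pi)
  names(phases) <- chrom_names
  truth <- vector("list", nrow(all_rows))
  tss_of <- vapply(models, function(g) g$tss, numeric(1))
  act_of <- list()
  for (i in seq_len(nrow(all_rows))) {
    row <- all_rows[i, ]
    tss <- tss_of[[row$gene_id]]
    if (row$class == "coding_activated") {
      on_lo <- config$onset_range_min[1L]
      on_hi <- config$onset_range_min[2L]
      onset <- if (config$spatial_autocorrelation) {
        mid <- (on_lo + on_hi) / 2
        amp <- (on_hi - on_lo) / 3
        min(max(mid + amp * sin(2 * pi * tss / 3e6 + phases[[row$chrom]]) +
                  stats::rnorm(1L, 0, 15), on_lo), on_hi)
      } else {
        stats::runif(1L, on_lo, on_hi)
      }
      act <- .draw_activation(onset)
      kin <- .draw_kinetics(config$halflife_range_min)
      act_of[[row$gene_id]] <- act
    } else if (row$class == "lnc_activated") {
      if (config$pair_coupling) {
        pact <- act_of[[row$partner_id]]
        s <- exp(stats::runif(1L, log(0.3), log(1)))
        act <- list(h0 = pact$h0 * s, h1 = pact$h1 * s, h2 = pact$h2 * s,
                    t1 = pact$t1 + config$lnc_lag_min,
                    t2 = pact$t2 + config$lnc_lag_min,
                    lambda1 = pact$lambda1, lambda2 = pact$lambda2)
      } else {
        act <- .draw_activation(stats::runif(1L, 60, 240))
      }
      # lncRNAs are rapidly turned over
      kin <- .draw_kinetics(c(5, 60))
    } else {
      level <- stats::runif(1L, 5, 50)
      act <- list(h0 = level, h1 = level, h2 = level, t1 = 100, t2 = 300,
                  lambda1 = 0.1, lambda2 = 0.1)
      kin <- .draw_kinetics(config$halflife_range_min)
    }
    truth[[i]] <- data.frame(
      gene_id = row$gene_id, biotype = row$biotype, class = row$class,
      activated = row$class != "background",
      partner_id = row$partner_id, tss_distance = row$tss_distance,
      h0 = act$h0, h1 = act$h1, h2 = act$h2, t1 = act$t1, t2 = act$t2,
      lambda1 = act$lambda1, lambda2 = act$lambda2, onset = act$t1,
      alpha = kin$alpha, beta = kin$beta, halflife = kin$halflife,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(genes = genes, truth = truth, config = config)
}

#' @export
print.gene_set <- function(x, ...) {
  bt <- table(vapply(x, function(g) g$biotype, character(1)))
  cat(sprintf("gene_set with %d genes (%s)\n", length(x),
              paste(sprintf("%s: %d", names(bt), bt), collapse = ", ")))
  invisible(x)
}

#' Summarize a gene set as a data frame
#'
#' @param genes A `gene_set` from [make_genome()].
#' @return Data frame with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `tss`, `biotype`, `length`, `intron_total`.
#' @export
gene_table <- function(genes) {
  do.call(rbind, lapply(genes, function(g) data.frame(
    gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
    start = g$start, end = g$end, tss = g$tss, biotype = g$biotype,
    length = gene_length(g), intron_total = intron_total(g),
    stringsAsFactors = FALSE, row.names = NULL)))
}

# representative genomic offsets (bp from TSS, transcribed direction) for a
# set of intervals, sampled every `by` bp at chunk midpoints
.interval_offsets <- function(intervals, tss, strand, by = 500) {
  unlist(lapply(seq_len(nrow(intervals)), function(i) {
    s <- intervals[i, 1L]; e <- intervals[i, 2L]
    pts <- if (e - s <= by) (s + e) / 2 else seq(s + by / 2, e, by = by)
    if (strand == "+") pts - tss else tss - pts
  }))
}

# mean of the TSS impulse shifted by each offset's elongation delay
.delayed_signal <- function(pars, tf, offsets_bp, rate_kb_min) {
  delays <- offsets_bp / 1000 / rate_kb_min
  acc <- numeric(length(tf))
  for (d in delays) acc <- acc + impulse_eval(pars, tf - d)
  acc / length(delays)
}

# exact one-interval update of dM/dt = beta*P - alpha*M for linear P
.ode_step <- function(M, P0, P1, h, alpha, beta) {
  E <- exp(-alpha * h)
  s <- (P1 - P0) / h
  M * E + beta * (P0 * (1 - E) / alpha + s * (h / alpha - (1 - E) / alpha^2))
}

#' Noise-free expectation surface of the simulator
#'
#' Computes, for every gene with introns, the expected (noise-free,
#' depth-free) signal of the three region classes on the measurement grid:
#' the TSS impulse delayed by elongation and averaged over the first and last
#' `window_kb` of concatenated intron (`intron5p`, `intron3p`), and the
#' mature-mRNA solution of dM/dt = beta*P - alpha*M driven by the
#' full-gene-body pre-mRNA (`exon`). Expectations are scaled by region length
#' (per 10 kb). Intronless genes contribute only an `exon` row.
#'
#' @param genes,truth,config Output of [make_genome()].
#' @return Wide data frame (`gene_id`, `region`, one column per time point).
#' @export
expectation_surface <- function(genes, truth, config) {
  times <- sim_times(config)
  tf <- seq(config$time_start, config$time_stop, by = 1)
  idx <- match(times, tf)
  rate <- config$elongation_rate_kb_per_min
  rows <- list()
  for (g in genes) {
    tr <- truth[truth$gene_id == g$gene_id, ]
    pars <- impulse_params(tr$h0, tr$h1, tr$h2, tr$t1, tr$t2,
                           tr$lambda1, tr$lambda2)
    has_introns <- nrow(g$introns) > 0L
    if (has_introns) {
      for (end in c("five_prime", "three_prime")) {
        win <- region_windows(g, config$window_kb, end)
        off <- .interval_offsets(win, g$tss, g$strand)
        sig <- .delayed_signal(pars, tf, off, rate)
        wl <- sum(win[, 2L] - win[, 1L])
        region <- if (end == "five_prime") "intron5p" else "intron3p"
        rows[[length(rows) + 1L]] <- c(
          list(gene_id = g$gene_id, region = region),
          as.list(sig[idx] * wl / 1e4 * config$count_scale))
      }
    }
    # mature mRNA driven by pre-mRNA averaged across the whole gene body
    body_off <- (seq(0.5, 24.5) / 25) * gene_length(g)
    P <- .delayed_signal(pars, tf, body_off, rate)
    M <- numeric(length(tf))
    M[1L] <- tr$beta * P[1L] / tr$alpha
    for (i in seq_len(length(tf) - 1L)) {
      M[i + 1L] <- .ode_step(M[i], P[i], P[i + 1L], tf[i + 1L] - tf[i],
                             tr$alpha, tr$beta)
    }
    exon_len <- sum(g$exons[, 2L] - g$exons[, 1L])
    rows[[length(rows) + 1L]] <- c(
      list(gene_id = g$gene_id, region = "exon"),
      as.list(M[idx] * exon_len / 1e4 * config$count_scale))
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    df <- as.data.frame(r, check.names = FALSE, stringsAsFactors = FALSE)
    names(df) <- c("gene_id", "region", as.character(times))
    df
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a count table from a synthetic genome
#'
#' Draws negative-binomial counts around the depth-scaled expectation
#' surface. Depth factors are taken from the configuration or drawn
#' log-normal(0, 0.1). The RNG stream is derived from `config$seed`, so
#' identical inputs give bit-identical counts.
#'
#' @param genes,truth,config Output of [make_genome()].
#' @return Wide count data frame (`gene_id`, `region`, one integer column per
#'   time point) with attributes `"expectations"` (the noise-free surface)
#'   and `"depth_factors"`.
#' @export
simulate_counts <- function(genes, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$lnc_lag_min %% 1 != 0)
    stop2("bad_lag",
          "lnc_lag_min must be a multiple of the 1-minute internal grid")
  expect <- expectation_surface(genes, truth, config)
  withr::with_seed(config$seed + 1L, {
    times <- sim_times(config)
    # always consume the depth draws so the downstream count stream is the
    # same whether depth factors are drawn or supplied (manifest replay)
    drawn <- stats::rlnorm(length(times), 0, 0.1)
    depth <- if (is.null(config$depth_factors)) drawn else config$depth_factors
    m <- profile_matrix(expect)
    mu <- sweep(m, 2L, depth, "*")
    counts <- if (config$nb_dispersion > 0) {
      matrix(stats::rnbinom(length(mu), mu = mu,
                            size = 1 / config$nb_dispersion),
             nrow = nrow(mu))
    } else {
      matrix(stats::rpois(length(mu), lambda = mu), nrow = nrow(mu))
    }
    out <- expect
    out[, as.character(times)] <- counts
    attr(out, "expectations") <- expect
    attr(out, "depth_factors") <- depth
    out
  })
}
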