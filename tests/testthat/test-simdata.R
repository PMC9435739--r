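test_that("identical config and seed reproduce the genome and counts exactly", {
  cfg <- sim_config(n_coding = 10, n_lnc_per_coding = 2, n_background = 5,
                    seed = 1)
  a <- make_genome(cfg)
  b <- make_genome(cfg)
  expect_identical(gene_table(a$genes), gene_table(b$genes))
  expect_identical(a$truth, b$truth)
  expect_identical(profile_matrix(simulate_counts(a$genes, a$truth, cfg)),
                   profile_matrix(simulate_counts(b$genes, b$truth, cfg)))
  # byte-identical GTF on replay
  f1 <- tempfile(fileext = ".gtf"); f2 <- tempfile(fileext = ".gtf")
  write_gtf(a$genes, f1); write_gtf(b$genes, f2)
  expect_identical(readLines(f1)[-(1:3)], readLines(f2)[-(1:3)])
  expect_equal(length(a$genes), 10 + 20 + 5)
})

test_that("the default time grid has 41 points at 10-minute spacing", {
  cfg <- sim_config(seed = 1)
  expect_equal(sim_times(cfg), seq(0, 400, by = 10))
  expect_length(sim_times(cfg), 41L)
  expect_length(profile_times(fx_small()$counts), 41L)
})

test_that("n_lnc_per_coding = 0 yields a genome without activated lncRNAs", {
  cfg <- sim_config(n_coding = 5, n_lnc_per_coding = 0, n_background = 0,
                    seed = 2)
  g <- make_genome(cfg)
  expect_false(any(gene_table(g$genes)$biotype == "lncRNA"))
})

test_that("simulated coding gene lengths match the configured 51.8 kb mean", {
  cfg <- sim_config(n_coding = 2000, n_lnc_per_coding = 0, n_background = 0,
                    seed = 3)
  tb <- gene_table(make_genome(cfg)$genes)
  expect_lt(abs(mean(tb$length) / 1000 - 51.8) / 51.8, 0.05)
  # heavy-tailed span: shortest under ~2 kb, longest beyond half a megabase
  expect_lt(min(tb$length), 5000)
  expect_gt(max(tb$length), 5e5)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_coding = 0), class = "introntime_bad_config")
  expect_error(sim_config(time_step = 7), class = "introntime_bad_config")
  expect_error(sim_config(time_stop = -10), class = "introntime_bad_config")
  expect_error(sim_config(halflife_range_min = c(10, 5)),
               class = "introntime_bad_config")
  cfg <- sim_config(lnc_lag_min = 2.5, seed = 1)
  g <- make_genome(cfg)
  expect_error(simulate_counts(g$genes, g$truth, cfg),
               class = "introntime_bad_lag")
})

test_that("the 5'-to-3' window peak delay tracks gene span over the elongation rate", {
  cfg <- sim_config(n_coding = 6, n_lnc_per_coding = 0, n_background = 0,
                    coding_length_mean_kb = 150, coding_length_sdlog = 0.3,
                    onset_range_min = c(40, 100), seed = 4)
  g <- make_genome(cfg)
  ex <- expectation_surface(g$genes, g$truth, cfg)
  times <- profile_times(ex)
  p5 <- ex[ex$region == "intron5p", ]
  p3 <- ex[ex$region == "intron3p", ]
  for (id in p5$gene_id) {
    gene <- g$genes[[id]]
    w5 <- region_windows(gene, 10, "five_prime")
    w3 <- region_windows(gene, 10, "three_prime")
    off5 <- mean(introntime:::.interval_offsets(w5, gene$tss, gene$strand))
    off3 <- mean(introntime:::.interval_offsets(w3, gene$tss, gene$strand))
    expected_delay <- (off3 - off5) / 1000 / cfg$elongation_rate_kb_per_min
    t5 <- peak_time(fit_impulse(as.numeric(p5[p5$gene_id == id, -(1:2)]), times))
    t3 <- peak_time(fit_impulse(as.numeric(p3[p3$gene_id == id, -(1:2)]), times))
    if (is.na(t5) || is.na(t3)) next
    expect_lt(abs((t3 - t5) - expected_delay), max(4, 0.15 * expected_delay))
  }
})

test_that("fast-decaying mRNA recapitulates the pre-mRNA shape", {
  # closed-form ODE limit: as alpha -> large, M(t) -> (beta/alpha) P(t)
  times <- seq(0, 400, by = 10)
  p <- impulse_params(2, 100, 10, 80, 180, 0.15, 0.1)
  P <- impulse_eval(p, times)
  M <- integrate_model(P, times, alpha = 2, beta = 1, M0 = P[1] / 2)
  expect_gt(stats::cor(zscore(M), zscore(P)), 0.99)
})

test_that("count column sums scale with the configured depth factors", {
  cfg <- sim_config(n_coding = 300, n_lnc_per_coding = 1, n_background = 200,
                    depth_factors = rep(c(0.8, 1.25), length.out = 41),
                    seed = 5)
  g <- make_genome(cfg)
  counts <- simulate_counts(g$genes, g$truth, cfg)
  expect_identical(attr(counts, "depth_factors"), cfg$depth_factors)
  m <- profile_matrix(counts)
  e <- profile_matrix(attr(counts, "expectations"))
  mu <- sweep(e, 2, cfg$depth_factors, "*")
  ratio <- colSums(m) / colSums(mu)
  # negative-binomial bound on the column-sum fluctuation: a handful of
  # high-expression genes dominate, so the tolerance follows the theory
  # rather than a blanket percentage
  sd_rel <- sqrt(colSums(mu + cfg$nb_dispersion * mu^2)) / colSums(mu)
  expect_true(all(abs(ratio - 1) < pmax(5 * sd_rel, 0.02)))
  expect_lt(median(abs(ratio - 1)), 0.02)
})

test_that("paired lncRNA pre-mRNA mirrors its partner, shifted by the configured lag", {
  for (lag in c(0, 30)) {
    cfg <- sim_config(n_coding = 8, n_lnc_per_coding = 1, n_background = 0,
                      lnc_lag_min = lag, seed = 6)
    g <- make_genome(cfg)
    ex <- expectation_surface(g$genes, g$truth, cfg)
    z <- introntime:::zscore_rows(introntime:::region_matrix(ex, "intron5p"))
    lnc <- g$truth[g$truth$class == "lnc_activated", ]
    steps <- lag / cfg$time_step
    n <- ncol(z)
    for (i in seq_len(nrow(lnc))) {
      a <- z[lnc$partner_id[i], seq_len(n - steps)]
      b <- z[lnc$gene_id[i], seq.int(1 + steps, n)]
      # amplitude scaling drops out of z-scores; elongation-delay mixing
      # differs slightly between the two gene bodies, hence not exactly 1
      expect_gt(stats::cor(a, b), 0.99)
    }
  }
})

test_that("fixtures round-trip through GTF/BED/TSV and refuse silent overwrite", {
  fx <- fx_small()
  d <- withr::local_tempdir()
  write_fixture(fx$genes, fx$counts, fx$truth, fx$cfg, d)
  expect_error(write_fixture(fx$genes, fx$counts, fx$truth, fx$cfg, d),
               class = "introntime_fixture_exists")
  back <- read_fixture(d)
  id <- names(fx$genes)[1]
  expect_equal(back$genes[[id]]$exons, fx$genes[[id]]$exons,
               ignore_attr = TRUE)
  tb_back <- gene_table(back$genes)
  tb_orig <- gene_table(fx$genes)
  tb_back <- tb_back[order(tb_back$gene_id), ]
  tb_orig <- tb_orig[order(tb_orig$gene_id), ]
  rownames(tb_back) <- rownames(tb_orig) <- NULL
  expect_equal(tb_back, tb_orig)
  expect_equal(profile_matrix(back$counts), profile_matrix(fx$counts))
  # GTF is 1-based inclusive, BED 0-based half-open: starts differ by 1
  gtf1 <- read.delim(file.path(d, "genes.gtf"), header = FALSE, skip = 3,
                     quote = "")
  bed1 <- read.delim(file.path(d, "genes.bed"), header = FALSE)
  gene_rows <- gtf1[gtf1$V3 == "gene", ]
  gtf_starts <- gene_rows$V4[match(bed1$V4, sub('.*gene_id "([^"]+)".*', "\\1",
                                                gene_rows$V9))]
  expect_equal(gtf_starts, bed1$V2 + 1)
  # manifest replay reproduces the counts exactly
  g2 <- make_genome(back$config)
  c2 <- simulate_counts(g2$genes, g2$truth, back$config)
  expect_equal(profile_matrix(c2), profile_matrix(fx$counts))
})
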