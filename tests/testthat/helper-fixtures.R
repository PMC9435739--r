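# Shared fixtures, built once per test run and memoized.

.fx_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fx_cache)) assign(key, builder(), envir = .fx_cache)
  get(key, envir = .fx_cache)
}

# small mixed fixture: activated coding genes with paired lncRNAs plus flat
# background, moderate noise
fx_small <- function() memo("small", function() {
  cfg <- sim_config(n_coding = 40, n_lnc_per_coding = 1, n_background = 60,
                    seed = 11)
  g <- make_genome(cfg)
  counts <- simulate_counts(g$genes, g$truth, cfg)
  list(cfg = cfg, genes = g$genes, truth = g$truth, counts = counts,
       norm = normalize_counts(counts))
})

# null fixture: placement as usual but dynamics independent of position
fx_null <- function() memo("null", function() {
  cfg <- sim_config(n_coding = 60, n_lnc_per_coding = 1, n_background = 80,
                    spatial_autocorrelation = FALSE, pair_coupling = FALSE,
                    seed = 12)
  g <- make_genome(cfg)
  counts <- simulate_counts(g$genes, g$truth, cfg)
  list(cfg = cfg, genes = g$genes, truth = g$truth, counts = counts,
       norm = normalize_counts(counts))
})

# hand-built two-intron gene used throughout the quantification tests:
# exons [0,1000) [6000,8000) [20000,21000), introns [1000,6000) [8000,20000)
toy_gene <- function(strand = "+") {
  gene_model("toy", "chrT", strand, 0, 21000, "protein_coding",
             exons = cbind(c(0, 6000, 20000), c(1000, 8000, 21000)))
}

# impulse parameter draw for profile-level simulations
rand_impulse <- function() {
  h0 <- stats::runif(1, 5, 20)
  amp <- exp(stats::runif(1, log(50), log(300)))
  t1 <- stats::runif(1, 60, 240)
  impulse_params(h0, h0 + amp, h0 + amp * stats::runif(1, 0, 0.25),
                 t1, t1 + stats::runif(1, 40, 120),
                 exp(stats::runif(1, log(0.05), log(0.3))),
                 exp(stats::runif(1, log(0.05), log(0.3))))
}
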