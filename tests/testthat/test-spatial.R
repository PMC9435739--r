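# three-gene toy: one lncRNA equidistant from two coding genes
.toy_tbl <- function() {
  data.frame(gene_id = c("c1", "c2", "l1"),
             chrom = "chrT", tss = c(100, 50100, 25100),
             biotype = c("protein_coding", "protein_coding", "lncRNA"),
             stringsAsFactors = FALSE)
}

.toy_profiles <- function(seed = 24) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(3 * 41), 3)
  })
  df <- data.frame(gene_id = c("c1", "c2", "l1"), region = "intron5p", m,
                   check.names = FALSE)
  names(df)[-(1:2)] <- as.character(seq(0, 400, 10))
  df
}

test_that("pair enumeration is many-to-many with strand-agnostic TSS distances", {
  pr <- make_pairs(.toy_tbl(), .toy_profiles(), max_distance_bp = 5e5)
  expect_equal(nrow(pr), 2L)  # the lncRNA pairs with both coding genes
  expect_setequal(pr$tss_distance, 25000)
  # distance arithmetic: TSS at 100 and 50100 -> 50 kb; identical TSS -> 0
  tbl <- .toy_tbl(); tbl$tss[3] <- 100
  pr2 <- make_pairs(tbl, .toy_profiles(), max_distance_bp = 5e5)
  expect_setequal(pr2$tss_distance, c(0, 50000))
  # max_distance filters
  pr3 <- make_pairs(.toy_tbl(), .toy_profiles(), max_distance_bp = 10000)
  expect_equal(nrow(pr3), 0L)
  # pair correlations equal cor() of the profiles
  m <- profile_matrix(.toy_profiles())
  rownames(m) <- c("c1", "c2", "l1")
  expect_equal(pr$pearson_r[pr$coding_id == "c1"],
               unname(stats::cor(m["c1", ], m["l1", ])), tolerance = 1e-12)
})

test_that("pairs are invariant to coordinate translation and chromosome relabeling", {
  fx <- fx_null()
  tbl <- gene_table(fx$genes)
  pr <- make_pairs(tbl, fx$norm)
  tbl2 <- tbl
  tbl2$tss <- tbl2$tss + 12345
  tbl2$chrom <- paste0("x", tbl2$chrom)
  pr2 <- make_pairs(tbl2, fx$norm)
  expect_equal(pr$tss_distance, pr2$tss_distance)
  expect_equal(pr$pearson_r, pr2$pearson_r)
})

test_that("the GAM trend recovers constant and linear truths", {
  withr::with_seed(25, {
    d <- runif(400, 0, 5e5)
    const <- data.frame(coding_id = "c", lnc_id = "l", tss_distance = d,
                        pearson_r = 0.3)
    tr <- gam_trend(const)
    grid <- seq(min(d), max(d), length.out = 50)
    expect_true(all(abs(tr$predict(grid) - 0.3) < 0.01))
    expect_lt(tr$edf, 1.5)
    lin <- const
    lin$pearson_r <- 0.8 - d / 1e6  # exactly linear in distance
    tr2 <- gam_trend(lin)
    interior <- grid[grid > quantile(d, 0.05) & grid < quantile(d, 0.95)]
    expect_true(all(abs(tr2$predict(interior) - (0.8 - interior / 1e6)) < 0.01))
  })
  expect_error(gam_trend(const[1:10, ]), class = "introntime_too_few_pairs")
})

test_that("the synchronous fixture shows correlation decaying with distance", {
  fx <- fx_small()
  pr <- make_pairs(fx$genes, fx$norm)
  tr <- gam_trend(pr, min_pairs = 30)
  grid <- seq(min(pr$tss_distance), max(pr$tss_distance), length.out = 50)
  expect_lt(stats::cor(tr$predict(grid), grid, method = "spearman"), 0)
})

test_that("block-size selection requires enough permutations and flags null data", {
  fx <- fx_null()
  pr <- make_pairs(fx$genes, fx$norm)
  expect_error(choose_block_size(pr, n_perm = 10),
               class = "introntime_bad_nperm")
  bs <- choose_block_size(pr, n_perm = 150, seed = 2)
  if (bs$flagged) expect_equal(bs$block_size, 5e5)
  # synchronous fixture: dependence extends at most to the pairing radius
  prs <- make_pairs(fx_small()$genes, fx_small()$norm)
  bss <- choose_block_size(prs, n_perm = 150, seed = 2)
  expect_false(bss$flagged)
  expect_lte(bss$block_size, 2 * 5e5)
})

test_that("pairs wholly inside one block keep their distance in every pseudochromosome", {
  fx <- fx_null()
  tbl <- gene_table(fx$genes)
  B <- 1e6
  withr::with_seed(26, {
    for (i in 1:5) {
      ps <- introntime:::.pseudochromosome(tbl, B)
      # genes that shared a block originally
      ps$block <- floor(ps$tss / B)  # block in the pseudochromosome
      orig_block <- floor(tbl$tss[match(ps$gene_id, tbl$gene_id)] / B)
      for (ch in unique(ps$chrom)) {
        sub <- ps[ps$chrom == ch, ]
        ob <- orig_block[ps$chrom == ch]
        for (b in unique(sub$block)) {
          sel <- sub$block == b
          if (sum(sel) < 2) next
          # all genes in one pseudo-block came from one original block and
          # keep their relative offsets exactly
          expect_equal(length(unique(ob[sel])), 1L)
          d_new <- diff(sort(sub$tss[sel]))
          d_old <- diff(sort(tbl$tss[match(sub$gene_id[sel], tbl$gene_id)]))
          expect_equal(d_new, d_old)
        }
      }
    }
  })
})

test_that("bootstrap envelopes are deterministic given the seed", {
  fx <- fx_null()
  e1 <- block_bootstrap_envelope(fx$genes, fx$norm, 5e5, n_boot = 40, seed = 9)
  e2 <- block_bootstrap_envelope(fx$genes, fx$norm, 5e5, n_boot = 40, seed = 9)
  expect_identical(e1, e2)
  expect_true(all(e1$lo <= e1$hi))
})

test_that("envelope bounds stabilize in n_boot without moving location", {
  fx <- fx_null()
  e_small <- block_bootstrap_envelope(fx$genes, fx$norm, 5e5, n_boot = 200,
                                      seed = 9)
  e_big <- block_bootstrap_envelope(fx$genes, fx$norm, 5e5, n_boot = 1000,
                                    seed = 9)
  # the 1st/99th percentile estimates wander pointwise at a few hundred
  # iterations but the band does not shift: its center stays put and the
  # average bound movement is small relative to the band width
  expect_lt(mean(abs(e_small$lo - e_big$lo)), 0.06)
  expect_lt(mean(abs(e_small$hi - e_big$hi)), 0.05)
  mid_small <- (e_small$lo + e_small$hi) / 2
  mid_big <- (e_big$lo + e_big$hi) / 2
  expect_lt(abs(mean(mid_small - mid_big)), 0.03)
})

test_that("cCRE proximity labels use the 300 bp TSS window", {
  tbl <- .toy_tbl()
  els <- GenomicRanges::GRanges("chrT",
                                IRanges::IRanges(start = c(400, 40000),
                                                 width = 50))
  cls <- classify_ccre_proximity(tbl, els)
  # c1 TSS at 100: element [400,449] is 300 bp away -> associated
  expect_true(cls$ccre_associated[cls$gene_id == "c1"])
  expect_false(cls$ccre_associated[cls$gene_id == "c2"])
  expect_false(cls$ccre_associated[cls$gene_id == "l1"])
})
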