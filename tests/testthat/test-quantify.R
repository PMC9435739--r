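test_that("intron windows follow transcription order on both strands", {
  # introns [1000,6000) and [8000,20000): 5 kb + 12 kb of intron sequence
  plus <- toy_gene("+")
  w <- region_windows(plus, 10, "five_prime")
  expect_equal(unclass(w)[, ], cbind(c(1000, 8000), c(6000, 13000)),
               ignore_attr = TRUE)
  expect_false(attr(w, "short"))
  # minus strand: the 5' end is the high-coordinate end
  minus <- toy_gene("-")
  w2 <- region_windows(minus, 10, "five_prime")
  expect_equal(unclass(w2)[, ], cbind(10000, 20000), ignore_attr = TRUE)
  # 3' window of the plus gene is the mirror of the minus 5' window
  w3 <- region_windows(plus, 10, "three_prime")
  expect_equal(unclass(w3)[, ], cbind(10000, 20000), ignore_attr = TRUE)
})

test_that("short-intron genes return all introns with a shortfall flag", {
  g <- gene_model("short", "chrT", "+", 0, 6000, "protein_coding",
                  exons = cbind(c(0, 5000), c(1000, 6000)))
  w <- region_windows(g, 10, "five_prime")
  expect_true(attr(w, "short"))
  expect_equal(sum(w[, 2] - w[, 1]), 4000)
  exonless <- gene_model("mono", "chrT", "+", 0, 3000, "lncRNA",
                         exons = cbind(0, 3000))
  expect_error(region_windows(exonless, 10), class = "introntime_no_intron")
})

test_that("windows are disjoint, in-bounds, and strand-reflection symmetric", {
  fx <- fx_small()
  for (g in fx$genes[1:25]) {
    if (nrow(g$introns) == 0L) next
    for (end in c("five_prime", "three_prime")) {
      w <- region_windows(g, 10, end)
      expect_true(all(w[, 1] < w[, 2]))
      expect_true(all(w[, 1] >= g$start & w[, 2] <= g$end))
      if (nrow(w) > 1L) expect_true(all(w[-1, 1] >= w[-nrow(w), 2]))
      expect_equal(sum(w[, 2] - w[, 1]), min(1e4, intron_total <- sum(
        g$introns[, 2] - g$introns[, 1])))
    }
    # reflect coordinates and flip strand: windows must swap ends exactly
    span <- g$start + g$end
    refl <- gene_model(g$gene_id, g$chrom,
                       if (g$strand == "+") "-" else "+",
                       g$start, g$end, g$biotype,
                       exons = cbind(span - g$exons[, 2], span - g$exons[, 1]))
    w_fw <- region_windows(g, 10, "five_prime")
    w_rv <- region_windows(refl, 10, "five_prime")
    expect_equal(sort(span - as.vector(w_fw)), sort(as.vector(w_rv)))
  }
})

test_that("intron tiling yields whole 1-kb tiles ordered 5' to 3'", {
  # 25.7 kb of intron: [1000,6000) 5 kb + [8000,28700) 20.7 kb
  g <- gene_model("tiled", "chrT", "+", 0, 30000, "protein_coding",
                  exons = cbind(c(0, 6000, 28700), c(1000, 8000, 30000)))
  tl <- intron_tiles(g)
  expect_equal(max(tl$tile), 25L)
  expect_equal(sum(tl$end - tl$start), 25000)
  gm <- gene_model("tiled", "chrT", "-", 0, 30000, "protein_coding",
                   exons = cbind(c(0, 6000, 28700), c(1000, 8000, 30000)))
  tlm <- intron_tiles(gm)
  expect_equal(max(tlm$tile), 25L)
  # on the minus strand tile 1 sits at the high-coordinate end
  expect_gt(min(tlm$start[tlm$tile == 1]), max(tlm$start[tlm$tile == 25]))
})

test_that("size factors match the median-of-ratios definition", {
  m <- matrix(rep(c(10, 50, 200), 3), ncol = 3)  # identical columns
  expect_equal(unname(size_factors(m)), rep(1, 3))
  m2 <- cbind(a = c(10, 100, 4), b = 2 * c(10, 100, 4))
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)))
  # direct-formula oracle on a random integer matrix
  set.seed(9)
  m3 <- matrix(rpois(250, 40) + 1L, nrow = 50, ncol = 5)
  geo <- exp(rowMeans(log(m3)))
  oracle <- apply(m3 / geo, 2, median)
  expect_equal(unname(size_factors(m3)), unname(oracle), tolerance = 1e-12)
  # scale equivariance: scaling the whole matrix leaves factors unchanged
  expect_equal(size_factors(7 * m3), size_factors(m3), tolerance = 1e-12)
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)),
               class = "introntime_unnormalizable")
})

test_that("z-scoring uses the population standard deviation", {
  expect_equal(zscore(c(0, 10, 20)), c(-1, 0, 1) * sqrt(3 / 2),
               tolerance = 1e-6)
  expect_equal(zscore(c(0, 10, 20)), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  z <- zscore(rnorm(20))
  expect_equal(zscore(z), z, tolerance = 1e-9)  # idempotent
  expect_error(zscore(rep(5, 10)), class = "introntime_degenerate_profile")
})

test_that("degenerate rows are dropped and reported when z-scoring tables", {
  df <- data.frame(gene_id = c("a", "b"), region = "exon",
                   rbind(1:5, rep(3, 5)), check.names = FALSE)
  names(df)[3:7] <- as.character(seq(0, 40, 10))
  z <- zscore_profiles(df)
  expect_equal(nrow(z), 1L)
  expect_equal(attr(z, "degenerate"), "b:exon")
  expect_equal(mean(as.numeric(z[1, -(1:2)])), 0)
  expect_equal(introntime:::sd_pop(as.numeric(z[1, -(1:2)])), 1)
})

test_that("normalization divides each time point by its size factor", {
  fx <- fx_small()
  f <- attr(fx$norm, "size_factors")
  expect_true(all(f > 0))
  m_raw <- profile_matrix(fx$counts)
  m_norm <- profile_matrix(fx$norm)
  expect_equal(m_norm, sweep(m_raw, 2, f, "/"))
})
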