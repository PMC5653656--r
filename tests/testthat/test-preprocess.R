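# Size factors, coverage filters, thinning, aggregation and dispersion.

test_that("median-of-ratios size factors: symmetry and planted ratios", {
  m <- matrix(rpois(300, 50) + 1, ncol = 3)
  same <- cbind(m[, 1], m[, 1], m[, 1])
  sf <- median_ratio_size_factors(same)
  expect_equal(sf$factors[1] / sf$factors[2], 1, tolerance = 1e-12)
  # lib3 exactly twice lib1 = lib2 at every site
  doubled <- cbind(m[, 1], m[, 1], 2 * m[, 1])
  sf2 <- median_ratio_size_factors(doubled)
  expect_equal(unname(sf2$factors[3] / sf2$factors[1]), 2,
               tolerance = 1e-12)
})

test_that("size factors recover planted factors on NB data within 5%", {
  set.seed(41)
  truth <- c(0.5, 1, 2)
  base <- matrix(rnbinom(2000 * 3, size = 10, mu = 100), ncol = 3)
  counts <- sweep(base, 2, truth, `*`)
  sf <- median_ratio_size_factors(counts)
  rel <- sf$factors / exp(mean(log(sf$factors)))
  rel_truth <- truth / exp(mean(log(truth)))
  expect_lt(max(abs(rel / rel_truth - 1)), 0.05)
})

test_that("size factor estimation errors without an all-positive site", {
  m <- matrix(c(0, 5, 5, 0), ncol = 2)
  expect_error(median_ratio_size_factors(m), "positive")
})

test_that("scaling one library scales its factor relative to the others", {
  # size factors are identified up to one global constant: scaling one
  # library by c multiplies its factor by c relative to every other
  # library, and normalized counts change only by a shared global rescale
  cfg <- tiny_config()
  sim <- simulate_dataset(cfg)
  raw <- filter_sites(sim$sites, verbose = FALSE)
  n1 <- normalize_site_table(raw)
  scaled <- raw
  scaled$F0_A_rep1 <- raw$F0_A_rep1 * 3
  n2 <- normalize_site_table(scaled)
  f1 <- n1$size_factors$factors
  f2 <- n2$size_factors$factors
  expect_equal(unname((f2["F0_A_rep1"] / f2["F0_B_rep2"]) /
                        (f1["F0_A_rep1"] / f1["F0_B_rep2"])), 3,
               tolerance = 1e-9)
  g1 <- n1$sites$F0_B_rep2 / n2$sites$F0_B_rep2
  g2 <- n1$sites$F0_A_rep1 / n2$sites$F0_A_rep1
  g3 <- n1$sites$F1_A_rep3 / n2$sites$F1_A_rep3
  expect_lt(max(abs(c(g1, g2, g3) - g1[1]), na.rm = TRUE), 1e-9)
})

test_that("coverage filters keep and drop per the replicate rules", {
  nine_ok <- make_site(c(12, 0, 0), rep(0, 3),
                       c(rep(10, 9), rep(3, 3)), rep(0, 12),
                       site_id = "nine")
  twelve_ok <- make_site(c(12, 0, 0), rep(0, 3), rep(10, 12), rep(2, 12),
                         site_id = "twelve", pos = 2000L)
  out <- filter_sites(rbind(nine_ok, twelve_ok), verbose = FALSE)
  expect_equal(out$site_id, "twelve")  # 9 qualifying F1 reps -> dropped
  empty <- filter_sites(out[0, ], verbose = FALSE)
  expect_equal(nrow(empty), 0)
})

test_that("thinning keeps the documented sites and is idempotent", {
  s2 <- make_sites(
    make_site(rep(1, 2), rep(1, 2), rep(1, 2), rep(1, 2), "p100",
              pos = 100L),
    make_site(rep(1, 2), rep(1, 2), rep(1, 2), rep(1, 2), "p300",
              pos = 300L))
  expect_equal(nrow(thin_sites_by_distance(s2, verbose = FALSE)), 1)
  s2$pos <- c(100L, 400L)
  expect_equal(nrow(thin_sites_by_distance(s2, verbose = FALSE)), 2)

  # coverages 5/9/7 at 100/200/600 -> keep {200, 600}
  s3 <- make_sites(
    make_site(5, 0, 0, 0, "a", pos = 100L),
    make_site(9, 0, 0, 0, "b", pos = 200L),
    make_site(7, 0, 0, 0, "c", pos = 600L))
  out <- thin_sites_by_distance(s3, verbose = FALSE)
  expect_equal(out$site_id, c("b", "c"))
  expect_equal(thin_sites_by_distance(out, verbose = FALSE), out)

  # property: random tables are spacing-valid and idempotent
  set.seed(5)
  for (k in 1:5) {
    n <- 60
    tab <- make_site(1, 1, 1, 1, "t", pos = 1L)[rep(1, n), ]
    tab$site_id <- paste0("t", seq_len(n))
    tab$pos <- sort(sample.int(5000, n))
    tab$F0_A_rep1 <- rpois(n, 20)
    th <- thin_sites_by_distance(tab, verbose = FALSE)
    expect_true(all(diff(th$pos) >= 250))
    expect_equal(thin_sites_by_distance(th, verbose = FALSE), th)
  }
})

test_that("histone aggregation sums member SNVs and conserves totals", {
  s <- make_sites(
    make_site(2, 3, 3, 1, "v1", pos = 150L),
    make_site(5, 1, 4, 2, "v2", pos = 180L),
    make_site(9, 9, 9, 9, "v3", pos = 950L),
    make_site(1, 1, 1, 1, "orphan", pos = 5000L))
  peaks <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(101, 901), c(300, 1000)))
  agg <- aggregate_histone_snvs(s, peaks, verbose = FALSE)
  expect_equal(nrow(agg), 2)
  expect_equal(agg$F1_A_rep1[1], 7)   # 3 + 4
  expect_equal(agg$F0_A_rep1[2], 9)   # single-SNV peak unchanged
  expect_equal(agg$members[1], "v1,v2")
  # conservation: totals over aggregated sites = totals over member SNVs
  cc <- hybridreg:::count_columns(s)
  expect_equal(sum(agg[, cc]), sum(s[s$site_id != "orphan", cc]))
})

test_that("dispersion estimation recovers Poisson and NB regimes", {
  set.seed(61)
  n <- 2000
  mk <- function(gen) {
    tab <- make_site(1, 1, 1, 1, "d", pos = 1L)[rep(1, n), ]
    tab$site_id <- paste0("d", seq_len(n))
    tab$pos <- seq_len(n) * 1000L
    for (j in 1:6) {
      tab[[paste0("F0_A_rep", j)]] <- gen(n)
      tab[[paste0("F0_B_rep", j)]] <- gen(n)
    }
    tab
  }
  pois <- mk(function(n) rpois(n, 100))
  dp <- estimate_dispersion(pois)
  expect_lte(median(dp$table$dispersion), 0.01)

  nb <- mk(function(n) rnbinom(n, size = 2, mu = 100))  # dispersion 0.5
  dn <- estimate_dispersion(nb)
  trend_at_100 <- dn$trend[["a0"]] + dn$trend[["a1"]] / 100
  expect_gt(trend_at_100, 0.4)
  expect_lt(trend_at_100, 0.6)

  # constant counts: raw moment estimate <= 0, final at the floor
  const <- mk(function(n) rep(50, n))
  dc <- suppressWarnings(estimate_dispersion(const))
  expect_true(all(dc$table$raw_dispersion == 0))
  expect_true(all(dc$table$dispersion == 1e-4))
})
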