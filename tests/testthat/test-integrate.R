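# Cross-layer integration: windows, regressions, diversity, matching,
# co-location and cis-extent summaries.

test_that("gene windows are strand-aware with inclusive boundaries", {
  genes <- data.frame(gene_id = c("g_plus", "g_minus"), chrom = "chr1",
                      tss = c(100000L, 100000L), strand = c("+", "-"),
                      stringsAsFactors = FALSE)
  sites <- make_site(1, 1, 1, 1, "s", pos = 1L)[rep(1, 4), ]
  sites$site_id <- c("up15k", "up20k1", "down_minus15k", "edge")
  sites$pos <- c(85000L, 79999L, 115000L, 80000L)
  sites$class <- "cis"
  tab <- assign_sites_to_genes(sites, genes)
  pairs <- attr(tab, "assignments")
  plus_sites <- pairs$site_id[pairs$gene_id == "g_plus"]
  expect_true("up15k" %in% plus_sites)        # 15 kb upstream on +
  expect_false("up20k1" %in% plus_sites)      # 20,001 bp upstream
  expect_true("edge" %in% plus_sites)         # exactly 20 kb: inclusive
  minus_sites <- pairs$site_id[pairs$gene_id == "g_minus"]
  expect_true("down_minus15k" %in% minus_sites)  # 15 kb upstream on -
  expect_false("up15k" %in% minus_sites)      # 15 kb downstream limit 10 kb
})

test_that("Shannon diversity matches closed forms and its bounds", {
  expect_equal(shannon_diversity(c(1, 0, 0, 0)), 0)
  expect_equal(shannon_diversity(rep(0.25, 4)), log(4), tolerance = 1e-12)
  expect_equal(shannon_diversity(c(0.5, 0.5, 0, 0)), log(2),
               tolerance = 1e-12)
  expect_error(shannon_diversity(c(-0.1, 1.1)), "non-negative")
  set.seed(4)
  for (k in 1:20) {
    p <- rgamma(4, 1); p <- p / sum(p)
    h <- shannon_diversity(p)
    expect_gte(h, 0); expect_lte(h, log(4) + 1e-12)
  }
})

test_that("region class enrichment reproduces the odds-ratio formula", {
  mk_region_sites <- function(k, n, cls = "cis") {
    s <- make_site(1, 1, 1, 1, "r", pos = 1L)[rep(1, n), ]
    s$site_id <- paste0("r", seq_len(n))
    s$pos <- seq_len(n) * 100L
    s$class <- c(rep(cls, k), rep("other", n - k))
    s
  }
  regions <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1e6))
  props <- c(cis = 0.25, other = 0.75)
  r50 <- region_class_enrichment(mk_region_sites(50, 100), regions, props)
  expect_equal(r50$odds_ratio[r50$class == "cis"], 3, tolerance = 1e-12)
  r25 <- region_class_enrichment(mk_region_sites(25, 100), regions, props)
  expect_equal(r25$odds_ratio[r25$class == "cis"], 1, tolerance = 1e-12)
  expect_gt(r25$p_value[r25$class == "cis"], 0.5)
  r0 <- region_class_enrichment(mk_region_sites(0, 100), regions, props)
  expect_lt(r0$p_value[r0$class == "cis"], 1e-9)
  expect_equal(r0$k_class[r0$class == "cis"], 0)
})

test_that("logistic enrichment finds planted signal and flags degeneracy", {
  set.seed(14)
  n <- 1000
  tab <- data.frame(gene_id = paste0("g", 1:n),
                    n_conserved = rpois(n, 2), n_cis = rpois(n, 2),
                    n_trans = rpois(n, 2), n_cis_trans = rpois(n, 2))
  cls <- sample(REG_CLASSES, n, replace = TRUE)
  # plant: cis genes get extra cis sites
  tab$n_cis <- tab$n_cis + ifelse(cls == "cis", rpois(n, 3), 0)
  tab$n_total <- rowSums(tab[, 2:5])
  tab$response_class <- cls
  res <- logistic_enrichment(tab, "cis")
  cis_row <- res[res$predictor == "n_cis", ]
  expect_gt(cis_row$odds_ratio, 1)
  expect_gt(cis_row$z, 2)
  # constant predictor: flagged non-estimable
  tab$n_trans <- 0L
  res2 <- logistic_enrichment(tab, "cis")
  expect_false(res2$estimable[res2$predictor == "n_trans"])
})

test_that("mark-gene concordance is extreme for copied labels", {
  set.seed(16)
  genes <- data.frame(gene_id = paste0("g", 1:120), chrom = "chr1",
                      tss = (1:120) * 50000L, strand = "+",
                      expr_class = sample(REG_CLASSES, 120, replace = TRUE),
                      stringsAsFactors = FALSE)
  marks <- make_site(1, 1, 1, 1, "m", pos = 1L)[rep(1, 120), ]
  marks$site_id <- paste0("m", 1:120)
  marks$pos <- genes$tss - 1000L
  marks$class <- genes$expr_class  # perfect concordance
  res <- promoter_mark_gene_concordance(marks, genes)
  expect_true(all(res$p_value < 1e-6))
  # diversity: a gene with a single site has H = 0
  tab <- assign_sites_to_genes(marks, genes)
  tab$expr_class <- genes$expr_class
  div <- diversity_by_expression_class(tab)
  expect_true(all(div$per_gene$H[div$per_gene$n_sites == 1] == 0))
})

test_that("expression matching preserves bins and is seed-deterministic", {
  set.seed(18)
  genes <- data.frame(gene_id = paste0("g", 1:300),
                      expr_class = rep(c("cis_trans", "conserved"), 150),
                      expr_f0_a = exp(rnorm(300, 4, 1)),
                      expr_f0_b = exp(rnorm(300, 4, 1)),
                      stringsAsFactors = FALSE)
  m1 <- suppressWarnings(
    expression_matched_subsample(genes, "cis_trans", "conserved", seed = 2))
  m2 <- suppressWarnings(
    expression_matched_subsample(genes, "cis_trans", "conserved", seed = 2))
  expect_identical(m1$target$gene_id, m2$target$gene_id)
  expect_identical(m1$matched_reference$gene_id,
                   m2$matched_reference$gene_id)
  kept <- m1$bins$n_target > 0 | m1$bins$n_reference > 0
  expect_equal(m1$bins$n_target, m1$bins$n_reference)
  expect_equal(nrow(m1$target), nrow(m1$matched_reference))
  expect_true(all(m1$matched_reference$expr_class == "conserved"))
})

test_that("co-location sharing uses the product of per-assay proportions", {
  calls <- function(cls) data.frame(site_id = paste0("s", seq_along(cls)),
                                    class = cls, stringsAsFactors = FALSE)
  # perfect agreement across three assays
  cls <- rep(c("cis", "conserved"), each = 20)
  trio <- list(a = calls(cls), b = calls(cls), c = calls(cls))
  res <- colocation_shared_class_test(trio)
  expect_equal(res$expected_p[res$class == "cis"], 0.5^3)
  expect_lt(res$p_value[res$class == "cis"], 1e-6)
  # independently shuffled labels stay near the expectation
  set.seed(20)
  n <- 600
  base <- sample(REG_CLASSES, n, replace = TRUE)
  shuf <- list(a = calls(sample(base)), b = calls(sample(base)),
               c = calls(sample(base)))
  res2 <- colocation_shared_class_test(shuf)
  for (i in seq_len(nrow(res2))) {
    expect_gt(res2$p_value[i], 0.001)  # no spurious extreme enrichment
  }
})

test_that("cis-extent correlation and magnitude comparison behave at the extremes", {
  set.seed(24)
  n <- 60
  sites <- make_site(1, 1, 1, 1, "s", pos = 1L)[rep(1, n), ]
  sites$site_id <- paste0("s", seq_len(n))
  sites$pos <- seq_len(n) * 1000L
  a <- rpois(n, 80) + 1
  b <- rpois(n, 80) + 1
  for (j in 1:6) { sites[[paste0("F0_A_rep", j)]] <- a
                   sites[[paste0("F0_B_rep", j)]] <- b }
  for (j in 1:12) { sites[[paste0("F1_A_rep", j)]] <- a
                    sites[[paste0("F1_B_rep", j)]] <- b }
  res <- cis_extent_correlation(sites)   # F1 ratios identical to F0
  expect_equal(res$r, 1, tolerance = 1e-9)
  # permuting the F1 side kills the correlation
  perm <- sites
  idx <- sample(n)
  for (j in 1:12) { perm[[paste0("F1_A_rep", j)]] <- a[idx]
                    perm[[paste0("F1_B_rep", j)]] <- b[idx] }
  res_p <- cis_extent_correlation(perm)
  expect_lt(abs(res_p$r), 3 / sqrt(n))

  genes <- data.frame(gene_id = paste0("g", 1:40),
                      expr_f0_a = rep(50, 40), expr_f0_b = rep(50, 40),
                      expr_f1_a = rep(50, 40), expr_f1_b = rep(50, 40))
  mag <- compare_cis_effect_magnitude(perm, genes, n_draws = 2000, seed = 3)
  expect_equal(mag$fraction_site_greater, 1, tolerance = 0.05)
  mag2 <- compare_cis_effect_magnitude(perm, genes, n_draws = 2000,
                                       seed = 3)
  expect_identical(mag, mag2)
})

test_that("direction concordance flags concordant and anti-concordant pairs", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", tss = 50000L,
                      strand = "+",
                      expr_f0_a = 80, expr_f0_b = 40,
                      expr_f1_a = 80, expr_f1_b = 40,
                      stringsAsFactors = FALSE)
  n <- 20
  sites <- make_site(1, 1, 1, 1, "s", pos = 1L)[rep(1, n), ]
  sites$site_id <- paste0("s", seq_len(n))
  sites$pos <- 40000L + seq_len(n) * 100L
  for (j in 1:12) { sites[[paste0("F1_A_rep", j)]] <- 60
                    sites[[paste0("F1_B_rep", j)]] <- 30 }
  res <- direction_concordance(sites, genes)
  expect_equal(res$agreement, 1)
  expect_lt(res$p_value, 1e-5)
  anti <- sites
  for (j in 1:12) { anti[[paste0("F1_A_rep", j)]] <- 30
                    anti[[paste0("F1_B_rep", j)]] <- 60 }
  res2 <- direction_concordance(anti, genes)
  expect_equal(res2$agreement, 0)
})
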