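# Generator moments, determinism, class marginals and planted structure.

test_that("Poisson-Gamma mixture reproduces NB moments", {
  set.seed(11)
  # dispersion 0.1 => r = 10; mean 10 => p = 0.5; var = m + d m^2 = 20
  x <- hybridreg:::rnb_mixture(10000, mean_per_draw = 10, dispersion = 0.1)
  se_mean <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 10), 3 * se_mean)
  v <- var(x)
  se_var <- sd((x - mean(x))^2) / sqrt(length(x))
  expect_lt(abs(v - 20), 3 * se_var)
  # dispersion 0 is plain Poisson
  y <- hybridreg:::rnb_mixture(10000, 10, 0)
  expect_lt(abs(var(y) - 10), 3 * sd((y - mean(y))^2) / sqrt(length(y)))
})

test_that("beta-binomial draws match closed-form moments", {
  set.seed(12)
  # n = 100, alpha = beta = 5: mean count 50,
  # var = n p q (alpha+beta+n) / (alpha+beta+1) = 100*.25*110/11 = 250
  z <- hybridreg:::rbetabin(rep(100L, 10000), mean = 0.5,
                            concentration = 10)
  expect_lt(abs(mean(z / 100) - 0.5), 3 * sd(z / 100) / sqrt(length(z)))
  se_var <- sd((z - mean(z))^2) / sqrt(length(z))
  expect_lt(abs(var(z) - 250), 3 * se_var)
})

test_that("identical config and seed give bit-identical datasets", {
  cfg <- tiny_config()
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1, s2)
  g1 <- simulate_genome_context(cfg)
  g2 <- simulate_genome_context(cfg)
  expect_identical(g1, g2)
})

test_that("dataset bookkeeping: balanced classes and truth rows", {
  cfg <- sim_config(n_sites_per_class = 100, seed = 3)
  sim <- simulate_dataset(cfg)
  expect_equal(nrow(sim$sites), 400)
  expect_equal(nrow(sim$truth), 400)
  expect_equal(sort(unique(sim$truth$true_class)), sort(REG_CLASSES))
  expect_equal(as.vector(table(sim$truth$true_class)), rep(100, 4))
  expect_false(any(duplicated(sim$sites$site_id)))
})

test_that("conserved and trans sites have F1 allelic mean 0.5; cis follows the odds", {
  cfg <- sim_config(n_sites_per_class = 400, seed = 7, library_size_cv = 0)
  frac_of <- function(class_label) {
    set.seed(42)
    m <- hybridreg:::sim_class_counts(800, class_label, cfg)
    za <- m[, grep("^F1_A", colnames(m))]
    zt <- za + m[, grep("^F1_B", colnames(m))]
    f <- za / zt
    f[zt == 0] <- NA
    f
  }
  for (cl in c("conserved", "trans")) {
    f <- frac_of(cl)
    z <- (mean(f, na.rm = TRUE) - 0.5) /
      (sd(f, na.rm = TRUE) / sqrt(sum(!is.na(f))))
    expect_lt(abs(z), 4)
  }
  # cis sites are direction-balanced: |fraction - 0.5| centers on 0.3
  f_cis <- frac_of("cis")
  expect_lt(abs(mean(abs(f_cis - 0.5), na.rm = TRUE) - 0.3), 0.05)
})

test_that("planted library scale factor doubles that library's totals", {
  cfg <- sim_config(n_sites_per_class = 500, seed = 9, library_size_cv = 0)
  lf <- list(f0_a = c(2, rep(1, 5)), f0_b = rep(1, 6), f1 = rep(1, 12))
  set.seed(31)
  m <- hybridreg:::sim_class_counts(2000, "conserved", cfg,
                                    lib_factors = lf)
  tot <- colSums(m[, grep("^F0_A", colnames(m))])
  expect_equal(unname(tot[1] / mean(tot[-1])), 2, tolerance = 0.05)
})

test_that("inheritance and lineage generators plant the advertised targets", {
  cfg <- sim_config(n_sites_per_class = 100, seed = 15,
                    library_size_cv = 0)
  dom <- simulate_inheritance_sites(300, "dominant_high_parent", cfg)
  f1_tot <- rowMeans(count_matrix(dom$sites, "F1_A") +
                       count_matrix(dom$sites, "F1_B"))
  # high parent sits at depth * sqrt(odds) = 200
  expect_equal(mean(f1_tot), 200, tolerance = 0.05)
  add <- simulate_inheritance_sites(300, "additive", cfg)
  f1_add <- rowMeans(count_matrix(add$sites, "F1_A") +
                       count_matrix(add$sites, "F1_B"))
  expect_equal(mean(f1_add), 125, tolerance = 0.05)  # midparent (200+50)/2

  lin <- simulate_lineage_sites(300, "cis", cfg)
  x <- rowMeans(count_matrix(lin$sites, "F0_A"))
  y <- rowMeans(count_matrix(lin$sites, "F1_A") +
                  count_matrix(lin$sites, "F1_B"))
  expect_equal(mean(2 * y) / mean(x), 1, tolerance = 0.05)  # 2:1 rule
  ct <- simulate_lineage_sites(300, "cis_trans", cfg)
  y2 <- rowMeans(count_matrix(ct$sites, "F1_A") +
                   count_matrix(ct$sites, "F1_B"))
  x2 <- rowMeans(count_matrix(ct$sites, "F0_A"))
  expect_equal(mean(2 * y2) / mean(x2), 2, tolerance = 0.06)
})

test_that("genome context plants extra cis sites near cis-class genes", {
  cfg <- sim_config(n_sites_per_class = 50, n_genes = 150, seed = 21,
                    planted_cis_bonus = 3)
  ctx <- simulate_genome_context(cfg)
  cls <- ctx$truth$true_class[match(ctx$sites$site_id,
                                    ctx$truth$site_id)]
  cis_sites <- ctx$sites[cls == "cis", ]
  tab <- assign_sites_to_genes(cis_sites, ctx$genes,
                               classes = rep("cis", nrow(cis_sites)))
  mean_cis <- tapply(tab$n_cis, ctx$genes$expr_class, mean)
  expect_gt(mean_cis[["cis"]], mean_cis[["conserved"]] + 1)

  # no planting: cis-site counts near genes are independent of gene class
  cfg0 <- sim_config(n_sites_per_class = 100, n_genes = 150, seed = 22,
                     chrom_length = 1e7)
  ctx0 <- simulate_genome_context(cfg0)
  cls0 <- ctx0$truth$true_class[match(ctx0$sites$site_id,
                                      ctx0$truth$site_id)]
  tab0 <- assign_sites_to_genes(ctx0$sites, ctx0$genes, classes = cls0)
  is_cis_gene <- ctx0$genes$expr_class == "cis"
  w <- suppressWarnings(wilcox.test(tab0$n_cis[is_cis_gene],
                                    tab0$n_cis[!is_cis_gene]))
  expect_gt(w$p.value, 0.01)

  # empty interaction request gives an empty endpoint table
  cfg_no <- sim_config(n_sites_per_class = 10, n_genes = 20,
                       n_interactions = 0, seed = 23)
  expect_equal(nrow(simulate_genome_context(cfg_no)$interactions), 0)
})

test_that("coordination landscape limits behave as advertised", {
  cfg <- sim_config(n_sites_per_class = 10, seed = 33, dispersion = 0.05,
                    concentration = 400)
  land_inf <- simulate_coordination_landscape(Inf, n_anchors = 40, cfg,
                                              n_partners = 20,
                                              noise_sd = 0.005)
  pr <- allelic_proportion(land_inf$sites)
  anchors <- land_inf$sites[land_inf$sites$is_anchor, ]
  partners <- land_inf$sites[!land_inf$sites$is_anchor, ]
  # with no attenuation every partner shares its anchor's shift
  a_of <- sub("_s[0-9]+$", "", partners$site_id)
  rho <- cor(pr[anchors$site_id][match(a_of, sub("_s000$", "",
                                                 anchors$site_id))],
             pr[partners$site_id], method = "spearman",
             use = "complete.obs")
  expect_gt(rho, 0.9)

  land0 <- simulate_coordination_landscape(0, n_anchors = 40, cfg,
                                           n_partners = 20)
  pr0 <- allelic_proportion(land0$sites)
  partners0 <- land0$sites[!land0$sites$is_anchor, ]
  anchors0 <- land0$sites[land0$sites$is_anchor, ]
  a_of0 <- sub("_s[0-9]+$", "", partners0$site_id)
  rho0 <- cor(pr0[anchors0$site_id][match(a_of0, sub("_s000$", "",
                                                     anchors0$site_id))],
              pr0[partners0$site_id], method = "spearman",
              use = "complete.obs")
  expect_lt(abs(rho0), 0.15)
})
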