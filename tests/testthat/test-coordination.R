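# Distance-decay coordination: proportions, binning, null, regression,
# elbow and contact enrichment.

test_that("allelic proportion averages per-replicate fractions", {
  s <- make_site(rep(10, 2), rep(10, 2), c(3, 7), c(7, 3))
  expect_equal(unname(allelic_proportion(s)), 0.5)
  all_a <- make_site(rep(10, 2), rep(10, 2), c(5, 9), c(0, 0))
  expect_equal(unname(allelic_proportion(all_a)), 1.0)
  zero <- make_site(rep(10, 2), rep(10, 2), c(0, 0), c(0, 0))
  expect_true(is.na(allelic_proportion(zero)))
})

test_that("pairs fall in exactly one bin and duplicated sites give rho = 1", {
  d <- runif(500, 400, 4e5)
  b <- hybridreg:::bin_index(d, 400, 1000)
  expect_true(all(b >= 1 & b <= 400))
  # bin edges: distance 400 -> bin 1; 1399 -> bin 1; 1400 -> bin 2
  expect_equal(hybridreg:::bin_index(c(400, 1399, 1400), 400, 1000),
               c(1L, 1L, 2L))

  # partners that copy their anchors' counts correlate perfectly
  set.seed(3)
  n <- 30
  anchors <- make_site(1, 1, 1, 1, "a", pos = 1L)[rep(1, n), ]
  anchors$site_id <- paste0("a", seq_len(n))
  anchors$pos <- seq_len(n) * 1000000L
  za <- rbinom(n, 100, runif(n, 0.2, 0.8))
  for (j in 1:12) {
    anchors[[paste0("F1_A_rep", j)]] <- za
    anchors[[paste0("F1_B_rep", j)]] <- 100 - za
  }
  partners <- anchors
  partners$site_id <- paste0("p", seq_len(n))
  partners$pos <- anchors$pos + 500L
  prof <- correlation_profile(anchors, partners, min_pairs = 10)
  pop <- prof$bins[!is.na(prof$bins$rho), ]
  expect_gt(nrow(pop), 0)
  expect_true(all(pop$rho == 1))

  # strain relabeling leaves the profile unchanged
  prof_swapped <- correlation_profile(swap_strains(anchors),
                                      swap_strains(partners),
                                      min_pairs = 10)
  expect_equal(prof_swapped$bins$rho, prof$bins$rho, tolerance = 1e-12)
})

test_that("null profile is deterministic under a seed and centered at zero", {
  cfg <- sim_config(n_sites_per_class = 10, seed = 47, dispersion = 0.05)
  land <- simulate_coordination_landscape(1e4, n_anchors = 40, cfg,
                                          n_partners = 60,
                                          max_distance = 4e4)
  anchors <- land$sites[land$sites$is_anchor, ]
  prof <- correlation_profile(anchors, land$sites, max_bp = 4e4,
                              min_pairs = 15)
  expect_gt(sum(!is.na(prof$bins$rho)), 10)
  n1 <- null_profile(prof, land$sites, n_resamples = 20, seed = 5)
  n2 <- null_profile(prof, land$sites, n_resamples = 20, seed = 5)
  expect_identical(n1, n2)
  mu <- mean(n1$null_mean, na.rm = TRUE)
  expect_lt(abs(mu), 0.1)
})

test_that("log-decay regression recovers exact and flat inputs", {
  bins <- data.frame(bin = 1:10, dist_lo = 0, dist_hi = 0,
                     dist_mid = (1:10) * 2000,
                     n_pairs = 50, rho = 0.9 - 0.08 * log((1:10) * 2000))
  prof <- structure(list(bins = bins), class = "coordination_profile")
  fit <- suppressWarnings(fit_log_decay(prof))  # exact fit: zero residuals
  expect_equal(fit$slope, -0.08, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.9, tolerance = 1e-10)
  flat <- prof
  set.seed(2)
  flat$bins$rho <- 0.3 + rnorm(10, 0, 0.01)
  cf <- fit_log_decay(flat)
  expect_true(cf$slope_ci[["lower"]] < 0 && cf$slope_ci[["upper"]] > 0)
  few <- prof; few$bins$rho[3:10] <- NA
  expect_error(fit_log_decay(few), ">= 3")
})

test_that("elbow detection matches a brute-force projection scan", {
  # independent oracle: explicit point-to-chord projection
  oracle <- function(f, from = 1000, to = 50000, step = 100) {
    d <- seq(from, to, by = step); yv <- f(d)
    xn <- (d - min(d)) / (max(d) - min(d))
    yn <- if (diff(range(yv)) > 0)
      (yv - min(yv)) / (max(yv) - min(yv)) else rep(0, length(yv))
    p1 <- c(xn[1], yn[1]); p2 <- c(xn[length(xn)], yn[length(yn)])
    u <- p2 - p1
    perp <- vapply(seq_along(d), function(i) {
      v <- c(xn[i], yn[i]) - p1
      t_par <- sum(v * u) / sum(u * u)
      sqrt(sum((v - t_par * u)^2))
    }, numeric(1))
    if (max(perp) < 1e-6) NA_real_ else d[which.max(perp)]
  }
  curves <- list(
    function(d) 0.8 - 0.07 * log(d),
    function(d) exp(-d / 10000),
    function(d) exp(-d / 3000),
    function(d) 1 / (1 + d / 5000),
    function(d) pmax(1 - d / 10000, 0),          # steep then flat at 10 kb
    function(d) 0.5 - 1e-6 * d                   # straight line
  )
  for (f in curves) {
    got <- find_elbow(f)$elbow
    want <- oracle(f)
    if (is.na(want)) expect_true(is.na(got)) else expect_equal(got, want)
  }
  # piecewise knee lands within one grid step of the kink
  knee <- find_elbow(function(d) pmax(1 - d / 10000, 0))$elbow
  expect_lt(abs(knee - 10000), 101)
  expect_error(find_elbow(function(d) rep(NA_real_, length(d))),
               "non-finite")
})

test_that("contact enrichment detects planted co-location and handles empties", {
  set.seed(9)
  n <- 80
  sites <- make_site(1, 1, 1, 1, "s", pos = 1L)[rep(1, n), ]
  sites$site_id <- paste0("s", seq_len(n))
  sites$pos <- seq_len(n) * 10000L
  sites$class <- rep(c("cis", "conserved"), each = n / 2)
  # 20 interactions linking cis sites to cis sites, 20 linking conserved
  # to conserved: cis-cis pairing is enriched over the marginal rates
  cis_pos <- sites$pos[sites$class == "cis"]
  con_pos <- sites$pos[sites$class == "conserved"]
  ep <- S4Vectors::Pairs(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(
      c(cis_pos[1:20], con_pos[1:20]) - 4,
      c(cis_pos[1:20], con_pos[1:20]) + 5)),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(
      c(cis_pos[21:40], con_pos[21:40]) - 4,
      c(cis_pos[21:40], con_pos[21:40]) + 5)))
  res <- contact_enrichment(sites, ep)
  cis_cis <- res[res$class_a == "cis" & res$class_b == "cis", ]
  expect_gt(cis_cis$enrichment, 1)
  expect_lt(cis_cis$p_value, 0.01)

  empty <- S4Vectors::Pairs(GenomicRanges::GRanges(),
                            GenomicRanges::GRanges())
  expect_message(res0 <- contact_enrichment(sites, empty),
                 "no interactions")
  expect_equal(nrow(res0), 0)
})
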