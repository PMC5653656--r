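## Distance decay of coordinated allelic imbalance around cis-class anchor
## sites, with a genome-wide resampled null, a log-distance regression, a
## vector-projection elbow estimate, and chromatin-contact enrichment.

#' Mean F1 allelic proportion of each site
#'
#' Mean across F1 replicates of allele-A reads over total reads; replicates
#' with zero total are skipped, and sites with no positive-total replicate
#' are returned as `NA`.
#'
#' @param sites site table.
#' @return named numeric vector (site_id -> proportion in `[0, 1]`).
#' @export
allelic_proportion <- function(sites) {
  za <- count_matrix(sites, "F1_A")
  zb <- count_matrix(sites, "F1_B")
  tot <- za + zb
  frac <- za / tot          # NaN where total is 0
  frac[tot == 0] <- NA
  out <- rowMeans(frac, na.rm = TRUE)
  out[is.nan(out)] <- NA
  stats::setNames(out, sites$site_id)
}

## Anchor-partner pair table: one row per (anchor, site) pair within
## [start_bp, max_bp] absolute distance on the same chromosome.
coordination_pairs <- function(anchors, sites, start_bp, max_bp) {
  pa <- allelic_proportion(anchors)
  ps <- allelic_proportion(sites)
  out <- list(); k <- 0L
  for (i in seq_len(nrow(anchors))) {
    same <- sites$chrom == anchors$chrom[i] &
      sites$site_id != anchors$site_id[i]
    d <- abs(sites$pos - anchors$pos[i])
    sel <- which(same & d >= start_bp & d <= max_bp & !is.na(ps) &
                   !is.na(pa[i]))
    if (length(sel) == 0) next
    k <- k + 1L
    out[[k]] <- data.frame(anchor_prop = unname(pa[i]),
                           site_prop = unname(ps[sel]),
                           distance = d[sel])
  }
  if (k == 0L) {
    return(data.frame(anchor_prop = numeric(), site_prop = numeric(),
                      distance = numeric()))
  }
  do.call(rbind, out)
}

bin_index <- function(distance, start_bp, bin_bp) {
  as.integer(floor((distance - start_bp) / bin_bp)) + 1L
}

#' Distance-binned Spearman correlation profile
#'
#' Pairs every cis-class anchor with all sites within `max_bp` on the same
#' chromosome (both directions pooled by absolute distance), partitions the
#' pairs into mutually exclusive distance bins of width `bin_bp` starting
#' `start_bp` from the anchor, and computes Spearman's rho between anchor
#' and partner allelic proportions within each bin. Bins with fewer than
#' `min_pairs` pairs are reported with `rho = NA`.
#'
#' @param anchors site table of anchor (cis-class) sites.
#' @param sites site table of candidate partner sites.
#' @param start_bp first bin offset from the anchor (default 400).
#' @param bin_bp bin width (default 1000).
#' @param max_bp maximum distance (default 4e5).
#' @param min_pairs minimum pairs per bin.
#' @return list of class `"coordination_profile"`: `bins` (`data.frame`:
#'   bin, dist_lo, dist_hi, dist_mid, n_pairs, rho), plus the binning
#'   parameters and the pair table.
#' @export
correlation_profile <- function(anchors, sites, start_bp = 400,
                                bin_bp = 1000, max_bp = 4e5,
                                min_pairs = 20) {
  n_bins <- ceiling((max_bp - start_bp) / bin_bp)
  pairs <- coordination_pairs(anchors, sites, start_bp, max_bp)
  bins <- data.frame(
    bin = seq_len(n_bins),
    dist_lo = start_bp + (seq_len(n_bins) - 1) * bin_bp,
    dist_hi = pmin(start_bp + seq_len(n_bins) * bin_bp, max_bp),
    n_pairs = 0L, rho = NA_real_
  )
  bins$dist_mid <- (bins$dist_lo + bins$dist_hi) / 2
  if (nrow(pairs) > 0) {
    pairs$bin <- bin_index(pairs$distance, start_bp, bin_bp)
    for (b in unique(pairs$bin)) {
      sub <- pairs[pairs$bin == b, ]
      bins$n_pairs[b] <- nrow(sub)
      if (nrow(sub) >= min_pairs) {
        bins$rho[b] <- stats::cor(sub$anchor_prop, sub$site_prop,
                                  method = "spearman")
      }
    }
  }
  structure(list(bins = bins, pairs = pairs, start_bp = start_bp,
                 bin_bp = bin_bp, max_bp = max_bp, min_pairs = min_pairs),
            class = "coordination_profile")
}

#' Resampled null for a coordination profile
#'
#' Keeps the anchors of every observed bin fixed and replaces their partner
#' sites with sites drawn at random (without replacement) from the
#' genome-wide pool, matching the observed number of pairs per bin;
#' Spearman's rho is computed exactly as for the observed profile. Repeated
#' `n_resamples` times to give a per-bin null mean and a central 95%
#' envelope. When the pool is smaller than a bin, sampling falls back to
#' with-replacement with a warning.
#'
#' @param profile a `"coordination_profile"`.
#' @param sites the site table supplying the partner pool.
#' @param n_resamples number of resampling rounds.
#' @param seed integer seed.
#' @return `data.frame`: bin, null_mean, null_lo, null_hi (2.5/97.5
#'   percentiles across resamples).
#' @export
null_profile <- function(profile, sites, n_resamples = 100, seed = 1) {
  set.seed(derive_seed(seed, "null_profile"))
  pool <- allelic_proportion(sites)
  pool <- pool[!is.na(pool)]
  pairs <- profile$pairs
  bins <- profile$bins
  out <- data.frame(bin = bins$bin, null_mean = NA_real_,
                    null_lo = NA_real_, null_hi = NA_real_)
  if (nrow(pairs) == 0 || length(pool) == 0) return(out)
  occupied <- bins$bin[bins$n_pairs >= profile$min_pairs]
  for (b in occupied) {
    sub <- pairs[pairs$bin == b, ]
    n_b <- nrow(sub)
    replace <- n_b > length(pool)
    if (replace) {
      warning("partner pool smaller than bin ", b,
              "; resampling with replacement")
    }
    rhos <- vapply(seq_len(n_resamples), function(k) {
      stats::cor(sub$anchor_prop, sample(pool, n_b, replace = replace),
                 method = "spearman")
    }, numeric(1))
    out$null_mean[out$bin == b] <- mean(rhos)
    qs <- stats::quantile(rhos, c(0.025, 0.975), names = FALSE,
                          na.rm = TRUE)
    out$null_lo[out$bin == b] <- qs[1]
    out$null_hi[out$bin == b] <- qs[2]
  }
  out
}

#' Log-distance regression of the correlation profile
#'
#' Least-squares fit `rho_b = a + b * ln(d_b)` over populated bins, with a
#' confidence interval on the slope (default 90%).
#'
#' @param profile a `"coordination_profile"`.
#' @param conf_level confidence level for the slope CI.
#' @return list: intercept, slope, slope_ci (lower, upper), n_bins, fit
#'   (the `lm` object).
#' @export
fit_log_decay <- function(profile, conf_level = 0.90) {
  bins <- profile$bins
  ok <- !is.na(bins$rho)
  if (sum(ok) < 3) stop("need >= 3 populated bins for the decay fit")
  fit <- stats::lm(rho ~ log(dist_mid), data = bins[ok, ])
  ci <- stats::confint(fit, "log(dist_mid)", level = conf_level)
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       slope_ci = c(lower = ci[1], upper = ci[2]),
       conf_level = conf_level, n_bins = sum(ok), fit = fit)
}

#' Elbow of a fitted decay curve by vector projection
#'
#' Evaluates the fitted curve on a distance grid (default 1-50 kb), draws
#' the chord between the first and last grid points after min-max
#' normalizing both axes to `[0, 1]`, and returns the grid distance with
#' the largest perpendicular distance to the chord. Returns `NA` when the
#' curve is a straight line (maximum perpendicular distance below `tol`).
#'
#' @param decay_fit result of [fit_log_decay()], or any function mapping
#'   distance (bp) to fitted correlation.
#' @param from,to,step grid definition in bp.
#' @param tol minimum normalized perpendicular distance for a real elbow.
#' @return list: elbow (bp or `NA`), max_perp_distance, grid
#'   (`data.frame`: distance, fitted).
#' @export
find_elbow <- function(decay_fit, from = 1000, to = 50000, step = 100,
                       tol = 1e-6) {
  f <- if (is.function(decay_fit)) {
    decay_fit
  } else {
    function(d) decay_fit$intercept + decay_fit$slope * log(d)
  }
  d <- seq(from, to, by = step)
  yv <- f(d)
  if (any(!is.finite(yv))) stop("non-finite fitted values on elbow grid")
  # min-max normalize both axes so the projection is unit-free
  xr <- range(d); yr <- range(yv)
  xn <- (d - xr[1]) / diff(xr)
  yn <- if (diff(yr) > 0) (yv - yr[1]) / diff(yr) else rep(0, length(yv))
  # perpendicular distance of each point to the chord (first -> last)
  ux <- xn[length(xn)] - xn[1]; uy <- yn[length(yn)] - yn[1]
  len <- sqrt(ux^2 + uy^2)
  perp <- abs(ux * (yn - yn[1]) - uy * (xn - xn[1])) / len
  i <- which.max(perp)
  elbow <- if (perp[i] < tol) NA_real_ else d[i]
  list(elbow = elbow, max_perp_distance = perp[i],
       grid = data.frame(distance = d, fitted = yv))
}

#' Chromatin-contact enrichment between regulatory classes
#'
#' For each ordered pair of regulatory classes (A, B), counts interactions
#' whose first endpoint overlaps (>= 1 bp) a class-A site and whose second
#' endpoint overlaps a class-B site, compares the count to the expectation
#' `n_interactions * p_A * p_B` built from the marginal endpoint-overlap
#' rates, and reports an exact binomial p-value.
#'
#' @param sites site table with a `class` column (or supply `classes`).
#' @param endpoints a `S4Vectors::Pairs` of endpoint `GRanges` (from
#'   [read_intervals()] with `kind = "interactions"`).
#' @param classes optional character vector of per-site classes.
#' @param site_width width of the site footprint used for overlap.
#' @return `data.frame`: class_a, class_b, observed, expected, enrichment,
#'   p_value; zero rows with a message when there are no interactions.
#' @export
contact_enrichment <- function(sites, endpoints, classes = NULL,
                               site_width = 1L) {
  if (is.null(classes)) classes <- sites$class
  stopifnot(length(classes) == nrow(sites))
  n_int <- length(S4Vectors::first(endpoints))
  if (n_int == 0) {
    message("no interactions supplied; contact enrichment skipped")
    return(data.frame(class_a = character(), class_b = character(),
                      observed = integer(), expected = numeric(),
                      enrichment = numeric(), p_value = numeric()))
  }
  gr <- sites_as_granges(sites, width = site_width)
  ep1 <- S4Vectors::first(endpoints)
  ep2 <- S4Vectors::second(endpoints)
  lv <- sort(unique(classes))
  # per-endpoint class overlap indicators
  hit_class <- function(ep, cl) {
    GenomicRanges::countOverlaps(ep, gr[classes == cl]) > 0
  }
  h1 <- sapply(lv, function(cl) hit_class(ep1, cl))
  h2 <- sapply(lv, function(cl) hit_class(ep2, cl))
  if (n_int == 1L) { h1 <- matrix(h1, 1); h2 <- matrix(h2, 1) }
  # marginal endpoint-overlap rate per class, pooled over both ends
  p_marg <- (colSums(h1) + colSums(h2)) / (2 * n_int)
  rows <- list(); k <- 0L
  for (a in seq_along(lv)) {
    for (b in seq_along(lv)) {
      obs <- sum((h1[, a] & h2[, b]) | (h1[, b] & h2[, a]))
      p_exp <- if (a == b) p_marg[a]^2 else 2 * p_marg[a] * p_marg[b]
      expd <- n_int * p_exp
      k <- k + 1L
      rows[[k]] <- data.frame(
        class_a = lv[a], class_b = lv[b], observed = obs,
        expected = expd,
        enrichment = if (expd > 0) obs / expd else NA_real_,
        p_value = if (p_exp > 0 && p_exp < 1) {
          stats::binom.test(obs, n_int, p_exp)$p.value
        } else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out <- out[as.integer(factor(out$class_a, lv)) <=
               as.integer(factor(out$class_b, lv)), ]
  rownames(out) <- NULL
  out
}
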