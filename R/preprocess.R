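## Depth normalization, site filters, SNV thinning, histone-mark SNV
## aggregation and dispersion estimation.

#' Median-of-ratios size factors
#'
#' For each library, the median over sites of the ratio of its count to the
#' site's geometric mean across libraries, using only sites with strictly
#' positive counts in every library. Dividing a library's counts by its
#' factor equalizes depth under the assumption that only a minority of
#' sites are truly differential.
#'
#' @param count_matrix numeric matrix, sites x libraries.
#' @return list of class `"size_factors"`: `factors` (named numeric vector,
#'   one per library) and `n_sites_used`.
#' @export
median_ratio_size_factors <- function(count_matrix) {
  if (ncol(count_matrix) < 2) stop("need >= 2 libraries")
  pos <- rowSums(count_matrix <= 0) == 0
  if (!any(pos)) {
    stop("no site has positive counts in all libraries; ",
         "median-of-ratios size factors are undefined")
  }
  m <- count_matrix[pos, , drop = FALSE]
  log_gm <- rowMeans(log(m))
  factors <- apply(m, 2, function(col) exp(stats::median(log(col) - log_gm)))
  if (is.null(names(factors))) names(factors) <- colnames(count_matrix)
  structure(list(factors = factors, n_sites_used = sum(pos)),
            class = "size_factors")
}

#' Estimate size factors for a site table and apply them
#'
#' Factors are computed per assay across all F0 and F1 libraries jointly,
#' using the F1 per-replicate total (allele A + allele B) as the F1 library
#' signal; each F1 factor is then applied identically to both allele
#' columns so allelic proportions are untouched.
#'
#' @param sites site table (raw counts).
#' @return list: `sites` (normalized, real-valued counts), `size_factors`.
#' @export
normalize_site_table <- function(sites) {
  f0a <- count_matrix(sites, "F0_A")
  f0b <- count_matrix(sites, "F0_B")
  f1a <- count_matrix(sites, "F1_A")
  f1b <- count_matrix(sites, "F1_B")
  lib_mat <- cbind(f0a, f0b, f1a + f1b)
  colnames(lib_mat) <- c(colnames(f0a), colnames(f0b),
                         sub("^F1_A_", "F1_", colnames(f1a)))
  sf <- median_ratio_size_factors(lib_mat)
  f <- sf$factors
  out <- sites
  for (j in seq_len(ncol(f0a))) {
    out[[colnames(f0a)[j]]] <- f0a[, j] / f[colnames(f0a)[j]]
    out[[colnames(f0b)[j]]] <- f0b[, j] / f[colnames(f0b)[j]]
  }
  for (j in seq_len(ncol(f1a))) {
    fj <- f[sub("^F1_A_", "F1_", colnames(f1a)[j])]
    out[[colnames(f1a)[j]]] <- f1a[, j] / fj
    out[[colnames(f1b)[j]]] <- f1b[, j] / fj
  }
  list(sites = out, size_factors = sf)
}

#' Coverage filters on raw counts
#'
#' Retains sites where the summed F0 count reaches `min_f0` in at least one
#' strain, and at least `min_f1_reps` F1 replicates have at least
#' `min_f1_reads` allele-resolved reads (both alleles combined).
#'
#' @param sites site table (raw counts).
#' @param min_f0 minimum summed F0 reads in either strain.
#' @param min_f1_reps minimum number of qualifying F1 replicates.
#' @param min_f1_reads minimum reads per qualifying F1 replicate.
#' @param per_replicate_f0 if `TRUE`, the F0 rule instead requires every
#'   replicate of one strain to reach `min_f0`.
#' @param verbose log attrition.
#' @return filtered site table.
#' @export
filter_sites <- function(sites, min_f0 = 10, min_f1_reps = 10,
                         min_f1_reads = 10, per_replicate_f0 = FALSE,
                         verbose = TRUE) {
  if (nrow(sites) == 0) return(sites)
  f0a <- count_matrix(sites, "F0_A")
  f0b <- count_matrix(sites, "F0_B")
  f1t <- count_matrix(sites, "F1_A") + count_matrix(sites, "F1_B")
  keep_f0 <- if (per_replicate_f0) {
    rowSums(f0a >= min_f0) == ncol(f0a) | rowSums(f0b >= min_f0) == ncol(f0b)
  } else {
    rowSums(f0a) >= min_f0 | rowSums(f0b) >= min_f0
  }
  keep_f1 <- rowSums(f1t >= min_f1_reads) >= min_f1_reps
  keep <- keep_f0 & keep_f1
  log_filter("coverage (F0 total / F1 replicate)", nrow(sites), sum(keep),
             verbose)
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Thin clustered SNVs
#'
#' Keeps at most one site in any window of `min_spacing` bp per chromosome.
#' Sites are considered in order of decreasing total (F0 + F1) coverage
#' (ties toward the smallest coordinate) and retained when no
#' already-retained site on the same chromosome lies within `min_spacing`
#' bp. Idempotent: the retained set is itself `min_spacing`-spaced.
#'
#' @param sites site table, any order.
#' @param min_spacing minimum spacing in bp (default 250).
#' @param verbose log attrition.
#' @return thinned site table, sorted by (chrom, pos).
#' @export
thin_sites_by_distance <- function(sites, min_spacing = 250,
                                   verbose = TRUE) {
  if (nrow(sites) <= 1) return(sites)
  cov <- rowSums(as.matrix(sites[, count_columns(sites), drop = FALSE]))
  keep <- logical(nrow(sites))
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    ord <- idx[order(-cov[idx], sites$pos[idx])]
    kept_pos <- numeric(0)
    for (k in ord) {
      if (length(kept_pos) == 0 ||
          min(abs(kept_pos - sites$pos[k])) >= min_spacing) {
        keep[k] <- TRUE
        kept_pos <- c(kept_pos, sites$pos[k])
      }
    }
  }
  out <- sites[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  log_filter(sprintf("thinning (>= %d bp spacing)", min_spacing),
             nrow(sites), nrow(out), verbose)
  rownames(out) <- NULL
  out
}

#' Aggregate SNV counts within histone-mark peaks
#'
#' Histone marks spread over wider regions than TF binding sites, diluting
#' per-SNV coverage; summing all member SNVs of a peak recovers power. Each
#' peak becomes one synthetic site whose per-library counts are the sums
#' over member SNVs; an SNV overlapping two peaks is assigned to the peak
#' with the nearest midpoint.
#'
#' @param sites site table of SNVs.
#' @param peak_intervals `GRanges` of peak intervals (union across genetic
#'   backgrounds).
#' @param verbose log attrition.
#' @return aggregated site table with a `members` column (comma-separated
#'   member SNV ids); `pos` is the peak midpoint.
#' @export
aggregate_histone_snvs <- function(sites, peak_intervals, verbose = TRUE) {
  gr <- sites_as_granges(sites)
  hits <- GenomicRanges::findOverlaps(gr, peak_intervals)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  if (any(duplicated(qh))) {
    # SNV in overlapping peaks: keep the peak whose midpoint is nearest
    mid <- (GenomicRanges::start(peak_intervals) +
              GenomicRanges::end(peak_intervals)) / 2
    d <- abs(sites$pos[qh] - mid[sh])
    o <- order(qh, d)
    qh <- qh[o]; sh <- sh[o]
    first <- !duplicated(qh)
    n_multi <- sum(!first)
    qh <- qh[first]; sh <- sh[first]
    if (verbose && n_multi > 0) {
      message("[aggregate] ", n_multi,
              " SNV-peak assignments resolved by nearest peak midpoint")
    }
  }
  n_dropped <- nrow(sites) - length(qh)
  log_filter("histone aggregation (SNVs outside peaks dropped)",
             nrow(sites), length(qh), verbose)

  cc <- count_columns(sites)
  rows <- lapply(sort(unique(sh)), function(pk) {
    mem <- qh[sh == pk]
    sums <- colSums(sites[mem, cc, drop = FALSE])
    mid <- round((GenomicRanges::start(peak_intervals)[pk] +
                    GenomicRanges::end(peak_intervals)[pk]) / 2)
    cbind(data.frame(site_id = paste0("peak_", pk),
                     chrom = as.character(
                       GenomicRanges::seqnames(peak_intervals)[pk]),
                     pos = as.integer(mid),
                     assay = sites$assay[mem[1]],
                     members = paste(sites$site_id[mem], collapse = ","),
                     stringsAsFactors = FALSE),
          as.data.frame(t(sums)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Estimate the NB dispersion from F0 replicates
#'
#' Per-site method-of-moments dispersion pooled across the two parental
#' strains, a fitted mean-dispersion trend `d(m) = a0 + a1/m`, and the final
#' per-site dispersion `max(trend(mean), floor)` with its reciprocal `r`
#' used as the NB size parameter by all model fits.
#'
#' @param sites site table of normalized F0 counts (>= 3 replicates per
#'   strain recommended).
#' @param floor minimum final dispersion.
#' @return list of class `"dispersion_model"`: `table` (site_id, mean,
#'   raw_dispersion, dispersion, r), `trend` (a0, a1).
#' @export
estimate_dispersion <- function(sites, floor = 1e-4) {
  f0a <- count_matrix(sites, "F0_A")
  f0b <- count_matrix(sites, "F0_B")
  ma <- rowMeans(f0a); mb <- rowMeans(f0b)
  va <- apply(f0a, 1, stats::var); vb <- apply(f0b, 1, stats::var)
  # pool within-strain moments; dispersion d solves var = m + d m^2
  pooled_mean <- (ma + mb) / 2
  raw <- (pmax(0, (va - ma)) / pmax(ma, 1e-8)^2 +
            pmax(0, (vb - mb)) / pmax(mb, 1e-8)^2) / 2
  use <- raw > 0 & pooled_mean > 0
  if (sum(use) >= 3) {
    fit <- stats::lm(raw[use] ~ I(1 / pooled_mean[use]))
    a0 <- unname(stats::coef(fit)[1]); a1 <- unname(stats::coef(fit)[2])
  } else {
    warning("too few sites with positive dispersion; trend set to the ",
            "median raw value (or floor)")
    a0 <- if (any(use)) stats::median(raw[use]) else floor
    a1 <- 0
  }
  trend_val <- a0 + a1 / pmax(pooled_mean, 1e-8)
  final <- pmax(trend_val, floor)
  structure(list(
    table = data.frame(site_id = sites$site_id, mean = pooled_mean,
                       raw_dispersion = raw, dispersion = final,
                       r = 1 / final, stringsAsFactors = FALSE),
    trend = c(a0 = a0, a1 = a1),
    floor = floor
  ), class = "dispersion_model")
}

#' Full preprocessing stage
#'
#' Applies the coverage filters on raw counts, optionally aggregates
#' histone-mark SNVs within peaks, thins clustered SNVs, normalizes depth by
#' median-of-ratios size factors, and estimates dispersion.
#'
#' @param sites raw site table.
#' @param peaks optional `GRanges` of histone peaks (enables aggregation).
#' @param min_f0,min_f1_reps,min_f1_reads,min_spacing filter parameters.
#' @param verbose log attrition.
#' @return list: `sites` (normalized), `size_factors`, `dispersion`
#'   (a `"dispersion_model"`), `raw_filtered` (filtered pre-normalization
#'   table).
#' @export
preprocess_sites <- function(sites, peaks = NULL, min_f0 = 10,
                             min_f1_reps = 10, min_f1_reads = 10,
                             min_spacing = 250, verbose = TRUE) {
  filtered <- filter_sites(sites, min_f0, min_f1_reps, min_f1_reads,
                           verbose = verbose)
  if (!is.null(peaks)) {
    filtered <- aggregate_histone_snvs(filtered, peaks, verbose = verbose)
  } else {
    filtered <- thin_sites_by_distance(filtered, min_spacing,
                                       verbose = verbose)
  }
  if (nrow(filtered) == 0) stop("no sites left after filtering")
  norm <- normalize_site_table(filtered)
  disp <- estimate_dispersion(norm$sites)
  list(sites = norm$sites, size_factors = norm$size_factors,
       dispersion = disp, raw_filtered = filtered)
}
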