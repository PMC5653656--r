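## Cross-layer integration: relating regulatory-class calls for TF binding,
## chromatin marks and gene expression via window assignment, logistic
## enrichment, concordance tests, mechanistic diversity, expression-matched
## subsampling, co-location tests and cis-extent summaries.

#' Assign classified sites to gene windows
#'
#' Counts sites of each regulatory class inside the strand-aware window
#' `up` bp upstream to `down` bp downstream of each TSS (inclusive bounds;
#' mirrored for minus-strand genes; truncated at the chromosome start).
#'
#' @param sites site table with a `class` column (or supply `classes`).
#' @param genes gene table (gene_id, chrom, tss, strand).
#' @param up,down window extents in bp.
#' @param classes optional per-site class vector.
#' @return `data.frame`: gene_id plus one `n_<class>` column per class and
#'   `n_total`; attribute `"assignments"` holds the site-gene pair table
#'   (gene_id, site_id, class, distance signed upstream < 0).
#' @export
assign_sites_to_genes <- function(sites, genes, up = 20000, down = 10000,
                                  classes = NULL) {
  if (is.null(classes)) classes <- sites$class
  stopifnot(length(classes) == nrow(sites))
  lv <- sort(unique(classes))
  counts <- matrix(0L, nrow(genes), length(lv),
                   dimnames = list(genes$gene_id, lv))
  pairs <- list(); k <- 0L
  for (g in seq_len(nrow(genes))) {
    plus <- genes$strand[g] == "+"
    lo <- if (plus) genes$tss[g] - up else genes$tss[g] - down
    hi <- if (plus) genes$tss[g] + down else genes$tss[g] + up
    lo <- max(lo, 0)
    sel <- which(sites$chrom == genes$chrom[g] &
                   sites$pos >= lo & sites$pos <= hi)
    if (length(sel) == 0) next
    tb <- table(factor(classes[sel], levels = lv))
    counts[g, ] <- counts[g, ] + as.integer(tb)
    k <- k + 1L
    d <- sites$pos[sel] - genes$tss[g]
    pairs[[k]] <- data.frame(gene_id = genes$gene_id[g],
                             site_id = sites$site_id[sel],
                             class = classes[sel],
                             distance = if (plus) d else -d,
                             stringsAsFactors = FALSE)
  }
  out <- data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE)
  for (cl in lv) out[[paste0("n_", cl)]] <- counts[, cl]
  out$n_total <- rowSums(counts)
  attr(out, "assignments") <- if (k > 0) do.call(rbind, pairs) else
    data.frame(gene_id = character(), site_id = character(),
               class = character(), distance = numeric())
  out
}

#' Logistic enrichment of a response class on per-class site counts
#'
#' Binary logistic regression of membership in one response class against
#' the per-class counts of nearby sites (four predictors). Odds ratios are
#' exponentiated coefficients; `|Z| > 2` marks the conventional 5%
#' significance level. Zero-variance predictors are flagged non-estimable.
#'
#' @param gene_table output of [assign_sites_to_genes()] with a
#'   `response_class` column naming each observation's own class.
#' @param response_class the class treated as the positive outcome.
#' @param predictors names of count columns; default all `n_<class>`.
#' @return `data.frame`: response, predictor, estimate (log-odds), odds_ratio,
#'   z, p_value, estimable.
#' @export
logistic_enrichment <- function(gene_table, response_class,
                                predictors = NULL) {
  if (is.null(predictors)) {
    predictors <- setdiff(grep("^n_", colnames(gene_table), value = TRUE),
                          "n_total")
  }
  yv <- as.integer(gene_table$response_class == response_class)
  if (length(unique(yv)) < 2) stop("response class has no contrast")
  dat <- gene_table[, predictors, drop = FALSE]
  const <- vapply(dat, function(v) stats::var(v) == 0, logical(1))
  form <- stats::as.formula(paste("yv ~",
    paste(predictors[!const], collapse = " + ")))
  dat$yv <- yv
  fit <- suppressWarnings(stats::glm(form, data = dat, family = stats::binomial()))
  sm <- summary(fit)$coefficients
  rows <- lapply(predictors, function(p) {
    if (const[p] || !(p %in% rownames(sm))) {
      data.frame(response = response_class, predictor = p,
                 estimate = NA_real_, odds_ratio = NA_real_, z = NA_real_,
                 p_value = NA_real_, estimable = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      est <- sm[p, "Estimate"]; se <- sm[p, "Std. Error"]
      # perfect separation leaves huge SEs; flag as non-estimable
      ok <- is.finite(est) && is.finite(se) && se < 100
      data.frame(response = response_class, predictor = p,
                 estimate = est, odds_ratio = exp(est),
                 z = sm[p, "z value"], p_value = sm[p, "Pr(>|z|)"],
                 estimable = ok, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Enrichment regressions for all four response classes
#'
#' Runs [logistic_enrichment()] with each class as the response in turn and
#' adds display-style mean-centered odds ratios (per-predictor log-odds
#' centred across the four response fits before exponentiation).
#'
#' @param gene_table as for [logistic_enrichment()].
#' @param classes response classes to cycle through.
#' @return `data.frame` of stacked enrichment rows with a
#'   `centered_odds_ratio` column.
#' @export
enrichment_by_class <- function(gene_table,
                                classes = intersect(REG_CLASSES,
                                  unique(gene_table$response_class))) {
  res <- do.call(rbind, lapply(classes, function(cl)
    logistic_enrichment(gene_table, cl)))
  ctr <- stats::ave(res$estimate, res$predictor,
                    FUN = function(v) v - mean(v, na.rm = TRUE))
  res$centered_odds_ratio <- exp(ctr)
  res
}

#' Enrichment of site classes around chromatin marks
#'
#' The same regression machinery with histone-mark locations as
#' observations and the counts of classified sites within `window` bp of
#' each mark as predictors.
#'
#' @param marks mark table (site-table layout plus a `class` column).
#' @param sites classified site table (needs a `class` column).
#' @param window half-width of the window centred on each mark, bp.
#' @return as [enrichment_by_class()].
#' @export
chromatin_tf_enrichment <- function(marks, sites, window = 2000) {
  pseudo_genes <- data.frame(gene_id = marks$site_id, chrom = marks$chrom,
                             tss = marks$pos, strand = "+",
                             stringsAsFactors = FALSE)
  tab <- assign_sites_to_genes(sites, pseudo_genes, up = window,
                               down = window)
  tab$response_class <- marks$class[match(tab$gene_id, marks$site_id)]
  enrichment_by_class(tab)
}

#' Concordance of promoter-mark and gene classes
#'
#' Assigns each mark to a gene when it lies within `upstream` bp upstream
#' of the TSS, then tests per class whether gene and assigned mark share
#' that class more often than the product of the marginal class frequencies
#' (one-sided exact binomial).
#'
#' @param marks classified mark table (`class` column).
#' @param genes gene table with an `expr_class` column.
#' @param upstream assignment window upstream of the TSS, bp.
#' @return `data.frame`: class, n_pairs, n_shared, expected_p, p_value; or
#'   zero rows when nothing is assignable.
#' @export
promoter_mark_gene_concordance <- function(marks, genes, upstream = 5000) {
  pairs <- list(); k <- 0L
  for (g in seq_len(nrow(genes))) {
    plus <- genes$strand[g] == "+"
    lo <- if (plus) genes$tss[g] - upstream else genes$tss[g]
    hi <- if (plus) genes$tss[g] else genes$tss[g] + upstream
    sel <- which(marks$chrom == genes$chrom[g] & marks$pos >= max(lo, 0) &
                   marks$pos <= hi)
    if (length(sel) == 0) next
    k <- k + 1L
    pairs[[k]] <- data.frame(gene_class = genes$expr_class[g],
                             mark_class = marks$class[sel],
                             stringsAsFactors = FALSE)
  }
  if (k == 0) {
    message("no mark-gene pairs within the assignment window")
    return(data.frame(class = character(), n_pairs = integer(),
                      n_shared = integer(), expected_p = numeric(),
                      p_value = numeric()))
  }
  tab <- do.call(rbind, pairs)
  n <- nrow(tab)
  out <- lapply(sort(unique(c(tab$gene_class, tab$mark_class))),
                function(cl) {
    p0 <- mean(tab$gene_class == cl) * mean(tab$mark_class == cl)
    shared <- sum(tab$gene_class == cl & tab$mark_class == cl)
    pv <- if (p0 > 0 && p0 < 1) {
      stats::binom.test(shared, n, p0, alternative = "greater")$p.value
    } else NA_real_
    data.frame(class = cl, n_pairs = n, n_shared = shared,
               expected_p = p0, p_value = pv, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Shannon diversity of class proportions
#'
#' `H' = -sum(a_i log a_i)` with `0 log 0 = 0`; ranges from 0 (a single
#' class) to `log(k)` at the uniform distribution over `k` classes.
#'
#' @param proportions non-negative proportions summing to 1.
#' @return H-prime.
#' @export
shannon_diversity <- function(proportions) {
  if (any(proportions < 0)) stop("proportions must be non-negative")
  s <- sum(proportions)
  if (abs(s - 1) > 1e-8) stop("proportions must sum to 1")
  p <- proportions[proportions > 0]
  -sum(p * log(p))
}

#' Mechanistic diversity of sites near genes, by expression class
#'
#' Per-gene Shannon diversity over the regulatory classes of its window's
#' sites, with two-sided rank-sum tests between expression classes.
#'
#' @param gene_table output of [assign_sites_to_genes()] with an
#'   `expr_class` column; genes with no assigned site are dropped.
#' @return list: `per_gene` (gene_id, expr_class, n_sites, H),
#'   `tests` (class_a, class_b, n_a, n_b, p_value; skipped pairs where a
#'   class has < 2 genes).
#' @export
diversity_by_expression_class <- function(gene_table) {
  cnt_cols <- setdiff(grep("^n_", colnames(gene_table), value = TRUE),
                      "n_total")
  keep <- gene_table$n_total >= 1
  tab <- gene_table[keep, , drop = FALSE]
  H <- apply(tab[, cnt_cols, drop = FALSE], 1, function(v) {
    shannon_diversity(v / sum(v))
  })
  per_gene <- data.frame(gene_id = tab$gene_id,
                         expr_class = tab$expr_class,
                         n_sites = tab$n_total, H = H,
                         stringsAsFactors = FALSE)
  lv <- sort(unique(per_gene$expr_class))
  tests <- list(); k <- 0L
  if (length(lv) >= 2) {
    for (i in seq_len(length(lv) - 1)) {
      for (j in seq.int(i + 1, length(lv))) {
        ha <- per_gene$H[per_gene$expr_class == lv[i]]
        hb <- per_gene$H[per_gene$expr_class == lv[j]]
        if (length(ha) < 2 || length(hb) < 2) next
        k <- k + 1L
        pv <- suppressWarnings(stats::wilcox.test(ha, hb)$p.value)
        tests[[k]] <- data.frame(class_a = lv[i], class_b = lv[j],
                                 n_a = length(ha), n_b = length(hb),
                                 p_value = pv, stringsAsFactors = FALSE)
      }
    }
  }
  list(per_gene = per_gene,
       tests = if (k > 0) do.call(rbind, tests) else
         data.frame(class_a = character(), class_b = character(),
                    n_a = integer(), n_b = integer(), p_value = numeric()))
}

#' Expression-matched subsampling of genes
#'
#' Bins the log expression of the more highly expressed parent into 20
#' equal-width intervals and matches every target-class gene to a
#' reference-class gene drawn (with replacement) from the same bin; target
#' genes in bins with no reference gene are dropped with a warning.
#'
#' @param genes gene table with `expr_class`, `expr_f0_a`, `expr_f0_b`.
#' @param target_class,reference_class expression classes to match.
#' @param n_bins number of equal-width log-expression bins.
#' @param seed integer seed.
#' @return list: `target` and `matched_reference` gene tables (equal rows,
#'   bin-aligned), `bins` (per-bin counts), `n_dropped`.
#' @export
expression_matched_subsample <- function(genes, target_class,
                                         reference_class, n_bins = 20,
                                         seed = 1) {
  set.seed(derive_seed(seed, "expression_matching"))
  hi_expr <- pmax(genes$expr_f0_a, genes$expr_f0_b)
  lx <- log(hi_expr + 0.5)
  brk <- seq(min(lx), max(lx), length.out = n_bins + 1)
  bin <- cut(lx, brk, include.lowest = TRUE, labels = FALSE)
  tgt <- which(genes$expr_class == target_class)
  ref <- which(genes$expr_class == reference_class)
  if (length(tgt) == 0 || length(ref) == 0) {
    stop("target or reference class empty")
  }
  matched <- integer(0); kept <- integer(0); dropped <- 0L
  for (i in tgt) {
    cand <- ref[bin[ref] == bin[i]]
    if (length(cand) == 0) { dropped <- dropped + 1L; next }
    kept <- c(kept, i)
    matched <- c(matched, if (length(cand) == 1) cand else sample(cand, 1))
  }
  if (dropped > 0) {
    warning(dropped, " target gene(s) dropped: empty reference bin")
  }
  list(target = genes[kept, , drop = FALSE],
       matched_reference = genes[matched, , drop = FALSE],
       bins = data.frame(bin = seq_len(n_bins),
                         n_target = tabulate(bin[kept], n_bins),
                         n_reference = tabulate(bin[matched], n_bins)),
       n_dropped = dropped)
}

#' Shared regulatory class at co-located sites
#'
#' For SNVs bound by all assays, tests per class whether all assays carry
#' the same class more often than the product of the per-assay class
#' proportions (one-sided exact binomial).
#'
#' @param calls_by_assay named list of call `data.frame`s (site_id, class),
#'   one per assay; only site_ids present in every assay are used.
#' @return `data.frame`: class, n_sites, n_shared, expected_p, p_value.
#' @export
colocation_shared_class_test <- function(calls_by_assay) {
  stopifnot(length(calls_by_assay) >= 2)
  shared_ids <- Reduce(intersect, lapply(calls_by_assay, `[[`, "site_id"))
  if (length(shared_ids) == 0) {
    message("no sites bound in all assays")
    return(data.frame(class = character(), n_sites = integer(),
                      n_shared = integer(), expected_p = numeric(),
                      p_value = numeric()))
  }
  mat <- sapply(calls_by_assay, function(tab)
    tab$class[match(shared_ids, tab$site_id)])
  if (length(shared_ids) == 1L) mat <- matrix(mat, nrow = 1)
  n <- nrow(mat)
  out <- lapply(sort(unique(as.vector(mat))), function(cl) {
    p_i <- prod(colMeans(mat == cl))
    k <- sum(rowSums(mat == cl) == ncol(mat))
    pv <- if (p_i > 0 && p_i < 1) {
      stats::binom.test(k, n, p_i, alternative = "greater")$p.value
    } else NA_real_
    data.frame(class = cl, n_sites = n, n_shared = k, expected_p = p_i,
               p_value = pv, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Class enrichment of sites inside genomic regions
#'
#' For sites overlapping (>= 1 bp) a region set, tests per class whether
#' the class is over- or under-represented relative to its overall
#' proportion (two-sided exact binomial), with the odds ratio
#' `(k/(n-k)) / (p/(1-p))`.
#'
#' @param sites classified site table (`class` column).
#' @param regions `GRanges` of regions (e.g. promoter or enhancer marks).
#' @param overall_props optional named overall class proportions (default:
#'   proportions among all input sites).
#' @return `data.frame`: class, n_in_regions, k_class, overall_p,
#'   odds_ratio, p_value.
#' @export
region_class_enrichment <- function(sites, regions, overall_props = NULL) {
  if (is.null(overall_props)) {
    overall_props <- prop.table(table(sites$class))
  }
  gr <- sites_as_granges(sites)
  inside <- GenomicRanges::countOverlaps(gr, regions) > 0
  n <- sum(inside)
  if (n == 0) {
    message("no site overlaps the region set")
    return(data.frame(class = character(), n_in_regions = integer(),
                      k_class = integer(), overall_p = numeric(),
                      odds_ratio = numeric(), p_value = numeric()))
  }
  cls_in <- sites$class[inside]
  out <- lapply(names(overall_props), function(cl) {
    p <- as.numeric(overall_props[cl])
    k <- sum(cls_in == cl)
    or <- if (k < n && p > 0 && p < 1) (k / (n - k)) / (p / (1 - p))
          else NA_real_
    pv <- if (p > 0 && p < 1) stats::binom.test(k, n, p)$p.value
          else NA_real_
    data.frame(class = cl, n_in_regions = n, k_class = k, overall_p = p,
               odds_ratio = or, p_value = pv, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

## Mean-based log2 ratios of a site table with a 0.5 pseudocount for zeros.
site_log2_ratios <- function(sites) {
  pc <- function(v) ifelse(v == 0, 0.5, v)
  a0 <- pc(rowMeans(count_matrix(sites, "F0_A")))
  b0 <- pc(rowMeans(count_matrix(sites, "F0_B")))
  a1 <- pc(rowMeans(count_matrix(sites, "F1_A")))
  b1 <- pc(rowMeans(count_matrix(sites, "F1_B")))
  data.frame(site_id = sites$site_id, f0_log2 = log2(a0 / b0),
             f1_log2 = log2(a1 / b1), stringsAsFactors = FALSE)
}

## Same for a gene table's expression summaries.
gene_log2_ratios <- function(genes) {
  pc <- function(v) ifelse(v == 0, 0.5, v)
  data.frame(gene_id = genes$gene_id,
             f0_log2 = log2(pc(genes$expr_f0_a) / pc(genes$expr_f0_b)),
             f1_log2 = log2(pc(genes$expr_f1_a) / pc(genes$expr_f1_b)),
             stringsAsFactors = FALSE)
}

#' Cis extent: Pearson correlation of F0 and F1 log2 ratios
#'
#' The correlation between the parental log2 ratio and the F1 allelic log2
#' ratio summarizes how much of the divergence is cis-directed: 1 means no
#' trans contribution; 0 means equal cis and trans contributions (in the
#' absence of noise).
#'
#' @param x a site table, or a gene table (`gene_id`/expression columns).
#' @return `data.frame`: r, ci_lower, ci_upper (Fisher-z 95% CI), n,
#'   p_value.
#' @export
cis_extent_correlation <- function(x) {
  ratios <- if ("gene_id" %in% colnames(x)) gene_log2_ratios(x)
            else site_log2_ratios(x)
  if (nrow(ratios) < 3) stop("need >= 3 units for a correlation")
  ct <- stats::cor.test(ratios$f0_log2, ratios$f1_log2)
  data.frame(r = unname(ct$estimate), ci_lower = ct$conf.int[1],
             ci_upper = ct$conf.int[2], n = nrow(ratios),
             p_value = ct$p.value)
}

#' Compare cis-effect magnitudes between sites and genes
#'
#' Over random (site, gene) pairs, the fraction where the site's F1 allelic
#' magnitude `|log2(A/B)|` exceeds the gene's (ties count one half).
#'
#' @param sites site table.
#' @param genes gene table.
#' @param n_draws number of random pairs.
#' @param seed integer seed.
#' @return `data.frame`: fraction_site_greater, n_draws.
#' @export
compare_cis_effect_magnitude <- function(sites, genes, n_draws = 10000,
                                         seed = 1) {
  if (nrow(sites) == 0 || nrow(genes) == 0) stop("empty input")
  set.seed(derive_seed(seed, "magnitude_comparison"))
  ms <- abs(site_log2_ratios(sites)$f1_log2)
  mg <- abs(gene_log2_ratios(genes)$f1_log2)
  si <- sample.int(length(ms), n_draws, replace = TRUE)
  gi <- sample.int(length(mg), n_draws, replace = TRUE)
  frac <- mean((ms[si] > mg[gi]) + 0.5 * (ms[si] == mg[gi]))
  data.frame(fraction_site_greater = frac, n_draws = n_draws)
}

#' Direction concordance of site and gene allelic changes
#'
#' For site-gene pairs from [assign_sites_to_genes()], tests whether the
#' signs of the F1 allelic log2 ratios agree more often than chance (exact
#' binomial against 0.5; zero-sign pairs dropped) and reports Spearman's
#' rho of the signed magnitudes.
#'
#' @param sites site table.
#' @param genes gene table.
#' @param up,down window extents, bp.
#' @return `data.frame`: n_pairs, agreement, p_value, rho.
#' @export
direction_concordance <- function(sites, genes, up = 20000, down = 10000) {
  cls <- if ("class" %in% colnames(sites)) sites$class
         else rep("site", nrow(sites))
  tab <- assign_sites_to_genes(sites, genes, up, down, classes = cls)
  pairs <- attr(tab, "assignments")
  if (nrow(pairs) == 0) stop("no site-gene pairs in the windows")
  sr <- site_log2_ratios(sites)
  gr <- gene_log2_ratios(genes)
  s_val <- sr$f1_log2[match(pairs$site_id, sr$site_id)]
  g_val <- gr$f1_log2[match(pairs$gene_id, gr$gene_id)]
  nz <- sign(s_val) != 0 & sign(g_val) != 0
  agree <- sign(s_val[nz]) == sign(g_val[nz])
  pv <- if (length(agree) > 0) {
    stats::binom.test(sum(agree), length(agree), 0.5)$p.value
  } else NA_real_
  rho <- suppressWarnings(
    stats::cor(s_val, g_val, method = "spearman"))
  data.frame(n_pairs = nrow(pairs),
             agreement = if (length(agree)) mean(agree) else NA_real_,
             p_value = pv, rho = rho)
}
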