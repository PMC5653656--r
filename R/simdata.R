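## Synthetic allele-specific count data with known ground truth.
##
## Generative hierarchy: F0 counts are Poisson with Gamma-distributed means
## (negative-binomial marginals); F1 totals come from the same family at the
## offspring's expected occupancy; F1 allele-A counts are beta-binomial with
## a class-determined mean. Library-size variation enters as multiplicative
## log-normal scale factors.

#' Simulation configuration
#'
#' Builds and validates the configuration object used by every generator in
#' the package. Defaults mirror the study design the package targets: six F0
#' replicates per parental strain and twelve allele-resolved F1 replicates.
#'
#' @param n_sites_per_class sites to simulate per regulatory class.
#' @param n_f0_reps F0 replicates per strain.
#' @param n_f1_reps F1 hybrid replicates (each yields two allele counts).
#' @param mean_depth expected reads per site per F0 replicate.
#' @param dispersion site-level overdispersion `d` (NB variance is
#'   `m + d m^2`); `0` gives Poisson counts.
#' @param f0_odds strain-A : strain-B intensity odds at non-conserved sites.
#' @param f1_allelic_mean_cis_trans expected strain-A allele fraction at
#'   cis-trans sites (cis sites derive theirs from `f0_odds`; conserved and
#'   trans sites sit at 0.5).
#' @param concentration beta concentration (alpha + beta) of the F1 allelic
#'   fraction.
#' @param library_size_cv coefficient of variation of the log-normal
#'   per-library scale factors.
#' @param f1_depth_ratio expected F1 total depth relative to the F0
#'   per-site depth.
#' @param trans_f1_multiplier shared multiplier applied to both F1 alleles
#'   (relative to the midparent) at trans and cis-trans sites.
#' @param chrom_length length in bp of the single simulated chromosome.
#' @param n_genes,n_interactions sizes for [simulate_genome_context()].
#' @param planted_cis_bonus expected number of extra cis-class sites planted
#'   in the upstream window of cis-class genes (0 disables planting).
#' @param assay assay label written on simulated sites.
#' @param seed root integer seed; every generator derives its own stream
#'   from it, so identical configs give bit-identical output.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_sites_per_class = 100,
                       n_f0_reps = 6,
                       n_f1_reps = 12,
                       mean_depth = 100,
                       dispersion = 0.1,
                       f0_odds = 4,
                       f1_allelic_mean_cis_trans = 2 / 3,
                       concentration = 50,
                       library_size_cv = 0.1,
                       f1_depth_ratio = 1,
                       trans_f1_multiplier = 1,
                       chrom_length = 5e7,
                       n_genes = 200,
                       n_interactions = 100,
                       planted_cis_bonus = 0,
                       assay = "TF1",
                       seed = 1L) {
  cfg <- list(
    n_sites_per_class = as.integer(n_sites_per_class),
    n_f0_reps = as.integer(n_f0_reps),
    n_f1_reps = as.integer(n_f1_reps),
    mean_depth = mean_depth,
    dispersion = dispersion,
    f0_odds = f0_odds,
    f1_allelic_mean_cis_trans = f1_allelic_mean_cis_trans,
    concentration = concentration,
    library_size_cv = library_size_cv,
    f1_depth_ratio = f1_depth_ratio,
    trans_f1_multiplier = trans_f1_multiplier,
    chrom_length = chrom_length,
    n_genes = as.integer(n_genes),
    n_interactions = as.integer(n_interactions),
    planted_cis_bonus = planted_cis_bonus,
    assay = assay,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_sites_per_class > 0, cfg$n_f0_reps > 0, cfg$n_f1_reps > 0,
    cfg$mean_depth > 0, cfg$dispersion >= 0, cfg$f0_odds > 0,
    cfg$f1_allelic_mean_cis_trans > 0, cfg$f1_allelic_mean_cis_trans < 1,
    cfg$concentration > 0, cfg$library_size_cv >= 0,
    cfg$f1_depth_ratio > 0, cfg$trans_f1_multiplier > 0,
    cfg$chrom_length > 0
  )
  invisible(cfg)
}

## Deterministic per-operation seed stream: one root seed, distinct
## sub-streams per labelled operation, all below 2^31.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587)
}

## Draw NB counts as an explicit Poisson-Gamma mixture (dispersion 0 ->
## plain Poisson). `mean_per_draw` may be a vector of per-draw means.
rnb_mixture <- function(n, mean_per_draw, dispersion) {
  if (length(mean_per_draw) == 1L) mean_per_draw <- rep(mean_per_draw, n)
  if (dispersion <= 0) return(stats::rpois(n, mean_per_draw))
  r <- 1 / dispersion
  lam <- stats::rgamma(n, shape = r, scale = mean_per_draw / r)
  stats::rpois(n, lam)
}

## Beta-binomial draws in mean/concentration form.
rbetabin <- function(n_totals, mean, concentration) {
  a <- mean * concentration
  b <- (1 - mean) * concentration
  p <- stats::rbeta(length(n_totals), a, b)
  stats::rbinom(length(n_totals), n_totals, p)
}

## Expected F0 strain means for a class: geometrically symmetric around the
## configured depth so the log-ratio is centred.
f0_class_means <- function(class_label, cfg) {
  if (class_label == "conserved") {
    c(a = cfg$mean_depth, b = cfg$mean_depth)
  } else {
    c(a = cfg$mean_depth * sqrt(cfg$f0_odds),
      b = cfg$mean_depth / sqrt(cfg$f0_odds))
  }
}

## Expected F1 strain-A allelic fraction for a class.
f1_class_mean <- function(class_label, cfg) {
  switch(class_label,
    conserved = 0.5,
    trans     = 0.5,
    cis       = cfg$f0_odds / (cfg$f0_odds + 1),
    cis_trans = cfg$f1_allelic_mean_cis_trans,
    stop("unknown regulatory class: ", class_label)
  )
}

## Expected F1 total occupancy given parental means and inheritance mode.
f1_total_target <- function(mode, mu_a, mu_b) {
  hi <- max(mu_a, mu_b); lo <- min(mu_a, mu_b)
  switch(mode,
    additive             = (mu_a + mu_b) / 2,
    dominant_high_parent = hi,
    dominant_low_parent  = lo,
    overdominant         = 1.5 * hi,
    underdominant        = 0.5 * lo,
    stop("unknown inheritance mode: ", mode)
  )
}

## Log-normal library scale factors with mean 1 and the configured CV.
draw_library_factors <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

## Core class-conditional count generator for `n` sites. `lib_factors` is a
## list with elements f0_a, f0_b, f1 (multiplicative, one per library).
## The strain carrying the higher occupancy is balanced exactly (half the
## sites each way, in random order) unless `flip` is given: real cross data
## is direction-symmetric, and a direction-imbalanced table would bias the
## median-of-ratios normalization downstream.
## Returns a numeric matrix with the standard column layout.
sim_class_counts <- function(n, class_label, cfg,
                             inheritance_mode = "additive",
                             lib_factors = NULL, flip = NULL) {
  class_label <- match.arg(class_label, REG_CLASSES)
  if (is.null(lib_factors)) {
    lib_factors <- list(f0_a = rep(1, cfg$n_f0_reps),
                        f0_b = rep(1, cfg$n_f0_reps),
                        f1 = rep(1, cfg$n_f1_reps))
  }
  if (is.null(flip)) {
    flip <- sample(rep(c(FALSE, TRUE), length.out = n))
  }
  if (length(flip) == 1L) flip <- rep(flip, n)
  mus <- f0_class_means(class_label, cfg)
  mu_a <- ifelse(flip, mus["b"], mus["a"])
  mu_b <- ifelse(flip, mus["a"], mus["b"])
  p_base <- f1_class_mean(class_label, cfg)
  p1 <- ifelse(flip, 1 - p_base, p_base)
  total <- f1_total_target(inheritance_mode, mus["a"], mus["b"]) *
    cfg$f1_depth_ratio
  if (class_label %in% c("trans", "cis_trans")) {
    total <- total * cfg$trans_f1_multiplier
  }

  f0_a <- sapply(seq_len(cfg$n_f0_reps), function(j)
    rnb_mixture(n, mu_a * lib_factors$f0_a[j], cfg$dispersion))
  f0_b <- sapply(seq_len(cfg$n_f0_reps), function(j)
    rnb_mixture(n, mu_b * lib_factors$f0_b[j], cfg$dispersion))
  f1_tot <- sapply(seq_len(cfg$n_f1_reps), function(j)
    rnb_mixture(n, total * lib_factors$f1[j], cfg$dispersion))
  if (n == 1L) {  # sapply drops single-site draws to vectors
    f0_a <- matrix(f0_a, nrow = 1); f0_b <- matrix(f0_b, nrow = 1)
    f1_tot <- matrix(f1_tot, nrow = 1)
  }
  f1_a <- apply(f1_tot, 2, function(nt) rbetabin(nt, p1, cfg$concentration))
  if (n == 1L) f1_a <- matrix(f1_a, nrow = 1)
  f1_b <- f1_tot - f1_a
  m <- cbind(f0_a, f0_b, f1_a, f1_b)
  colnames(m) <- count_column_names(cfg$n_f0_reps, cfg$n_f1_reps)
  m
}

count_column_names <- function(n_f0, n_f1) {
  c(paste0("F0_A_rep", seq_len(n_f0)), paste0("F0_B_rep", seq_len(n_f0)),
    paste0("F1_A_rep", seq_len(n_f1)), paste0("F1_B_rep", seq_len(n_f1)))
}

#' Simulate one allele-specific site
#'
#' Draws replicate F0 and F1 counts for a single site of a given regulatory
#' class under the package's generative hierarchy.
#'
#' @param class_label one of `"conserved"`, `"cis"`, `"trans"`, `"cis_trans"`.
#' @param config a [sim_config()] object.
#' @param seed integer seed for this draw; defaults to a stream derived from
#'   `config$seed`.
#' @param inheritance_mode inheritance mode shaping the expected F1 total.
#' @param site_id,chrom,pos,assay site metadata.
#' @param flip if `TRUE`, strain B carries the higher occupancy (default
#'   `FALSE`: strain A high, the single-site convention).
#' @return One-row `data.frame` in the site-table layout (see
#'   [read_site_table()]).
#' @export
simulate_site <- function(class_label, config,
                          seed = derive_seed(config$seed, "site"),
                          inheritance_mode = "additive",
                          site_id = "site_1", chrom = "chr1", pos = 1000L,
                          assay = config$assay, flip = FALSE) {
  class_label <- match.arg(class_label, REG_CLASSES)
  validate_sim_config(config)
  set.seed(seed)
  m <- sim_class_counts(1L, class_label, config, inheritance_mode,
                        flip = flip)
  cbind(data.frame(site_id = site_id, chrom = chrom, pos = as.integer(pos),
                   assay = assay, stringsAsFactors = FALSE),
        as.data.frame(m))
}

#' Simulate a full site table with ground truth
#'
#' Generates a balanced (or weighted) mixture of the four regulatory classes
#' with per-library log-normal scale factors applied multiplicatively, and a
#' truth table recording every planted property.
#'
#' @param config a [sim_config()] object.
#' @param class_weights optional non-negative weights over the four classes;
#'   default balanced.
#' @return list with elements `sites` (site table `data.frame`), `truth`
#'   (`data.frame`: site_id, true_class, true_inheritance, true_lineage,
#'   true_outgroup), and `lib_factors` (list of the planted factors).
#' @export
simulate_dataset <- function(config, class_weights = NULL) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "dataset"))
  if (is.null(class_weights)) class_weights <- rep(1, 4)
  stopifnot(length(class_weights) == 4, all(class_weights >= 0))
  n_per <- round(config$n_sites_per_class * 4 *
                   class_weights / sum(class_weights))

  lib_factors <- list(
    f0_a = draw_library_factors(config$n_f0_reps, config$library_size_cv),
    f0_b = draw_library_factors(config$n_f0_reps, config$library_size_cv),
    f1 = draw_library_factors(config$n_f1_reps, config$library_size_cv)
  )

  blocks <- list(); truths <- list()
  for (ci in seq_along(REG_CLASSES)) {
    cl <- REG_CLASSES[ci]
    n <- n_per[ci]
    if (n == 0) next
    m <- sim_class_counts(n, cl, config, lib_factors = lib_factors)
    blocks[[cl]] <- m
    truths[[cl]] <- data.frame(true_class = rep(cl, n),
                               stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, blocks)
  n_tot <- nrow(counts)
  pos <- sort(sample.int(config$chrom_length, n_tot))
  sites <- cbind(
    data.frame(site_id = sprintf("site_%05d", seq_len(n_tot)),
               chrom = "chr1", pos = pos, assay = config$assay,
               stringsAsFactors = FALSE),
    as.data.frame(counts)
  )
  rownames(sites) <- NULL
  truth <- do.call(rbind, truths)
  truth <- data.frame(site_id = sites$site_id,
                      true_class = truth$true_class,
                      true_inheritance = ifelse(
                        truth$true_class == "conserved",
                        "equal_parents", "additive"),
                      true_lineage = "shared",
                      true_outgroup = NA,
                      stringsAsFactors = FALSE)
  list(sites = sites, truth = truth, lib_factors = lib_factors)
}

#' Simulate sites with planted inheritance modes
#'
#' Non-conserved sites (parental odds from the config) whose expected F1
#' total occupancy follows the requested inheritance mode; `"equal_parents"`
#' plants truly identical parents, for testing the exclusion rules.
#'
#' @param n number of sites.
#' @param mode `"additive"`, `"dominant_high_parent"`,
#'   `"dominant_low_parent"`, `"overdominant"`, `"underdominant"`, or
#'   `"equal_parents"`.
#' @param config a [sim_config()] object.
#' @param class_label regulatory class of the planted sites (default trans,
#'   so the F1 allelic fraction stays at 0.5).
#' @return list(sites, truth) as in [simulate_dataset()].
#' @export
simulate_inheritance_sites <- function(n, mode, config,
                                       class_label = "trans") {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, paste0("inherit_", mode)))
  if (mode == "equal_parents") {
    m <- sim_class_counts(n, "conserved", config)
    true_class <- "conserved"
  } else {
    m <- sim_class_counts(n, class_label, config, inheritance_mode = mode)
    true_class <- class_label
  }
  sites <- cbind(
    data.frame(site_id = sprintf("inh_%s_%04d", mode, seq_len(n)),
               chrom = "chr1",
               pos = sort(sample.int(config$chrom_length, n)),
               assay = config$assay, stringsAsFactors = FALSE),
    as.data.frame(m)
  )
  truth <- data.frame(site_id = sites$site_id, true_class = true_class,
                      true_inheritance = mode, true_lineage = "shared",
                      true_outgroup = NA, stringsAsFactors = FALSE)
  list(sites = sites, truth = truth)
}

#' Simulate lineage-specific sites
#'
#' Sites bound in only one parental strain and on only the matching F1
#' allele. Under a pure cis mechanism the F1 total is half the bound
#' parent's F0 level (one bound allele in a diploid); under cis-trans the
#' F1 total deviates from that 2:1 expectation (default: equals the F0
#' level).
#'
#' @param n number of sites.
#' @param mechanism `"cis"` or `"cis_trans"`.
#' @param config a [sim_config()] object.
#' @param bound_strain `"A"` or `"B"`.
#' @param f1_over_f0 expected F1-total : F0 ratio; defaults to 0.5 for cis
#'   and 1 for cis-trans.
#' @param background_rate residual relative occupancy of the unbound strain.
#' @param outgroup_prob probability the site is present in the outgroup.
#' @return list(sites, truth); truth carries `true_lineage` ("A_specific" or
#'   "B_specific"), `true_mechanism` and `true_outgroup`.
#' @export
simulate_lineage_sites <- function(n, mechanism = c("cis", "cis_trans"),
                                   config, bound_strain = "A",
                                   f1_over_f0 = NULL,
                                   background_rate = 0.005,
                                   outgroup_prob = 0.5) {
  mechanism <- match.arg(mechanism)
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, paste0("lineage_", mechanism,
                                           bound_strain)))
  if (is.null(f1_over_f0)) f1_over_f0 <- if (mechanism == "cis") 0.5 else 1
  depth <- config$mean_depth
  mu_bound <- depth
  mu_bg <- depth * background_rate
  total <- depth * f1_over_f0
  bound_frac <- 1 - background_rate  # F1 reads almost all from bound allele

  nf0 <- config$n_f0_reps; nf1 <- config$n_f1_reps
  draw_f0 <- function(mu) sapply(seq_len(nf0), function(j)
    rnb_mixture(n, mu, config$dispersion))
  f0_bound <- draw_f0(mu_bound)
  f0_bg <- draw_f0(mu_bg)
  f1_tot <- sapply(seq_len(nf1), function(j)
    rnb_mixture(n, total, config$dispersion))
  if (n == 1L) {
    f0_bound <- matrix(f0_bound, 1); f0_bg <- matrix(f0_bg, 1)
    f1_tot <- matrix(f1_tot, 1)
  }
  p_a <- if (bound_strain == "A") bound_frac else 1 - bound_frac
  f1_a <- apply(f1_tot, 2, function(nt)
    rbetabin(nt, p_a, config$concentration))
  if (n == 1L) f1_a <- matrix(f1_a, 1)
  f1_b <- f1_tot - f1_a
  if (bound_strain == "A") {
    m <- cbind(f0_bound, f0_bg, f1_a, f1_b)
  } else {
    m <- cbind(f0_bg, f0_bound, f1_a, f1_b)
  }
  colnames(m) <- count_column_names(nf0, nf1)
  sites <- cbind(
    data.frame(site_id = sprintf("lin_%s_%s_%04d", mechanism, bound_strain,
                                 seq_len(n)),
               chrom = "chr1",
               pos = sort(sample.int(config$chrom_length, n)),
               assay = config$assay, stringsAsFactors = FALSE),
    as.data.frame(m)
  )
  truth <- data.frame(
    site_id = sites$site_id,
    true_class = mechanism,
    true_inheritance = NA,
    true_lineage = paste0(bound_strain, "_specific"),
    true_mechanism = mechanism,
    true_outgroup = stats::runif(n) < outgroup_prob,
    stringsAsFactors = FALSE
  )
  list(sites = sites, truth = truth)
}

#' Simulate genes, regulatory intervals and chromatin interactions
#'
#' Places genes with TSS, strand and a true expression regulatory class on
#' the simulated chromosome, generates strain/allele expression summaries
#' from the same count hierarchy, lays down promoter and enhancer intervals
#' around TSSs, simulated classified sites, and chromatin-interaction
#' endpoint pairs. Optionally plants extra cis-class sites in the upstream
#' window of cis-class genes so integration enrichments have a known signal.
#'
#' @param config a [sim_config()] object (`n_genes`, `n_interactions`,
#'   `planted_cis_bonus` are read from it).
#' @return list of class `"genomic_feature_set"` with elements `genes`,
#'   `sites`, `truth`, `promoters`, `enhancers`, `interactions`.
#' @export
simulate_genome_context <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "genome_context"))
  ng <- config$n_genes
  L <- config$chrom_length
  if (ng <= 0) stop("n_genes must be positive")

  tss <- sort(sample.int(L - 60000L, ng) + 30000L)
  strand <- sample(c("+", "-"), ng, replace = TRUE)
  expr_class <- sample(REG_CLASSES, ng, replace = TRUE)

  # strain/allele expression summaries from the same generative family
  expr <- t(vapply(expr_class, function(cl) {
    m <- sim_class_counts(1L, cl, config)
    c(f0_a = mean(m[1, grep("^F0_A", colnames(m))]),
      f0_b = mean(m[1, grep("^F0_B", colnames(m))]),
      f1_a = mean(m[1, grep("^F1_A", colnames(m))]),
      f1_b = mean(m[1, grep("^F1_B", colnames(m))]))
  }, numeric(4)))
  genes <- data.frame(gene_id = sprintf("gene_%04d", seq_len(ng)),
                      chrom = "chr1", tss = tss, strand = strand,
                      expr_class = expr_class,
                      expr_f0_a = expr[, "f0_a"], expr_f0_b = expr[, "f0_b"],
                      expr_f1_a = expr[, "f1_a"], expr_f1_b = expr[, "f1_b"],
                      stringsAsFactors = FALSE)

  sim <- simulate_dataset(config)
  sites <- sim$sites
  truth <- sim$truth

  if (config$planted_cis_bonus > 0) {
    extra <- list(); extra_truth <- list()
    cis_genes <- genes[genes$expr_class == "cis", ]
    k <- 0L
    for (gi in seq_len(nrow(cis_genes))) {
      n_extra <- stats::rpois(1, config$planted_cis_bonus)
      if (n_extra == 0) next
      g <- cis_genes[gi, ]
      lo <- if (g$strand == "+") g$tss - 20000L else g$tss + 1L
      hi <- if (g$strand == "+") g$tss - 1L else g$tss + 20000L
      lo <- max(lo, 1L); hi <- min(hi, L)
      m <- sim_class_counts(n_extra, "cis", config)
      k <- k + 1L
      extra[[k]] <- cbind(
        data.frame(site_id = sprintf("pln_%04d_%02d", gi, seq_len(n_extra)),
                   chrom = "chr1",
                   pos = sample(seq.int(lo, hi), n_extra, replace = TRUE),
                   assay = config$assay, stringsAsFactors = FALSE),
        as.data.frame(m))
      extra_truth[[k]] <- data.frame(
        site_id = extra[[k]]$site_id, true_class = "cis",
        true_inheritance = "additive", true_lineage = "shared",
        true_outgroup = NA, stringsAsFactors = FALSE)
    }
    if (k > 0) {
      sites <- rbind(sites, do.call(rbind, extra))
      truth <- rbind(truth, do.call(rbind, extra_truth))
      o <- order(sites$pos)
      sites <- sites[o, ]; rownames(sites) <- NULL
      truth <- truth[match(sites$site_id, truth$site_id), ]
      rownames(truth) <- NULL
    }
  }

  # promoter intervals around TSSs, enhancer intervals at random offsets
  promoters <- data.frame(chrom = "chr1",
                          start = pmax(genes$tss - 2000L, 0L),
                          end = pmin(genes$tss + 2000L, L),
                          name = paste0("prom_", genes$gene_id),
                          stringsAsFactors = FALSE)
  enh_mid <- sample.int(L - 2000L, ng) + 1000L
  enhancers <- data.frame(chrom = "chr1",
                          start = enh_mid - 1000L, end = enh_mid + 1000L,
                          name = sprintf("enh_%04d", seq_len(ng)),
                          stringsAsFactors = FALSE)

  interactions <- if (config$n_interactions > 0) {
    a <- sample.int(L - 5000L, config$n_interactions)
    b <- sample.int(L - 5000L, config$n_interactions)
    data.frame(chrom1 = "chr1", start1 = a, end1 = a + 5000L,
               chrom2 = "chr1", start2 = b, end2 = b + 5000L,
               stringsAsFactors = FALSE)
  } else {
    data.frame(chrom1 = character(), start1 = integer(), end1 = integer(),
               chrom2 = character(), start2 = integer(), end2 = integer(),
               stringsAsFactors = FALSE)
  }

  out <- list(genes = genes, sites = sites, truth = truth,
              promoters = promoters, enhancers = enhancers,
              interactions = interactions)
  class(out) <- "genomic_feature_set"
  out
}

#' Simulate a coordination landscape of shared cis effects
#'
#' Anchor sites carry a latent allelic shift; neighbouring sites inherit the
#' shift attenuated by `exp(-distance / decay_scale)` plus independent
#' noise, so the Spearman correlation of allelic proportions between anchors
#' and their neighbours decays with genomic distance at a known scale.
#' Anchors are spaced far enough apart that their neighbourhoods never
#' overlap.
#'
#' @param decay_scale e-folding distance of the shared shift, in bp
#'   (`Inf` = perfect sharing; `0` = independence).
#' @param n_anchors number of anchor sites.
#' @param config a [sim_config()] object.
#' @param n_partners sites placed around each anchor.
#' @param max_distance largest anchor-partner distance, bp.
#' @param shift_range half-width of the uniform latent shift on the allelic
#'   fraction.
#' @param noise_sd SD of independent per-site noise on the allelic fraction.
#' @return list(sites, anchor_ids, decay_scale); `sites` carries an
#'   `is_anchor` column and every anchor is labelled class `cis`.
#' @export
simulate_coordination_landscape <- function(decay_scale, n_anchors, config,
                                            n_partners = 60,
                                            max_distance = 4e5,
                                            shift_range = 0.35,
                                            noise_sd = 0.02) {
  stopifnot(decay_scale >= 0, n_anchors > 0)
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "coordination"))
  spacing <- 2 * max_distance + 10000
  anchor_pos <- as.integer(seq_len(n_anchors) * spacing)
  shifts <- stats::runif(n_anchors, -shift_range, shift_range)

  rows <- vector("list", n_anchors)
  for (a in seq_len(n_anchors)) {
    d <- stats::runif(n_partners, 400, max_distance)
    side <- sample(c(-1, 1), n_partners, replace = TRUE)
    pos <- as.integer(round(anchor_pos[a] + side * d))
    att <- if (is.infinite(decay_scale)) rep(1, n_partners)
           else if (decay_scale == 0) rep(0, n_partners)
           else exp(-d / decay_scale)
    p_partner <- 0.5 + shifts[a] * att +
      stats::rnorm(n_partners, 0, noise_sd)
    p_anchor <- 0.5 + shifts[a] + stats::rnorm(1, 0, noise_sd / 4)
    p_all <- pmin(pmax(c(p_anchor, p_partner), 0.02), 0.98)
    pos_all <- c(anchor_pos[a], pos)
    n_all <- n_partners + 1L

    nf0 <- config$n_f0_reps; nf1 <- config$n_f1_reps
    odds <- p_all / (1 - p_all)
    mu_a <- config$mean_depth * sqrt(odds)
    mu_b <- config$mean_depth / sqrt(odds)
    f0_a <- sapply(seq_len(nf0), function(j)
      rnb_mixture(n_all, mu_a, config$dispersion))
    f0_b <- sapply(seq_len(nf0), function(j)
      rnb_mixture(n_all, mu_b, config$dispersion))
    f1_tot <- sapply(seq_len(nf1), function(j)
      rnb_mixture(n_all, config$mean_depth * config$f1_depth_ratio,
                  config$dispersion))
    f1_a <- matrix(rbetabin(as.vector(f1_tot),
                            rep(p_all, nf1), config$concentration),
                   nrow = n_all)
    f1_b <- f1_tot - f1_a
    m <- cbind(f0_a, f0_b, f1_a, f1_b)
    colnames(m) <- count_column_names(nf0, nf1)
    rows[[a]] <- cbind(
      data.frame(site_id = sprintf("coord_a%03d_s%03d", a,
                                   seq_len(n_all) - 1L),
                 chrom = "chr1", pos = pos_all, assay = config$assay,
                 is_anchor = c(TRUE, rep(FALSE, n_partners)),
                 stringsAsFactors = FALSE),
      as.data.frame(m))
  }
  sites <- do.call(rbind, rows)
  rownames(sites) <- NULL
  list(sites = sites,
       anchor_ids = sites$site_id[sites$is_anchor],
       decay_scale = decay_scale)
}
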