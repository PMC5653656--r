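## End-to-end orchestration: simulate or load inputs, then run
## preprocess -> classify -> {inheritance, lineage} -> coordination ->
## integrate, collecting per-stage tables into a report bundle.

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order on a site table (and optional
#' genomic context), returning every stage's result table plus run
#' metadata. The pipeline is a pure function of (inputs, config, seed):
#' re-running with identical inputs gives identical outputs.
#'
#' @param sites raw site table (see [read_site_table()]).
#' @param context optional `"genomic_feature_set"` (genes, promoters,
#'   enhancers, interactions) as from [simulate_genome_context()].
#' @param stages character vector of enabled stages, a subset of
#'   `c("preprocess", "classify", "inheritance", "lineage", "coordination",
#'   "integrate")`. Later stages require earlier ones.
#' @param seed integer seed for the resampling stages.
#' @param outgroup optional outgroup presence table for the lineage stage.
#' @param min_f0,min_f1_reps,min_f1_reads,min_spacing preprocess settings.
#' @param n_resamples null resamples for the coordination stage.
#' @param verbose log stage progress and filter attrition.
#' @return list of class `"report_bundle"`: per-stage tables and `meta`
#'   (seed, stage list, n sites in/out, package version).
#' @export
run_pipeline <- function(sites, context = NULL,
                         stages = c("preprocess", "classify", "inheritance",
                                    "lineage", "coordination", "integrate"),
                         seed = 1, outgroup = NULL, min_f0 = 10,
                         min_f1_reps = 10, min_f1_reads = 10,
                         min_spacing = 250, n_resamples = 100,
                         verbose = TRUE) {
  all_stages <- c("preprocess", "classify", "inheritance", "lineage",
                  "coordination", "integrate")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  deps <- list(classify = "preprocess", inheritance = "classify",
               lineage = "classify", coordination = "classify",
               integrate = "classify")
  for (st in stages) {
    need <- deps[[st]]
    if (!is.null(need) && !all(need %in% stages)) {
      stop("stage '", st, "' requires stage '", need, "'")
    }
  }
  bundle <- list(meta = list(seed = seed, stages = stages,
                             n_sites_in = nrow(sites),
                             package_version =
                               as.character(utils::packageVersion("hybridreg"))))

  if ("preprocess" %in% stages) {
    if (verbose) message("[stage] preprocess")
    pp <- preprocess_sites(sites, min_f0 = min_f0,
                           min_f1_reps = min_f1_reps,
                           min_f1_reads = min_f1_reads,
                           min_spacing = min_spacing, verbose = verbose)
    bundle$normalized <- pp$sites
    bundle$size_factors <- data.frame(
      library = names(pp$size_factors$factors),
      factor = unname(pp$size_factors$factors), stringsAsFactors = FALSE)
    bundle$dispersion <- pp$dispersion$table
    bundle$meta$n_sites_filtered <- nrow(pp$sites)
    disp <- pp$dispersion
  }

  if ("classify" %in% stages) {
    if (verbose) message("[stage] classify")
    bundle$calls <- classify_sites(bundle$normalized, disp)
    bundle$ratio_diagnostic <-
      ratio_difference_diagnostic(bundle$normalized, bundle$calls)
  }

  if ("inheritance" %in% stages) {
    if (verbose) message("[stage] inheritance")
    bundle$inheritance <- assign_inheritance(bundle$normalized,
                                             bundle$calls, disp)
  }

  if ("lineage" %in% stages) {
    if (verbose) message("[stage] lineage")
    bundle$lineage <- assign_lineage(bundle$normalized, bundle$calls, disp,
                                     outgroup = outgroup)
  }

  if ("coordination" %in% stages) {
    if (verbose) message("[stage] coordination")
    cls <- bundle$calls$class[match(bundle$normalized$site_id,
                                    bundle$calls$site_id)]
    anchors <- bundle$normalized[cls == "cis", , drop = FALSE]
    if (nrow(anchors) >= 2) {
      prof <- correlation_profile(anchors, bundle$normalized)
      bundle$coordination <- prof$bins
      bundle$coordination_null <- null_profile(prof, bundle$normalized,
                                               n_resamples = n_resamples,
                                               seed = seed)
      if (sum(!is.na(prof$bins$rho)) >= 3) {
        dec <- fit_log_decay(prof)
        elb <- find_elbow(dec)
        bundle$decay <- data.frame(slope = dec$slope,
                                   intercept = dec$intercept,
                                   slope_ci_lower = dec$slope_ci[["lower"]],
                                   slope_ci_upper = dec$slope_ci[["upper"]],
                                   elbow_bp = elb$elbow)
      }
    } else if (verbose) {
      message("[stage] coordination skipped: < 2 cis anchors")
    }
  }

  if ("integrate" %in% stages && !is.null(context)) {
    if (verbose) message("[stage] integrate")
    sites_cls <- bundle$normalized
    sites_cls$class <- bundle$calls$class[
      match(sites_cls$site_id, bundle$calls$site_id)]
    sites_cls <- sites_cls[sites_cls$class %in% REG_CLASSES, , drop = FALSE]
    genes <- context$genes
    tab <- assign_sites_to_genes(sites_cls, genes)
    tab$response_class <- genes$expr_class[match(tab$gene_id,
                                                 genes$gene_id)]
    tab$expr_class <- tab$response_class
    bundle$gene_site_counts <- tab
    bundle$enrichment <- tryCatch(enrichment_by_class(tab),
                                  error = function(e) NULL)
    bundle$diversity <- diversity_by_expression_class(tab)$per_gene
    bundle$cis_extent_sites <- cis_extent_correlation(sites_cls)
    bundle$cis_extent_genes <- tryCatch(cis_extent_correlation(genes),
                                        error = function(e) NULL)
    bundle$magnitude <- compare_cis_effect_magnitude(sites_cls, genes,
                                                     seed = seed)
    if (!is.null(context$interactions) &&
        nrow(context$interactions) > 0) {
      ep <- S4Vectors::Pairs(
        GenomicRanges::GRanges(context$interactions$chrom1,
          IRanges::IRanges(context$interactions$start1 + 1L,
                           context$interactions$end1)),
        GenomicRanges::GRanges(context$interactions$chrom2,
          IRanges::IRanges(context$interactions$start2 + 1L,
                           context$interactions$end2)))
      bundle$contact_enrichment <- contact_enrichment(sites_cls, ep)
    }
  }

  class(bundle) <- "report_bundle"
  bundle
}

#' Write a report bundle to disk
#'
#' Each table becomes `<name>.tsv`; run metadata and a content hash of
#' every table go to `report.json`.
#'
#' @param bundle a `"report_bundle"`.
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of per-table content hashes.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hashes <- list()
  for (nm in setdiff(names(bundle), "meta")) {
    x <- bundle[[nm]]
    if (!is.data.frame(x)) next
    # stable numeric formatting so hashes are platform-reproducible
    xx <- x
    num <- vapply(xx, is.numeric, logical(1))
    xx[num] <- lapply(xx[num], function(v) formatC(v, digits = 10,
                                                   format = "g"))
    path <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(xx, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    hashes[[nm]] <- table_hash(xx)
  }
  meta <- bundle$meta
  meta$table_hashes <- hashes
  jsonlite::write_json(meta, file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(unlist(hashes))
}

## Deterministic content hash of a data frame (no external digest
## dependency): DJB2 over the serialized text.
table_hash <- function(x) {
  txt <- paste(utils::capture.output(utils::write.table(x, sep = "\t",
    quote = FALSE, row.names = FALSE)), collapse = "\n")
  h <- 5381
  for (v in utf8ToInt(txt)) h <- (h * 33 + v) %% 2147483647
  sprintf("%08x", h)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; recognized top-level keys: `sim` (arguments to
#'   [sim_config()]), `stages`, `seed`, and preprocess settings.
#' @return named list.
#' @export
read_pipeline_config <- function(path) {
  yaml::read_yaml(path)
}
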