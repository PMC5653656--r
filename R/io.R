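## Site-table and interval I/O shared by every stage.
##
## The site table is a TSV with columns site_id, chrom, pos (1-based SNV
## coordinate), assay, then one column per library: F0_A_rep*, F0_B_rep*,
## F1_A_rep*, F1_B_rep*. Intervals are BED (0-based half-open), interactions
## BEDPE. Internally all interval arithmetic is done on GRanges.

#' Extract a per-library count matrix from a site table
#'
#' @param sites site-table `data.frame`.
#' @param group one of `"F0_A"`, `"F0_B"`, `"F1_A"`, `"F1_B"`.
#' @return numeric matrix, one row per site, one column per replicate.
#' @export
count_matrix <- function(sites, group = c("F0_A", "F0_B", "F1_A", "F1_B")) {
  group <- match.arg(group)
  cols <- grep(paste0("^", group, "_rep"), colnames(sites), value = TRUE)
  if (length(cols) == 0) stop("no ", group, " columns in site table")
  m <- as.matrix(sites[, cols, drop = FALSE])
  rownames(m) <- sites$site_id
  m
}

## All count columns of a site table, in layout order.
count_columns <- function(sites) {
  grep("^F[01]_[AB]_rep", colnames(sites), value = TRUE)
}

#' Read a site table from TSV
#'
#' Validates column presence, count non-negativity and site_id uniqueness;
#' malformed rows are reported with their line numbers.
#'
#' @param path path to a TSV file with the documented header.
#' @return validated site-table `data.frame`.
#' @export
read_site_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  validate_site_table(tab, context = path)
  tab
}

#' Write a site table to TSV
#' @param sites site-table `data.frame`.
#' @param path output path.
#' @export
write_site_table <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_site_table <- function(tab, context = "site table") {
  need <- c("site_id", "chrom", "pos", "assay")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) {
    stop(context, ": missing columns: ", paste(miss, collapse = ", "))
  }
  cc <- count_columns(tab)
  if (length(cc) == 0) stop(context, ": no count columns (F0_*/F1_*_rep*)")
  cm <- as.matrix(tab[, cc, drop = FALSE])
  bad <- which(rowSums(cm < 0 | !is.finite(cm)) > 0)
  if (length(bad)) {
    stop(context, ": negative or non-finite counts in rows (excluding ",
         "header): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  dup <- tab$site_id[duplicated(tab$site_id)]
  if (length(dup)) {
    stop(context, ": duplicate site_id: ",
         paste(utils::head(unique(dup), 5), collapse = ", "))
  }
  if (any(tab$pos < 1)) stop(context, ": pos must be >= 1 (1-based)")
  invisible(tab)
}

#' Read genomic intervals (BED) or interaction endpoints (BEDPE)
#'
#' BED files are parsed with rtracklayer (0-based half-open on disk,
#' 1-based closed as GRanges). BEDPE files are read as two linked GRanges.
#'
#' @param path file path.
#' @param kind `"intervals"` (BED) or `"interactions"` (BEDPE).
#' @return For `"intervals"`, a sorted `GRanges`; for `"interactions"`, a
#'   `S4Vectors::Pairs` of two `GRanges` of equal length.
#' @export
read_intervals <- function(path, kind = c("intervals", "interactions")) {
  kind <- match.arg(kind)
  if (kind == "intervals") {
    gr <- rtracklayer::import(path, format = "BED")
    return(GenomicRanges::sort(gr))
  }
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 6) stop("BEDPE requires >= 6 columns")
  if (any(tab[[3]] <= tab[[2]]) || any(tab[[6]] <= tab[[5]])) {
    stop("BEDPE interval with end <= start")
  }
  first <- GenomicRanges::GRanges(tab[[1]],
             IRanges::IRanges(tab[[2]] + 1L, tab[[3]]))
  second <- GenomicRanges::GRanges(tab[[4]],
              IRanges::IRanges(tab[[5]] + 1L, tab[[6]]))
  S4Vectors::Pairs(first, second)
}

#' Write intervals to BED / interactions to BEDPE
#' @param x `data.frame` with chrom/start/end (BED, 0-based half-open) or
#'   chrom1/start1/end1/chrom2/start2/end2 (BEDPE).
#' @param path output path.
#' @export
write_intervals <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## Site positions as a point GRanges (1-based SNV coordinates).
sites_as_granges <- function(sites, width = 1L) {
  half <- (width - 1L) %/% 2L
  GenomicRanges::GRanges(sites$chrom,
    IRanges::IRanges(pmax(sites$pos - half, 1L), sites$pos + half),
    site_id = sites$site_id)
}

#' Per-site F0 minus F1 ratio diagnostic
#'
#' For each classified site, the strain-A proportion among F0 means minus
#' the strain-A allelic proportion among F1 allele means. Near zero for cis
#' and conserved sites; appreciably non-zero for trans and cis-trans sites
#' on well-powered data.
#'
#' @param sites site table (normalized or raw).
#' @param calls optional calls `data.frame` with site_id and class; classes
#'   are joined onto the result when given.
#' @return `data.frame`: site_id, f0_ratio, f1_ratio, ratio_difference
#'   (and class when `calls` is supplied). Sites with a zero F0 or F1 total
#'   are dropped with a message.
#' @export
ratio_difference_diagnostic <- function(sites, calls = NULL) {
  a0 <- rowMeans(count_matrix(sites, "F0_A"))
  b0 <- rowMeans(count_matrix(sites, "F0_B"))
  a1 <- rowMeans(count_matrix(sites, "F1_A"))
  b1 <- rowMeans(count_matrix(sites, "F1_B"))
  ok <- (a0 + b0) > 0 & (a1 + b1) > 0
  if (any(!ok)) {
    message(sum(!ok), " site(s) with zero F0 or F1 total excluded ",
            "from ratio diagnostic")
  }
  out <- data.frame(
    site_id = sites$site_id[ok],
    f0_ratio = (a0 / (a0 + b0))[ok],
    f1_ratio = (a1 / (a1 + b1))[ok],
    stringsAsFactors = FALSE
  )
  out$ratio_difference <- out$f0_ratio - out$f1_ratio
  if (!is.null(calls)) {
    out$class <- calls$class[match(out$site_id, calls$site_id)]
  }
  out
}

## Filter-attrition logging used by the preprocess stage.
log_filter <- function(rule, n_in, n_out, verbose = TRUE) {
  if (verbose) {
    message(sprintf("[filter] %s: %d -> %d sites", rule, n_in, n_out))
  }
  invisible(data.frame(rule = rule, n_in = n_in, n_out = n_out,
                       stringsAsFactors = FALSE))
}
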