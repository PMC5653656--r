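## Inheritance-mode assignment for total occupancy at non-conserved sites.
##
## Parents are ordered by median replicate intensity into a high (pmax) and
## low (pmin) parent. Three NB models (size r) describe the count blocks
## x_max, x_min (F0) and y (F1 per-replicate totals, allele A + allele B):
##
##   free      : three means S_pmax, S_pmin, S_o              (k = 3)
##   S_o=S_pmax: shared mean for the high parent and offspring (k = 2)
##   S_o=S_pmin: shared mean for the low parent and offspring  (k = 2)
##
## The dominant and free (additive) models are compared by BIC separately
## for each parent: equality winning for exactly one parent gives a
## dominant call for that parent; for neither, additive; for both, the
## offspring is indistinguishable from both parents and the site is
## excluded. Sites whose parents are separated by less than
## max(2 * SE of the mean difference, `min_separation`) normalized counts
## are excluded up front, as are sites with an exact parental median tie.

## BICs of the three inheritance models for count blocks (xmax, xmin, y).
inheritance_model_bics <- function(xmax, xmin, y, r) {
  n_obs <- length(xmax) + length(xmin) + length(y)
  ll <- function(v, m) nb_loglik_mean(v, r, max(m, 1e-6))
  m_max <- mean(xmax); m_min <- mean(xmin); m_o <- mean(y)
  ll_free <- ll(xmax, m_max) + ll(xmin, m_min) + ll(y, m_o)
  m_sh_max <- mean(c(xmax, y))
  ll_dom_max <- ll(xmax, m_sh_max) + ll(xmin, m_min) + ll(y, m_sh_max)
  m_sh_min <- mean(c(xmin, y))
  ll_dom_min <- ll(xmax, m_max) + ll(xmin, m_sh_min) + ll(y, m_sh_min)
  list(
    bic_free = bic(ll_free, 3, n_obs),
    bic_dom_max = bic(ll_dom_max, 2, n_obs),
    bic_dom_min = bic(ll_dom_min, 2, n_obs),
    s_pmax = m_max, s_pmin = m_min, s_o = m_o
  )
}

#' Assign the inheritance mode of one site
#'
#' @param site one-row site-table `data.frame` (normalized counts).
#' @param r NB size (reciprocal dispersion) for this site.
#' @param min_separation minimum parental mean difference in normalized
#'   counts (the absolute floor of the separation filter).
#' @return list of class `"inheritance_call"`: `site_id`, `mode`, parameter
#'   estimates `s_pmax`, `s_pmin`, `s_o`, the model BICs and the separation
#'   statistics.
#' @export
fit_inheritance <- function(site, r, min_separation = 19) {
  stopifnot(nrow(site) == 1, is.finite(r), r > 0)
  a <- round(as.numeric(count_matrix(site, "F0_A")))
  b <- round(as.numeric(count_matrix(site, "F0_B")))
  za <- round(as.numeric(count_matrix(site, "F1_A")))
  zb <- round(as.numeric(count_matrix(site, "F1_B")))
  y <- za + zb

  res <- list(site_id = site$site_id, mode = NA_character_,
              s_pmax = NA_real_, s_pmin = NA_real_, s_o = mean(y),
              separation = abs(mean(a) - mean(b)),
              separation_threshold = NA_real_,
              bic_free = NA_real_, bic_dom_max = NA_real_,
              bic_dom_min = NA_real_)
  class(res) <- "inheritance_call"

  if (stats::median(a) == stats::median(b)) {
    res$mode <- "excluded_equal_parents"
    return(res)
  }
  # separation filter: parental mean difference must exceed twice the
  # standard error of that difference, and an absolute count floor
  se_diff <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
  thr <- max(2 * se_diff, min_separation)
  res$separation_threshold <- thr
  if (res$separation < thr) {
    res$mode <- "excluded_low_separation"
    return(res)
  }

  if (stats::median(a) > stats::median(b)) {
    xmax <- a; xmin <- b
  } else {
    xmax <- b; xmin <- a
  }
  fit <- inheritance_model_bics(xmax, xmin, y, r)
  res[c("s_pmax", "s_pmin", "s_o")] <- fit[c("s_pmax", "s_pmin", "s_o")]
  res[c("bic_free", "bic_dom_max", "bic_dom_min")] <-
    fit[c("bic_free", "bic_dom_max", "bic_dom_min")]

  eq_max <- fit$bic_dom_max <= fit$bic_free
  eq_min <- fit$bic_dom_min <= fit$bic_free
  res$mode <- if (eq_max && eq_min) {
    "excluded_equal_parents"
  } else if (eq_max) {
    "dominant_high_parent"
  } else if (eq_min) {
    "dominant_low_parent"
  } else {
    "additive"
  }
  res
}

#' Over/under-dominance of one site
#'
#' For sites whose offspring mean is distinguishable from both parents
#' (both equality-constrained models rejected by BIC), classifies the site
#' as over-dominant when the mean F1 total exceeds both parental means,
#' under-dominant when it falls below both, and neither otherwise. Callers
#' should restrict input to sites with a confident regulatory call
#' (delta-BIC > 1).
#'
#' @param site one-row site-table `data.frame` (normalized counts).
#' @param r NB size for this site.
#' @return one of `"overdominant"`, `"underdominant"`, `"neither"`, or
#'   `"not_applicable"` when an equality model fits one of the parents.
#' @export
classify_overdominance <- function(site, r) {
  a <- round(as.numeric(count_matrix(site, "F0_A")))
  b <- round(as.numeric(count_matrix(site, "F0_B")))
  y <- round(as.numeric(count_matrix(site, "F1_A"))) +
    round(as.numeric(count_matrix(site, "F1_B")))
  if (stats::median(a) >= stats::median(b)) {
    xmax <- a; xmin <- b
  } else {
    xmax <- b; xmin <- a
  }
  fit <- inheritance_model_bics(xmax, xmin, y, r)
  if (fit$bic_dom_max <= fit$bic_free || fit$bic_dom_min <= fit$bic_free) {
    return("not_applicable")
  }
  m_o <- mean(y)
  if (m_o > max(mean(a), mean(b))) return("overdominant")
  if (m_o < min(mean(a), mean(b))) return("underdominant")
  "neither"
}

#' Inheritance calls for a table of classified sites
#'
#' Applies [fit_inheritance()] to every non-conserved site (per the
#' upstream regulatory call) and [classify_overdominance()] to additive
#' sites with a confident call.
#'
#' @param sites normalized site table.
#' @param calls regulatory calls from [classify_sites()].
#' @param dispersion_model a `"dispersion_model"` or single numeric `r`.
#' @param min_separation separation floor in normalized counts.
#' @param classes regulatory classes eligible for inheritance analysis.
#' @param min_delta_bic confidence cut on the regulatory call used for the
#'   over/under-dominance screen.
#' @return `data.frame`: site_id, class, mode, s_pmax, s_pmin, s_o,
#'   separation, model BICs, overdominance.
#' @export
assign_inheritance <- function(sites, calls, dispersion_model,
                               min_separation = 19,
                               classes = c("cis", "trans"),
                               min_delta_bic = 1) {
  cls <- calls$class[match(sites$site_id, calls$site_id)]
  dbic <- calls$delta_bic[match(sites$site_id, calls$site_id)]
  idx <- which(cls %in% classes)
  rows <- lapply(idx, function(i) {
    r <- if (is.numeric(dispersion_model)) dispersion_model else {
      dispersion_model$table$r[
        match(sites$site_id[i], dispersion_model$table$site_id)]
    }
    site <- sites[i, , drop = FALSE]
    ic <- fit_inheritance(site, r, min_separation)
    od <- if (!is.na(dbic[i]) && dbic[i] > min_delta_bic &&
              ic$mode == "additive") {
      classify_overdominance(site, r)
    } else NA_character_
    data.frame(site_id = ic$site_id, class = cls[i], mode = ic$mode,
               s_pmax = ic$s_pmax, s_pmin = ic$s_pmin, s_o = ic$s_o,
               separation = ic$separation,
               separation_threshold = ic$separation_threshold,
               bic_free = ic$bic_free, bic_dom_max = ic$bic_dom_max,
               bic_dom_min = ic$bic_dom_min, overdominance = od,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(site_id = character(), class = character(),
                      mode = character(), s_pmax = numeric(),
                      s_pmin = numeric(), s_o = numeric(),
                      separation = numeric(),
                      separation_threshold = numeric(),
                      bic_free = numeric(), bic_dom_max = numeric(),
                      bic_dom_min = numeric(),
                      overdominance = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
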