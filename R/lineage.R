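## Lineage-specific sites: cis vs cis-trans mechanism, compensatory vs
## diversifying trans effects, and apomorphic vs plesiomorphic status.

#' Flag lineage-specific sites
#'
#' A site is strain-specific when the strain-A share of the mean occupancy
#' is extreme in both generations:
#' `(ratio_F0 < lo and ratio_F1 < lo)` or `(ratio_F0 > hi and
#' ratio_F1 > hi)`, with ratios computed on means across replicates
#' (F1 ratios on allele means).
#'
#' @param site one-row site-table `data.frame` (normalized counts).
#' @param lo,hi ratio cutoffs (defaults 0.05 / 0.95).
#' @return `"A_specific"`, `"B_specific"` or `"shared"`; `NA` (with a
#'   message) when both generations have zero totals.
#' @export
call_lineage_specific <- function(site, lo = 0.05, hi = 0.95) {
  a0 <- mean(as.numeric(count_matrix(site, "F0_A")))
  b0 <- mean(as.numeric(count_matrix(site, "F0_B")))
  a1 <- mean(as.numeric(count_matrix(site, "F1_A")))
  b1 <- mean(as.numeric(count_matrix(site, "F1_B")))
  if (a0 + b0 == 0 && a1 + b1 == 0) {
    message("site ", site$site_id, ": zero totals, lineage flag undefined")
    return(NA_character_)
  }
  if (a0 + b0 == 0 || a1 + b1 == 0) return("shared")
  r0 <- a0 / (a0 + b0)
  r1 <- a1 / (a1 + b1)
  if (r0 > hi && r1 > hi) return("A_specific")
  if (r0 < lo && r1 < lo) return("B_specific")
  "shared"
}

#' Cis vs cis-trans mechanism at a lineage-specific site
#'
#' A purely cis-driven strain-specific site carries one bound allele in the
#' diploid F1, so its F1 total is expected at half the bound parent's F0
#' level. Doubled F1 totals `2 y_j` are fitted against the bound strain's
#' F0 counts `x_i` under NB models with a shared mean (cis, 1 parameter)
#' versus free means (cis-trans, 2 parameters); BIC selects, ties toward
#' the simpler cis model, so an exact 2:1 site is always called cis.
#'
#' @param site one-row site-table `data.frame` (normalized counts).
#' @param r NB size for this site.
#' @param lineage the site's lineage flag (`"A_specific"`/`"B_specific"`);
#'   computed with [call_lineage_specific()] when missing.
#' @return list of class `"lineage_call"`: `site_id`, `lineage`,
#'   `mechanism` (`"cis"` or `"cis_trans"`), `s_pmax`, `s_o`, `delta_bic`.
#' @export
fit_lineage_models <- function(site, r, lineage = NULL) {
  stopifnot(nrow(site) == 1, is.finite(r), r > 0)
  if (is.null(lineage)) lineage <- call_lineage_specific(site)
  if (is.na(lineage) || lineage == "shared") {
    stop("fit_lineage_models requires a lineage-specific site")
  }
  x <- if (lineage == "A_specific") {
    round(as.numeric(count_matrix(site, "F0_A")))
  } else {
    round(as.numeric(count_matrix(site, "F0_B")))
  }
  y <- round(as.numeric(count_matrix(site, "F1_A"))) +
    round(as.numeric(count_matrix(site, "F1_B")))
  y2 <- 2 * y
  n_obs <- length(x) + length(y2)

  m_x <- max(mean(x), 1e-6)
  m_o <- max(mean(y2), 1e-6)
  m_sh <- max(mean(c(x, y2)), 1e-6)
  ll_cis <- nb_loglik_mean(x, r, m_sh) + nb_loglik_mean(y2, r, m_sh)
  ll_ct <- nb_loglik_mean(x, r, m_x) + nb_loglik_mean(y2, r, m_o)
  bic_cis <- bic(ll_cis, 1, n_obs)
  bic_ct <- bic(ll_ct, 2, n_obs)
  mech <- if (bic_cis <= bic_ct) "cis" else "cis_trans"
  out <- list(site_id = site$site_id, lineage = lineage, mechanism = mech,
              s_pmax = if (mech == "cis") m_sh else m_x,
              s_o = if (mech == "cis") m_sh else m_o,
              delta_bic = abs(bic_ct - bic_cis),
              bic_cis = bic_cis, bic_cis_trans = bic_ct)
  class(out) <- "lineage_call"
  out
}

#' Compensatory vs diversifying trans effects
#'
#' At cis-trans sites bound on both alleles, the trans component either
#' shrinks the parental difference in the hybrid (compensatory: |log2 F1
#' allelic ratio| < |log2 F0 ratio|) or amplifies it (diversifying). Exact
#' ties are excluded. A pseudocount of 0.5 is applied to zero means.
#'
#' @param site one-row site-table `data.frame` (normalized counts).
#' @return `"compensatory"`, `"diversifying"` or `"tie_excluded"`.
#' @export
classify_compensatory <- function(site) {
  pc <- function(v) if (v == 0) 0.5 else v
  a0 <- pc(mean(as.numeric(count_matrix(site, "F0_A"))))
  b0 <- pc(mean(as.numeric(count_matrix(site, "F0_B"))))
  a1 <- pc(mean(as.numeric(count_matrix(site, "F1_A"))))
  b1 <- pc(mean(as.numeric(count_matrix(site, "F1_B"))))
  d0 <- abs(log2(a0 / b0))
  d1 <- abs(log2(a1 / b1))
  if (d1 < d0) return("compensatory")
  if (d1 > d0) return("diversifying")
  "tie_excluded"
}

#' Apomorphic vs plesiomorphic status of a lineage-specific site
#'
#' Parsimony over the two ingroup strains and one outgroup: a site bound in
#' exactly one ingroup lineage is a lineage-specific gain (apomorphic) when
#' absent from the outgroup, and a loss in the unbound lineage
#' (plesiomorphic) when the outgroup shares it.
#'
#' @param site one-row site-table `data.frame`, or any object with a
#'   lineage flag supplied via `lineage`.
#' @param outgroup_present logical: is the site bound in the outgroup?
#' @param lineage the site's lineage flag; computed when missing.
#' @return `"apomorphic"`, `"plesiomorphic"` or `"unresolved"`.
#' @export
classify_apomorphy <- function(site, outgroup_present, lineage = NULL) {
  if (is.null(lineage)) lineage <- call_lineage_specific(site)
  if (is.na(lineage) || lineage == "shared") {
    warning("apomorphy is defined only for lineage-specific sites")
    return("unresolved")
  }
  if (is.na(outgroup_present)) return("unresolved")
  if (outgroup_present) "plesiomorphic" else "apomorphic"
}

#' Exact binomial balance test of compensatory vs diversifying labels
#'
#' @param labels character vector of `"compensatory"` / `"diversifying"`
#'   (other values are ignored).
#' @return `data.frame`: n, n_compensatory, proportion, p_value (two-sided
#'   exact binomial against 0.5).
#' @export
compensatory_balance_test <- function(labels) {
  labels <- labels[labels %in% c("compensatory", "diversifying")]
  if (length(labels) == 0) stop("no compensatory/diversifying labels")
  k <- sum(labels == "compensatory")
  n <- length(labels)
  p <- stats::binom.test(k, n, p = 0.5)$p.value
  data.frame(n = n, n_compensatory = k, proportion = k / n, p_value = p)
}

#' Lineage analysis for a table of classified sites
#'
#' Flags lineage-specific sites, fits the cis vs cis-trans models at them,
#' labels compensatory/diversifying status at shared cis-trans sites, and
#' resolves apomorphy where an outgroup presence flag is available.
#'
#' @param sites normalized site table.
#' @param calls regulatory calls from [classify_sites()].
#' @param dispersion_model a `"dispersion_model"` or single numeric `r`.
#' @param outgroup optional `data.frame` (site_id, outgroup_present).
#' @return `data.frame`: site_id, lineage, mechanism, delta_bic,
#'   compensatory, apomorphy.
#' @export
assign_lineage <- function(sites, calls, dispersion_model,
                           outgroup = NULL) {
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    site <- sites[i, , drop = FALSE]
    lin <- call_lineage_specific(site)
    cls <- calls$class[match(site$site_id, calls$site_id)]
    mech <- NA_character_; dbic <- NA_real_
    comp <- NA_character_; apo <- NA_character_
    if (!is.na(lin) && lin != "shared") {
      r <- if (is.numeric(dispersion_model)) dispersion_model else {
        dispersion_model$table$r[
          match(site$site_id, dispersion_model$table$site_id)]
      }
      fit <- try(fit_lineage_models(site, r, lineage = lin), silent = TRUE)
      if (!inherits(fit, "try-error")) {
        mech <- fit$mechanism; dbic <- fit$delta_bic
      } else {
        mech <- "unresolved"
      }
      og <- if (!is.null(outgroup)) {
        outgroup$outgroup_present[match(site$site_id, outgroup$site_id)]
      } else NA
      apo <- classify_apomorphy(site, og, lineage = lin)
    } else if (!is.na(lin) && lin == "shared" &&
               !is.na(cls) && cls == "cis_trans") {
      comp <- classify_compensatory(site)
    }
    data.frame(site_id = site$site_id, lineage = lin, mechanism = mech,
               delta_bic = dbic, compensatory = comp, apomorphy = apo,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
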