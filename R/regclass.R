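## Four-model regulatory classification of allele-specific sites.
##
## Each site contributes three count blocks: F0 strain-A replicates x_i and
## strain-B replicates y_i (negative binomial with size r and means tied to
## p_mu, p_nu), and F1 allele-A counts z_j out of totals n_j (beta-binomial
## with mean m_b and concentration c). The four regulatory scenarios
## constrain these parameters:
##
##   conserved: p_mu = p_nu, m_b = 1/2            (k = 2: shared p, c)
##   cis:       m_b = odds(p_mu)/(odds(p_mu)+odds(p_nu))  (k = 3)
##   trans:     m_b = 1/2                          (k = 3)
##   cis-trans: all free                           (k = 4)
##
## For a fixed NB size the mean MLE is the sample mean, so the conserved,
## trans and cis-trans fits reduce to closed-form NB parts plus a 1- or 2-D
## beta-binomial optimization; only the cis fit couples the blocks and needs
## a 3-D search. The cis beta mean equals mu/(mu+nu) of the F0 means because
## NB means are proportional to the success odds.

REG_MODEL_K <- c(conserved = 2, cis = 3, trans = 3, cis_trans = 4)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Round real-valued normalized counts for discrete likelihoods; F1 totals
## are recomputed as the sum of the rounded allele counts.
round_site_counts <- function(x, y, z, n) {
  z <- round(z); b <- round(n - z)
  list(x = round(x), y = round(y), z = z, n = z + b)
}

## Fit all four constrained models to one site's count blocks.
## Returns a list of per-model fits plus the selected class.
fit_site_models <- function(x, y, z, n, r, reltol = 1e-10) {
  n_obs <- length(x) + length(y) + length(z)
  keep <- n > 0
  zk <- z[keep]; nk <- n[keep]
  has_f1 <- length(nk) > 0

  bb <- function(mean_, conc) {
    if (!has_f1) return(0)
    betabin_loglik(zk, nk, mean_, conc)
  }
  mx <- max(mean(x), 1e-6)
  my <- max(mean(y), 1e-6)
  m0 <- max(mean(c(x, y)), 1e-6)

  # conserved: shared NB mean, beta mean 1/2, concentration free
  bb_half <- if (has_f1) bb_fit_concentration(zk, nk, 0.5)
             else list(concentration = NA_real_, loglik = 0)
  ll_cons <- nb_loglik_mean(x, r, m0) + nb_loglik_mean(y, r, m0) +
    bb_half$loglik
  fit_cons <- list(loglik = ll_cons, p_mu = m0 / (r + m0),
                   p_nu = m0 / (r + m0), beta_mean = 0.5,
                   concentration = bb_half$concentration)

  # trans: free NB means, beta mean 1/2 (same beta-binomial part)
  ll_nb_free <- nb_loglik_mean(x, r, mx) + nb_loglik_mean(y, r, my)
  fit_trans <- list(loglik = ll_nb_free + bb_half$loglik,
                    p_mu = mx / (r + mx), p_nu = my / (r + my),
                    beta_mean = 0.5, concentration = bb_half$concentration)

  # cis: beta mean tied to mu/(mu+nu); 3-D search over
  # (log mu, log nu, log c) from several starts, keeping the best
  neg_cis <- function(par) {
    mu <- exp(clamp(par[1], -14, 21)); nu <- exp(clamp(par[2], -14, 21))
    conc <- exp(clamp(par[3], log(1e-2), log(1e8)))
    -(nb_loglik_mean(x, r, mu) + nb_loglik_mean(y, r, nu) +
        bb(mu / (mu + nu), conc))
  }
  c_start <- if (has_f1) {
    log(bb_moment_concentration(zk, nk, clamp(mx / (mx + my), 1e-3, 1 - 1e-3)))
  } else log(10)
  f1_frac <- if (has_f1) clamp(sum(zk) / sum(nk), 1e-3, 1 - 1e-3) else 0.5
  tot <- mx + my
  starts <- list(
    c(log(mx), log(my), c_start),
    c(log(m0), log(m0), log(max(bb_half$concentration, 0.1, na.rm = TRUE))),
    c(log(max(tot * f1_frac, 1e-6)), log(max(tot * (1 - f1_frac), 1e-6)),
      c_start)
  )
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, neg_cis, method = "Nelder-Mead",
                      control = list(reltol = reltol, maxit = 2000))
    if (is.null(best) || o$value < best$value) best <- o
  }
  mu_c <- exp(clamp(best$par[1], -14, 21))
  nu_c <- exp(clamp(best$par[2], -14, 21))
  fit_cis <- list(loglik = -best$value,
                  p_mu = mu_c / (r + mu_c), p_nu = nu_c / (r + nu_c),
                  beta_mean = mu_c / (mu_c + nu_c),
                  concentration = exp(clamp(best$par[3], log(1e-2),
                                            log(1e8))))

  # cis-trans: free NB means (closed form) + 2-D beta-binomial search
  if (has_f1) {
    neg_ct <- function(par) {
      m_b <- stats::plogis(clamp(par[1], -15, 15))
      conc <- exp(clamp(par[2], log(1e-2), log(1e8)))
      -bb(m_b, conc)
    }
    ct_starts <- list(
      c(stats::qlogis(f1_frac), c_start),
      c(0, log(max(bb_half$concentration, 0.1, na.rm = TRUE))),
      c(stats::qlogis(clamp(fit_cis$beta_mean, 1e-6, 1 - 1e-6)),
        log(fit_cis$concentration))
    )
    best_ct <- NULL
    for (s in ct_starts) {
      o <- stats::optim(s, neg_ct, method = "Nelder-Mead",
                        control = list(reltol = reltol, maxit = 2000))
      if (is.null(best_ct) || o$value < best_ct$value) best_ct <- o
    }
    bb_ct <- -best_ct$value
    m_b_ct <- stats::plogis(clamp(best_ct$par[1], -15, 15))
    c_ct <- exp(clamp(best_ct$par[2], log(1e-2), log(1e8)))
  } else {
    bb_ct <- 0; m_b_ct <- NA_real_; c_ct <- NA_real_
  }
  fit_ct <- list(loglik = ll_nb_free + bb_ct,
                 p_mu = mx / (r + mx), p_nu = my / (r + my),
                 beta_mean = m_b_ct, concentration = c_ct)

  fits <- list(conserved = fit_cons, cis = fit_cis, trans = fit_trans,
               cis_trans = fit_ct)
  for (m in names(fits)) {
    fits[[m]]$k <- REG_MODEL_K[[m]]
    fits[[m]]$bic <- bic(fits[[m]]$loglik, REG_MODEL_K[[m]], n_obs)
  }
  fits
}

#' Fit the four regulatory models to one site
#'
#' Maximum-likelihood fits of the conserved, cis, trans and cis-trans
#' scenarios, compared by BIC (`k log N - 2 logL`, N = number of replicate
#' observations). Ties are broken toward the model with fewer parameters,
#' then toward conserved.
#'
#' @param site one-row site-table `data.frame` (normalized counts are
#'   rounded for the discrete likelihoods).
#' @param r NB size (reciprocal dispersion) for this site.
#' @return list of class `"regulatory_call"`: `site_id`, `class`,
#'   `delta_bic`, `fits` (per-model parameter estimates, log-likelihood,
#'   BIC).
#' @export
fit_regulatory_models <- function(site, r) {
  stopifnot(nrow(site) == 1, is.finite(r), r > 0)
  x <- as.numeric(count_matrix(site, "F0_A"))
  y <- as.numeric(count_matrix(site, "F0_B"))
  za <- as.numeric(count_matrix(site, "F1_A"))
  zb <- as.numeric(count_matrix(site, "F1_B"))
  cts <- round_site_counts(x, y, za, za + zb)

  if (sum(cts$x) + sum(cts$y) == 0 || sum(cts$n) == 0) {
    out <- list(site_id = site$site_id, class = "unclassified",
                delta_bic = NA_real_, fits = NULL)
    class(out) <- "regulatory_call"
    return(out)
  }
  fits <- fit_site_models(cts$x, cts$y, cts$z, cts$n, r)
  # order encodes the tie-break preference (fewer k first, conserved first)
  pref <- c("conserved", "cis", "trans", "cis_trans")
  bics <- vapply(fits[pref], `[[`, numeric(1), "bic")
  ks <- vapply(fits[pref], `[[`, numeric(1), "k")
  o <- order(bics, ks, seq_along(pref))
  winner <- pref[o[1]]
  delta <- bics[o[2]] - bics[o[1]]
  out <- list(site_id = site$site_id, class = winner, delta_bic = delta,
              fits = fits)
  class(out) <- "regulatory_call"
  out
}

#' Classify every site in a table
#'
#' @param sites preprocessed (filtered, normalized) site table.
#' @param dispersion_model a `"dispersion_model"` from
#'   [estimate_dispersion()], or a single numeric `r` applied to all sites.
#' @return calls `data.frame`: site_id, class, delta_bic, winner parameter
#'   estimates (p_mu, p_nu, beta_mean, concentration) and per-model
#'   loglik_* / bic_* columns.
#' @export
classify_sites <- function(sites, dispersion_model) {
  r_for <- function(id) {
    if (is.numeric(dispersion_model)) return(dispersion_model)
    tab <- dispersion_model$table
    r <- tab$r[match(id, tab$site_id)]
    if (is.na(r)) stop("no dispersion estimate for site ", id)
    r
  }
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    call <- fit_regulatory_models(sites[i, , drop = FALSE],
                                  r_for(sites$site_id[i]))
    if (call$class == "unclassified") {
      base <- data.frame(site_id = call$site_id, class = "unclassified",
                         delta_bic = NA_real_, p_mu = NA_real_,
                         p_nu = NA_real_, beta_mean = NA_real_,
                         concentration = NA_real_,
                         stringsAsFactors = FALSE)
      for (m in names(REG_MODEL_K)) {
        base[[paste0("loglik_", m)]] <- NA_real_
        base[[paste0("bic_", m)]] <- NA_real_
      }
      return(base)
    }
    w <- call$fits[[call$class]]
    base <- data.frame(site_id = call$site_id, class = call$class,
                       delta_bic = call$delta_bic, p_mu = w$p_mu,
                       p_nu = w$p_nu, beta_mean = w$beta_mean,
                       concentration = w$concentration,
                       stringsAsFactors = FALSE)
    for (m in names(call$fits)) {
      base[[paste0("loglik_", m)]] <- call$fits[[m]]$loglik
      base[[paste0("bic_", m)]] <- call$fits[[m]]$bic
    }
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
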