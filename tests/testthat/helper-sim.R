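# Shared fixtures: all synthetic, built in code.

# small default config for fast unit tests
tiny_config <- function(...) {
  sim_config(n_sites_per_class = 20, mean_depth = 100, dispersion = 0.1,
             seed = 101, ...)
}

# deterministic one-row site table from explicit replicate vectors
make_site <- function(f0_a, f0_b, f1_a, f1_b, site_id = "s1",
                      chrom = "chr1", pos = 1000L, assay = "TF1") {
  stopifnot(length(f0_a) == length(f0_b), length(f1_a) == length(f1_b))
  df <- data.frame(site_id = site_id, chrom = chrom, pos = pos,
                   assay = assay, stringsAsFactors = FALSE)
  for (i in seq_along(f0_a)) df[[paste0("F0_A_rep", i)]] <- f0_a[i]
  for (i in seq_along(f0_b)) df[[paste0("F0_B_rep", i)]] <- f0_b[i]
  for (i in seq_along(f1_a)) df[[paste0("F1_A_rep", i)]] <- f1_a[i]
  for (i in seq_along(f1_b)) df[[paste0("F1_B_rep", i)]] <- f1_b[i]
  df
}

# stack several make_site() rows
make_sites <- function(...) {
  rows <- list(...)
  do.call(rbind, rows)
}

# swap the strain-A and strain-B columns (F0 and F1 alike)
swap_strains <- function(sites) {
  out <- sites
  a0 <- grep("^F0_A_rep", colnames(sites)); b0 <- grep("^F0_B_rep",
                                                       colnames(sites))
  a1 <- grep("^F1_A_rep", colnames(sites)); b1 <- grep("^F1_B_rep",
                                                       colnames(sites))
  out[, a0] <- sites[, b0]; out[, b0] <- sites[, a0]
  out[, a1] <- sites[, b1]; out[, b1] <- sites[, a1]
  out
}
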