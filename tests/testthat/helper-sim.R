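# Shared fixtures, built in code.

tiny_panel <- function(seed = 1, n_hap = 200, n_var = 50, rho = 0.8,
                       block = 10, genome = 1e6) {
  simulate_panel(n_hap, n_var, block_size = block,
                 within_block_correlation = rho, genome_length = genome,
                 seed = seed)
}

# Adjacent-variant genotype correlation of a haplotype matrix.
adjacent_r <- function(H, idx_a, idx_b) {
  vapply(seq_along(idx_a), function(k)
    suppressWarnings(cor(H[, idx_a[k]], H[, idx_b[k]])), numeric(1))
}

# Convert a cohort to a dosage_matrix with realized info scores.
as_dm <- function(dosages, variants) {
  dm <- dosage_matrix(dosages, variants)
  dm$variants$info <- info_score(dosages)
  dm
}

# Classical TDT z from hard-genotype trios: transmissions from het parents.
tdt_oracle_z <- function(trios, j) {
  b <- 0; c_ <- 0
  for (par in c("father", "mother")) {
    g <- trios[[par]][, j]
    het <- g == 1
    tr <- trios[[paste0("t_", substr(par, 1, 6))]][het, j]
    b <- b + sum(tr == 1)
    c_ <- c_ + sum(tr == 0)
  }
  if (b + c_ == 0) return(NA_real_)
  (b - c_) / sqrt(b + c_)
}
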