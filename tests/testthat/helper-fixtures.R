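# Shared fixtures: everything is generated in code at test time.

# standard 8-library design (3 males, 2 sexual females, 3 asexual females)
std_design <- function() {
  tibble::tibble(
    library = c("M1", "M2", "M3", "F1", "F2", "A1", "A2", "A3"),
    morph = c("M", "M", "M", "F", "F", "A", "A", "A")
  )
}

# NB count matrix with per-gene morph factors; rows named g1..gG
nb_counts <- function(mu, factors_M = 1, factors_F = 1, factors_A = 1,
                      dispersion = 0.05) {
  G <- length(mu)
  fac <- cbind(M = rep_len(factors_M, G), F = rep_len(factors_F, G),
               A = rep_len(factors_A, G))
  design <- std_design()
  m <- sapply(seq_len(nrow(design)), function(j) {
    rnbinom(G, mu = mu * fac[, design$morph[j]], size = 1 / dispersion)
  })
  rownames(m) <- paste0("g", seq_len(G))
  colnames(m) <- design$library
  m
}

# small synthetic-dataset configuration used across expression tests
small_synth_config <- function(...) {
  synth_config(n_genes = 800, n_markers = 150, n_scaffolds = 60,
               n_chimeric = 3, depth_range = c(2e6, 3e6), ...)
}

# binomial std error (percent scale) for an observed proportion
pct_se <- function(pct, n) sqrt(pct * (100 - pct) / n)
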