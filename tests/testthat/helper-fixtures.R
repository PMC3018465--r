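# shared in-code fixtures: everything is generated, nothing stored on disk

six_samples <- function(library_total = 1e7) {
  tibble::tibble(
    sample_id = c("M1", "M2", "A1", "A2", "S1", "S2"),
    tissue = rep(c("meiocyte", "anther", "seedling"), each = 2),
    replicate = rep(1:2, 3),
    library_total = library_total,
    is_pseudo = FALSE
  )
}

# tiny counts table with known values, one row per planted pattern
tiny_counts <- function(samples = six_samples()) {
  tibble::tibble(
    gene_id = c("g_hk", "g_mei", "g_wall"),
    M1 = c(100L, 400L, 20L), M2 = c(110L, 380L, 22L),
    A1 = c(105L, 40L, 400L), A2 = c(95L, 44L, 380L),
    S1 = c(102L, 0L, 0L), S2 = c(98L, 1L, 0L)
  )
}

# truth table with explicit per-tissue means, Poisson by default
manual_truth <- function(mu_m, mu_a = mu_m, mu_s = mu_m, dispersion = 0) {
  n <- length(mu_m)
  tibble::tibble(
    gene_id = sprintf("G%05d", seq_len(n)),
    mu_m = mu_m, mu_a = rep_len(mu_a, n), mu_s = rep_len(mu_s, n),
    dispersion = rep_len(dispersion, n)
  )
}

# small simulation config that still carries the full genomic structure
small_sim <- function(n_genes = 1500, ...) {
  sim_config(n_genes = n_genes, mgi_n_genes = 50, ...)
}

# independent Benjamini-Hochberg oracle: literal step-up definition,
# q_i = min over j with p_(j) >= p_(i) of p_(j) * m / j
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- which(p[ord] >= p[i])
    q[i] <- min(p[ord][js] * m / js)
  }
  pmin(q, 1)
}
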