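# shared fixture builders (all data generated in code)

# random genotype table with k equifrequent-ish alleles per locus
rand_table <- function(n, L = 3, k = 4, seed = 1, missing = 0,
                       sample_id = "rand") {
  set.seed(seed)
  labels <- 100 + 2 * seq_len(k)
  calls <- array(sample(labels, n * L * 2, replace = TRUE), dim = c(n, L, 2))
  if (missing > 0) {
    drop <- which(matrix(runif(n * L) < missing, n, L), arr.ind = TRUE)
    for (r in seq_len(nrow(drop))) {
      calls[drop[r, 1], drop[r, 2], ] <- NA_integer_
    }
  }
  genotype_table(calls, sample_id = sample_id)
}

# Hardy-Weinberg sample at given allele frequencies (one locus)
hw_table <- function(n, freqs, seed = 1, sample_id = "hw") {
  set.seed(seed)
  k <- length(freqs)
  g <- matrix(sample(seq_len(k), 2 * n, replace = TRUE, prob = freqs), n, 2)
  genotype_table(array(c(g[, 1], g[, 2]), dim = c(n, 1, 2)),
                 sample_id = sample_id)
}

# exact Mann-Whitney p (two-sided) by full enumeration of group assignments
enumerate_mw_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  all_v <- c(x, y)
  u_of <- function(idx) {
    r <- rank(all_v)
    sum(r[idx]) - nx * (nx + 1) / 2
  }
  u_obs <- u_of(seq_len(nx))
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2, u_of)
  mu <- nx * ny / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}
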