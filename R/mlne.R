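# --- Pseudo-maximum-likelihood temporal Ne --------------------------------

# Wright-Fisher transition matrix on a discretized frequency grid.
# Grid points are bin midpoints f_k = (k - 0.5)/K; one generation of drift in
# a pool of M gene copies is Binomial(M, f); counts are folded back into bins.
.wf_transition <- function(M, K) {
  f <- (seq_len(K) - 0.5) / K
  cnt <- 0:M
  bin <- pmin(K, floor(cnt / M * K) + 1L)
  T <- matrix(0, K, K)
  for (k in seq_len(K)) {
    s <- rowsum(stats::dbinom(cnt, M, f[k]), bin)
    row <- numeric(K)
    row[as.integer(rownames(s))] <- s
    T[k, ] <- row
  }
  T
}

# t-generation transition by repeated squaring/multiplication
.wf_transition_t <- function(M, K, t) {
  T <- .wf_transition(M, K)
  out <- T
  if (t > 1) for (i in seq_len(t - 1)) out <- out %*% T
  out
}

# each-allele-vs-rest observed copy counts for the likelihood factors
.mlne_factors <- function(tps) {
  c0 <- ct <- m0 <- mt <- numeric(0)
  for (loc in tps$loci) {
    tm <- .tps_locus_terms(loc)
    if (tm$K == 0L) next
    g0 <- tps$ploidy * loc$S0
    gt <- tps$ploidy * loc$St
    c0 <- c(c0, round(tm$x * g0))
    ct <- c(ct, round(tm$y * gt))
    m0 <- c(m0, rep(g0, tm$K))
    mt <- c(mt, rep(gt, tm$K))
  }
  if (length(c0) == 0L) stop("degenerate samples: no usable alleles")
  list(c0 = c0, ct = ct, m0 = m0, mt = mt)
}

#' Pseudo-maximum-likelihood temporal estimator of Ne
#'
#' Likelihood of the two temporal samples over a grid of candidate Ne values:
#' for each allele (treated allele-vs-rest, factors multiplied across alleles
#' and loci), a uniform prior over a discretized initial frequency is combined
#' with binomial sampling of the first sample, `t` generations of
#' Wright-Fisher drift in a pool of `ploidy * Ne` gene copies (matrix
#' transitions on the frequency grid), and binomial sampling of the second
#' sample. The point estimate is the grid maximum; a maximum attained at the
#' upper grid bound is reported as `+Inf`. The confidence interval is the
#' 2-unit profile-likelihood support interval.
#'
#' @param tps a [temporal_pair_stats].
#' @param ne_grid ascending grid of candidate Ne (default: 60 log-spaced
#'   values from 10 to 10^4).
#' @param freq_bins frequency-grid resolution (>= 64).
#' @param cache optional environment to reuse transition matrices across calls
#'   with identical `ne_grid`, `freq_bins`, `t` and ploidy (useful in
#'   simulation studies).
#' @return `ne_estimate` with `method = "mlne"` (haploid input:
#'   `"haploid_mlne"`) and the profile log-likelihood in `$profile`.
#' @export
mlne_ne <- function(tps, ne_grid = NULL, freq_bins = 128L, cache = NULL) {
  if (freq_bins < 64L) stop("freq_grid resolution must be >= 64 bins")
  if (is.null(ne_grid)) ne_grid <- exp(seq(log(10), log(1e4), length.out = 60))
  ne_grid <- sort(ne_grid)
  K <- as.integer(freq_bins)
  fac <- .mlne_factors(tps)
  f <- (seq_len(K) - 0.5) / K
  nal <- length(fac$c0)
  # allele x bin sampling likelihoods
  B0 <- matrix(0, nal, K); Bt <- matrix(0, nal, K)
  for (i in seq_len(nal)) {
    B0[i, ] <- stats::dbinom(fac$c0[i], fac$m0[i], f)
    Bt[i, ] <- stats::dbinom(fac$ct[i], fac$mt[i], f)
  }
  A <- B0 / K                             # uniform prior folded in
  ll <- vapply(seq_along(ne_grid), function(j) {
    M <- max(2L, as.integer(round(tps$ploidy * ne_grid[j])))
    key <- sprintf("M%d_K%d_t%d", M, K, tps$t)
    Tt <- if (!is.null(cache) && !is.null(cache[[key]])) cache[[key]]
          else {
            tm <- .wf_transition_t(M, K, tps$t)
            if (!is.null(cache)) cache[[key]] <- tm
            tm
          }
    lik <- rowSums((A %*% Tt) * Bt)
    sum(log(pmax(lik, 1e-300)))
  }, 0)
  jmax <- which.max(ll)
  at_top <- jmax == length(ne_grid)
  point <- if (at_top) Inf else ne_grid[jmax]
  in_support <- ll >= ll[jmax] - 2
  ci_low <- ne_grid[which(in_support)[1L]]
  ci_high <- if (in_support[length(ne_grid)]) Inf
             else ne_grid[max(which(in_support))]
  .ne_estimate(point, ci_low, ci_high,
               method = if (tps$ploidy == 1L) "haploid_mlne" else "mlne",
               t = tps$t,
               flags = if (at_top) "maximum at upper grid bound" else character(0),
               extra = list(profile = data.frame(ne = ne_grid, loglik = ll)))
}
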