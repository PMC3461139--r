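# --- Linkage-disequilibrium single-sample Ne ------------------------------

# Burrows composite disequilibrium r^2 for every allele pair across every
# locus pair, after screening out alleles rarer than Pcrit.
.burrows_r2 <- function(tab, Pcrit) {
  L <- length(tab$loci)
  # allele dosage matrices per locus (individual x allele), NA rows = missing
  dosages <- vector("list", L)
  for (l in seq_len(L)) {
    a1 <- tab$calls[, l, 1L]; a2 <- tab$calls[, l, 2L]
    ok <- !is.na(a1)
    alleles <- sort(unique(c(a1[ok], a2[ok])))
    if (length(alleles) < 2L) { dosages[[l]] <- NULL; next }
    p <- (tabulate(match(a1[ok], alleles), length(alleles)) +
          tabulate(match(a2[ok], alleles), length(alleles))) / (2 * sum(ok))
    keep <- p >= Pcrit & p <= 1 - Pcrit
    if (sum(keep) < 1L) { dosages[[l]] <- NULL; next }
    alleles <- alleles[keep]
    D <- matrix(NA_real_, tab$n_individuals, length(alleles))
    D[ok, ] <- outer(a1[ok], alleles, "==") + outer(a2[ok], alleles, "==")
    dosages[[l]] <- D
  }
  use <- which(!vapply(dosages, is.null, TRUE))
  if (length(use) < 2L) stop("fewer than 2 polymorphic loci after Pcrit screening")
  r2 <- n_used <- pair_id <- numeric(0)
  for (i in seq_along(use)[-length(use)]) {
    for (j in seq.int(i + 1L, length(use))) {
      Da <- dosages[[use[i]]]; Db <- dosages[[use[j]]]
      ok <- !is.na(Da[, 1L]) & !is.na(Db[, 1L])
      n <- sum(ok)
      if (n < 2L) next
      Xa <- Da[ok, , drop = FALSE]; Xb <- Db[ok, , drop = FALSE]
      pa <- colMeans(Xa) / 2; pb <- colMeans(Xb) / 2
      for (a in seq_along(pa)) for (b in seq_along(pb)) {
        if (pa[a] <= 0 || pa[a] >= 1 || pb[b] <= 0 || pb[b] >= 1) next
        delta <- (n / (n - 1)) *
          (mean(Xa[, a] * Xb[, b]) / 2 - 2 * pa[a] * pb[b])
        r2 <- c(r2, delta^2 / (pa[a] * (1 - pa[a]) * pb[b] * (1 - pb[b])))
        n_used <- c(n_used, n)
        pair_id <- c(pair_id, i * 1000L + j)
      }
    }
  }
  if (length(r2) == 0L) stop("no usable locus pairs")
  list(r2 = r2, n = n_used, pair = pair_id)
}

.ld_expected_r2 <- function(S) {
  if (S >= 30) 1 / S + 3.19 / S^2 else 0.0018 + 0.907 / S + 4.44 / S^2
}

# random-mating inversion of the drift expectation of r2'
.ld_invert <- function(r2p, S) {
  if (r2p <= 0) return(Inf)
  if (S >= 30) { a <- 1 / 3; b <- 2.76 } else { a <- 0.308; b <- 2.08 }
  disc <- a^2 - b * r2p
  if (disc < 0) return(0)               # below estimable minimum
  (a + sqrt(disc)) / (2 * r2p)
}

#' Linkage-disequilibrium estimator of effective size
#'
#' Single-sample Ne from the Burrows composite disequilibrium: squared
#' correlations `r^2 = Delta^2 / [pA(1-pA) pB(1-pB)]` are computed for every
#' allele pair across every locus pair (alleles rarer than `Pcrit` screened
#' out), averaged with weights proportional to the individuals used, and
#' bias-adjusted by the sampling expectation
#' `E[r^2 | S] = 1/S + 3.19/S^2` (S >= 30; `0.0018 + 0.907/S + 4.44/S^2`
#' below). The random-mating inversion
#' `Ne = (1/3 + sqrt(1/9 - 2.76 r2')) / (2 r2')` (constants 0.308, 2.08 for
#' S < 30) gives the point estimate; `r2' <= 0` yields `+Inf`, and a negative
#' discriminant is reported as 0 with a "below estimable minimum" flag.
#' The confidence interval is a delete-one locus-pair jackknife on the r2'
#' scale.
#'
#' @param tab a [genotype_table] with >= 10 individuals.
#' @param Pcrit minimum allele frequency for inclusion (conventional choices
#'   0.05, 0.02, 0.01).
#' @param mating only `"random"` is implemented.
#' @param conf confidence level.
#' @return `ne_estimate` with `method = "ld"`, plus `r2_mean`, `r2_expected`,
#'   `r2_prime`, `S` (weighted harmonic-mean sample size).
#' @export
ld_ne <- function(tab, Pcrit = 0.02, mating = "random", conf = 0.95) {
  mating <- match.arg(mating, "random")
  if (tab$n_individuals < 10L) stop("need >= 10 individuals")
  bw <- .burrows_r2(tab, Pcrit)
  w <- bw$n
  r2_mean <- sum(w * bw$r2) / sum(w)
  S <- sum(w) / sum(w / bw$n)           # weighted harmonic mean of n
  r2_exp <- .ld_expected_r2(S)
  r2p <- r2_mean - r2_exp
  point <- .ld_invert(r2p, S)
  flags <- if (is.finite(point) && point == 0) "below estimable minimum"
           else character(0)
  pairs <- unique(bw$pair)
  if (length(pairs) >= 2L) {
    jk <- vapply(pairs, function(pid) {
      keep <- bw$pair != pid
      wk <- bw$n[keep]
      m <- sum(wk * bw$r2[keep]) / sum(wk)
      Sk <- sum(wk) / sum(wk / bw$n[keep])
      m - .ld_expected_r2(Sk)
    }, 0)
    J <- length(pairs)
    se <- sqrt((J - 1) / J * sum((jk - mean(jk))^2))
    zq <- stats::qnorm(1 - (1 - conf) / 2)
    lo <- .ld_invert(r2p + zq * se, S)    # larger r2' -> smaller Ne
    hi <- .ld_invert(r2p - zq * se, S)
    ci_low <- min(lo, hi); ci_high <- max(lo, hi)
  } else {
    ci_low <- NA_real_; ci_high <- NA_real_
    flags <- c(flags, "single locus pair: jackknife CI undefined")
  }
  .ne_estimate(point, ci_low, ci_high, method = "ld",
               flags = flags,
               extra = list(r2_mean = r2_mean, r2_expected = r2_exp,
                            r2_prime = r2p, S = S, Pcrit = Pcrit,
                            n_comparisons = length(bw$r2)))
}
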