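# --- Temporal and broodstock effective-size estimators --------------------

#' Drift statistics for a pair of temporal samples
#'
#' Builds the per-locus allele-frequency pairs (x at the first sample, y at
#' the second) needed by the temporal Ne estimators, together with sample
#' sizes, generations elapsed, sampling plan and (Plan I) census size.
#' Accepts two [genotype_table]s (diploid), two [haplotype_table]s (haploid),
#' or explicit frequency vectors.
#'
#' @param s0,st the two samples (same type); or, for explicit input, lists of
#'   per-locus frequency vectors (same allele order within a locus).
#' @param t generations elapsed between the samples (>= 1).
#' @param plan temporal sampling plan, `"II"` or `"I"` (Plan I: sampled before
#'   reproduction, with replacement; requires `census_N`).
#' @param census_N census size N entering the Plan I sampling correction.
#' @param S0,St sample sizes (individuals for diploid, sequences for haploid)
#'   per locus; only needed for explicit frequency input.
#' @param ploidy 1 or 2; inferred from table input.
#' @return object of class `temporal_pair_stats`: per-locus `x`, `y`, `S0`,
#'   `St`, plus `t`, `plan`, `census_N`, `ploidy`.
#' @export
temporal_pair_stats <- function(s0, st, t, plan = c("II", "I"), census_N = NULL,
                                S0 = NULL, St = NULL, ploidy = NULL) {
  plan <- match.arg(plan)
  if (t < 1) stop("t must be >= 1 generation")
  if (plan == "I" && (is.null(census_N) || census_N <= 0))
    stop("Plan I requires a positive census_N")
  loci <- list()
  if (inherits(s0, "genotype_table") && inherits(st, "genotype_table")) {
    ploidy <- 2L
    shared <- intersect(s0$loci, st$loci)
    if (length(shared) == 0L) stop("no shared loci")
    for (nm in shared) {
      c0 <- allele_counts(s0, nm); ct <- allele_counts(st, nm)
      if (length(c0) == 0L || length(ct) == 0L) next
      alleles <- sort(unique(c(names(c0), names(ct))))
      x <- setNames(rep(0, length(alleles)), alleles)
      y <- x
      x[names(c0)] <- c0 / sum(c0)
      y[names(ct)] <- ct / sum(ct)
      loci[[nm]] <- list(x = x, y = y, S0 = sum(c0) / 2, St = sum(ct) / 2)
    }
  } else if (inherits(s0, "haplotype_table") && inherits(st, "haplotype_table")) {
    ploidy <- 1L
    h0 <- s0$haplotype[!is.na(s0$haplotype)]
    ht <- st$haplotype[!is.na(st$haplotype)]
    alleles <- sort(unique(c(h0, ht)))
    x <- table(factor(h0, levels = alleles)) / length(h0)
    y <- table(factor(ht, levels = alleles)) / length(ht)
    loci[["mt"]] <- list(x = as.numeric(x), y = as.numeric(y),
                         S0 = length(h0), St = length(ht))
  } else {
    if (is.null(ploidy)) stop("ploidy must be given for explicit frequency input")
    if (!is.list(s0)) { s0 <- list(s0); st <- list(st) }
    if (is.null(S0) || is.null(St)) stop("S0 and St required for frequency input")
    S0 <- rep_len(S0, length(s0)); St <- rep_len(St, length(s0))
    for (l in seq_along(s0)) {
      loci[[paste0("L", l)]] <- list(x = as.numeric(s0[[l]]),
                                     y = as.numeric(st[[l]]),
                                     S0 = S0[l], St = St[l])
    }
  }
  if (length(loci) == 0L) stop("no usable loci")
  structure(list(loci = loci, t = t, plan = plan,
                 census_N = if (is.null(census_N)) NA_real_ else census_N,
                 ploidy = as.integer(ploidy)),
            class = "temporal_pair_stats")
}

# per-locus retained alleles (drop alleles absent, or fixed, at both times)
.tps_locus_terms <- function(loc) {
  x <- loc$x; y <- loc$y
  z <- (x + y) / 2
  keep <- (z - x * y) > 0        # drops z == 0 and z == 1
  list(x = x[keep], y = y[keep], z = z[keep], K = sum(keep))
}

#' Nei-Tajima standardized temporal variance Fc
#'
#' Per locus, `Fc = (1/K) * sum_i (x_i - y_i)^2 / (z_i - x_i * y_i)` with
#' `z = (x + y)/2`; alleles absent (or fixed) at both times are dropped.
#' Loci are combined weighting by allele count K.
#'
#' @param tps a [temporal_pair_stats].
#' @return list with `Fc` (multi-locus), `per_locus`, `K` per locus, and
#'   `df = sum(K - 1)` independent alleles.
#' @export
temporal_fc <- function(tps) {
  per <- K <- numeric(0)
  for (nm in names(tps$loci)) {
    tm <- .tps_locus_terms(tps$loci[[nm]])
    if (tm$K == 0L) next
    per[nm] <- mean((tm$x - tm$y)^2 / (tm$z - tm$x * tm$y))
    K[nm] <- tm$K
  }
  if (length(per) == 0L) stop("no polymorphic shared loci")
  list(Fc = sum(K * per) / sum(K), per_locus = per, K = K,
       df = sum(pmax(K - 1, 1)))
}

# container for Ne point + CI with explicit infinity semantics
.ne_estimate <- function(point, ci_low, ci_high, method, t = NA_real_,
                         flags = character(0), extra = list()) {
  structure(c(list(point = point, ci_low = ci_low, ci_high = ci_high,
                   method = method, t = t,
                   corrected_for_overlap = FALSE,
                   G = NA_real_, C = NA_real_, flags = flags), extra),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  f <- function(v) if (is.infinite(v)) "Inf" else sprintf("%.1f", v)
  cat(sprintf("Ne (%s): %s  [95%% CI %s, %s]%s\n", x$method, f(x$point),
              f(x$ci_low), f(x$ci_high),
              if (x$corrected_for_overlap)
                sprintf("  (overlap-corrected, C = %.3g, G = %.3g)", x$C, x$G)
              else ""))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

# allele-count-weighted mean of per-locus sampling corrections
.tps_sampling_correction <- function(tps, fc) {
  corr <- vapply(names(fc$K), function(nm) {
    loc <- tps$loci[[nm]]
    if (tps$ploidy == 2L) 1 / (2 * loc$S0) + 1 / (2 * loc$St)
    else 1 / loc$S0 + 1 / loc$St
  }, 0)
  sum(fc$K * corr) / sum(fc$K)
}

.f_to_ne <- function(fprime, t, ploidy) {
  if (fprime <= 0) Inf else t / (ploidy * fprime)
}

#' Temporal moments estimator of variance effective size
#'
#' Standardized temporal variance Fc corrected for sampling:
#' `F' = Fc - 1/(2*S0) - 1/(2*St) [+ 1/N under Plan I]` for diploid data
#' (haploid: `Fc - 1/S0 - 1/St`), and `Ne = t / (2*F')` (haploid:
#' `Nef = t / F'`). When the corrected drift signal is <= 0 the point estimate
#' is `+Inf` (drift below sampling noise). The chi-square confidence interval
#' uses `df = sum(K_l - 1)` independent alleles.
#'
#' @param tps a [temporal_pair_stats].
#' @param conf confidence level.
#' @return [`ne_estimate`][temporal_fc] object (`method = "moments"` or
#'   `"haploid_moments"`).
#' @export
moments_ne <- function(tps, conf = 0.95) {
  fc <- temporal_fc(tps)
  corr <- .tps_sampling_correction(tps, fc)
  plan_term <- if (tps$plan == "I") 1 / tps$census_N else 0
  fprime <- fc$Fc - corr + plan_term
  al <- (1 - conf) / 2
  df <- fc$df
  f_lo <- df * fc$Fc / stats::qchisq(1 - al, df)
  f_hi <- df * fc$Fc / stats::qchisq(al, df)
  ne_point <- .f_to_ne(fprime, tps$t, tps$ploidy)
  ne_low <- .f_to_ne(f_hi - corr + plan_term, tps$t, tps$ploidy)
  ne_high <- .f_to_ne(f_lo - corr + plan_term, tps$t, tps$ploidy)
  .ne_estimate(ne_point, min(ne_low, ne_high), max(ne_low, ne_high),
               method = if (tps$ploidy == 1L) "haploid_moments" else "moments",
               t = tps$t, extra = list(Fc = fc$Fc, df = df))
}

#' Haploid temporal moments estimator (female effective size)
#'
#' Convenience wrapper of [moments_ne] for haploid (mtDNA) data:
#' `Nef = t / (Fc - 1/S0 - 1/St)`, sample sizes in sequences.
#'
#' @param tps haploid [temporal_pair_stats].
#' @return `ne_estimate` with `method = "haploid_moments"`.
#' @export
haploid_moments_nef <- function(tps) {
  if (tps$ploidy != 1L) stop("haploid_moments_nef needs haploid data")
  moments_ne(tps)
}

# Jorde-Ryman corrected Fs. Sample sizes in individuals (diploid) or
# sequences (haploid); the harmonic-mean form below is in "individuals" units
# such that 1/n_tilde equals the total binomial sampling correction.
.fs_correct <- function(fs, n_tilde, nt, plan_term) {
  num <- fs * (1 - 1 / (4 * n_tilde)) - 1 / n_tilde + plan_term
  den <- (1 + fs / 4) * (1 - 1 / (2 * nt))
  num / den
}

#' Unbiased Fs temporal estimator of effective size
#'
#' The allele-frequency-change statistic
#' `Fs = sum_i (x_i - y_i)^2 / sum_i z_i (1 - z_i)` with numerators and
#' denominators pooled across loci, corrected for finite sample size (and,
#' under Plan I, finite census size):
#' `Fs' = [Fs (1 - 1/(4*n~)) - 1/n~ + 1/N] / [(1 + Fs/4)(1 - 1/(2*St))]`,
#' where `n~` is the harmonic mean sample size in individuals. `Ne = t/(2*Fs')`
#' (+Inf when `Fs' <= 0`). The confidence interval is a delete-one-locus
#' jackknife on the corrected Fs scale.
#'
#' @param tps a diploid [temporal_pair_stats] (the estimator assumes diploidy).
#' @param conf confidence level.
#' @return `ne_estimate` with `method = "tempofs"`.
#' @export
tempofs_ne <- function(tps, conf = 0.95) {
  if (tps$ploidy != 2L) stop("the Fs estimator assumes diploid data")
  nms <- names(tps$loci)
  num <- den <- numeric(length(nms))
  s0 <- st <- numeric(length(nms))
  keepl <- logical(length(nms))
  for (i in seq_along(nms)) {
    tm <- .tps_locus_terms(tps$loci[[i]])
    if (tm$K == 0L) next
    keepl[i] <- TRUE
    num[i] <- sum((tm$x - tm$y)^2)
    den[i] <- sum(tm$z * (1 - tm$z))
    s0[i] <- tps$loci[[i]]$S0; st[i] <- tps$loci[[i]]$St
  }
  if (!any(keepl)) stop("no polymorphic shared loci")
  num <- num[keepl]; den <- den[keepl]; s0 <- s0[keepl]; st <- st[keepl]
  L <- length(num)
  plan_term <- if (tps$plan == "I") 1 / tps$census_N else 0
  corrected <- function(idx) {
    fs <- sum(num[idx]) / sum(den[idx])
    S0h <- 1 / mean(1 / s0[idx]); Sth <- 1 / mean(1 / st[idx])
    ntil <- 2 / (1 / S0h + 1 / Sth)
    .fs_correct(fs, ntil, Sth, plan_term)
  }
  fsp <- corrected(seq_len(L))
  point <- .f_to_ne(fsp, tps$t, 2L)
  if (L >= 2L) {
    jk <- vapply(seq_len(L), function(l) corrected(setdiff(seq_len(L), l)), 0)
    se <- sqrt((L - 1) / L * sum((jk - mean(jk))^2))
    zq <- stats::qnorm(1 - (1 - conf) / 2)
    f_lo <- fsp - zq * se; f_hi <- fsp + zq * se
    ne_low <- .f_to_ne(f_hi, tps$t, 2L)
    ne_high <- .f_to_ne(f_lo, tps$t, 2L)
    flags <- character(0)
  } else {
    ne_low <- NA_real_; ne_high <- NA_real_
    flags <- "single locus: jackknife CI undefined"
  }
  .ne_estimate(point, ne_low, ne_high, method = "tempofs", t = tps$t,
               flags = flags, extra = list(Fs = sum(num) / sum(den),
                                           Fs_corrected = fsp))
}

#' Overlapping-generation correction of an Ne estimate
#'
#' Rescales a consecutive-sample temporal estimate for overlapping
#' generations: `Ne_adj = (C / G) * Ne_raw`, with G the generation length in
#' years and C the analytical correction factor of the age-structured model.
#' Infinity maps to infinity; confidence bounds are scaled by the same factor.
#'
#' @param est an `ne_estimate`.
#' @param C correction factor (> 0).
#' @param G generation length in years (> 0).
#' @return rescaled `ne_estimate` with `corrected_for_overlap = TRUE`.
#' @export
overlap_correction <- function(est, C, G) {
  if (C <= 0 || G <= 0) stop("C and G must be positive")
  f <- C / G
  est$point <- est$point * f
  est$ci_low <- est$ci_low * f
  est$ci_high <- est$ci_high * f
  est$corrected_for_overlap <- TRUE
  est$C <- C; est$G <- G
  est
}

#' Effective number of breeders from a sex-ratio census
#'
#' `Ne = 4 * Nm * Nf / (Nm + Nf)`; equals `Nm + Nf` when the sex ratio is
#' even.
#'
#' @param Nm,Nf male and female breeder counts (>= 1).
#' @return numeric Ne (vectorized).
#' @export
broodstock_ne <- function(Nm, Nf) {
  if (any(Nm < 1) || any(Nf < 1)) stop("Nm and Nf must both be >= 1")
  4 * Nm * Nf / (Nm + Nf)
}
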