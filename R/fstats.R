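# --- Weir-Cockerham theta and hierarchical AMOVA --------------------------

#' Weir-Cockerham F_ST (theta)
#'
#' Variance-component estimator of theta over two or more samples. Per-allele
#' components a (among samples), b (among individuals within samples) and c
#' (within individuals) are summed over alleles and loci;
#' `theta = sum(a) / sum(a + b + c)`.
#'
#' @param samples list of [genotype_table] sharing a locus set.
#' @return list with `theta` (overall), `per_locus` (named vector) and the
#'   summed `components` (a, b, c).
#' @export
weir_cockerham_fst <- function(samples) {
  if (length(samples) < 2L) stop("need >= 2 samples")
  loci <- samples[[1L]]$loci
  L <- length(loci)
  tot <- c(a = 0, b = 0, c = 0)
  per <- setNames(rep(NA_real_, L), loci)
  any_poly <- FALSE
  for (l in seq_len(L)) {
    dat <- lapply(samples, function(s) {
      a1 <- s$calls[, l, 1L]; a2 <- s$calls[, l, 2L]
      ok <- !is.na(a1)
      cbind(a1[ok], a2[ok])
    })
    dat <- dat[vapply(dat, nrow, 1L) > 1L]
    r <- length(dat)
    if (r < 2L) next
    alleles <- sort(unique(unlist(dat)))
    if (length(alleles) < 2L) next
    any_poly <- TRUE
    ns <- vapply(dat, nrow, 1L)
    nbar <- mean(ns)
    nc <- (r * nbar - sum(ns^2) / (r * nbar)) / (r - 1)
    la <- lb <- lc <- 0
    for (al in alleles) {
      p_i <- vapply(dat, function(d) mean(d == al), 0)
      h_i <- vapply(dat, function(d) mean((d[, 1L] == al) != (d[, 2L] == al)), 0)
      pbar <- sum(ns * p_i) / (r * nbar)
      s2 <- sum(ns * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ns * h_i) / (r * nbar)
      a <- (nbar / nc) *
        (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
      b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
      cc <- hbar / 2
      la <- la + a; lb <- lb + b; lc <- lc + cc
    }
    if (la + lb + lc != 0) per[l] <- la / (la + lb + lc)
    tot <- tot + c(a = la, b = lb, c = lc)
  }
  if (!any_poly) stop("all loci monomorphic across samples")
  list(theta = tot[["a"]] / sum(tot), per_locus = per, components = tot)
}

# SSD of a pooled set of labelled items: sum over unordered pairs of squared
# distances, divided by the set size.
.ssd_from_counts <- function(counts, d2) {
  n <- sum(counts)
  if (n == 0) return(0)
  as.numeric(counts %*% d2 %*% counts) / (2 * n)
}

# Variance components for one locus of diploid data under the nested design
# groups / samples / individuals / gene copies (identity distance between
# allele labels). `g` is a 2-column matrix of integer allele labels (no NA),
# `samp` the sample index per individual, `grp` the group index per sample.
# Returns c(sa, sb, sc, sd) or NULL when degenerate. With G = 1 group, sa = 0.
.amova_locus_diploid <- function(g, samp, grp) {
  keep_s <- sort(unique(samp))
  S <- length(keep_s)
  samp_i <- match(samp, keep_s)
  grp_i <- as.integer(factor(grp[keep_s]))
  G <- length(unique(grp_i))
  n_ind <- nrow(g)
  if (S < 2L || n_ind <= S) return(NULL)
  labels <- sort(unique(c(g)))
  nlab <- length(labels)
  if (nlab < 2L) return(NULL)
  d2 <- 1 - diag(nlab)
  gi <- matrix(match(g, labels), ncol = 2L)
  # sample x label copy counts
  cnt_sample <- matrix(0L, S, nlab)
  for (cpy in 1:2) {
    t1 <- table(factor(samp_i, levels = seq_len(S)),
                factor(gi[, cpy], levels = seq_len(nlab)))
    cnt_sample <- cnt_sample + unclass(t1)
  }
  ms <- rowSums(cnt_sample)                        # copies per sample
  N <- sum(ms)
  cnt_group <- rowsum(cnt_sample, grp_i)
  mg <- rowSums(cnt_group)
  cnt_tot <- colSums(cnt_sample)
  ssd_tot <- .ssd_from_counts(cnt_tot, d2)
  ssd_ws <- sum(vapply(seq_len(S), function(s)
    .ssd_from_counts(cnt_sample[s, ], d2), 0))
  ssd_wg <- sum(vapply(seq_len(nrow(cnt_group)), function(gg)
    .ssd_from_counts(cnt_group[gg, ], d2), 0))
  ssd_wi <- sum(gi[, 1L] != gi[, 2L]) / 2          # within individuals
  ssd_ai <- ssd_ws - ssd_wi                        # among individuals within samples
  ssd_as <- ssd_wg - ssd_ws                        # among samples within groups
  ssd_ag <- ssd_tot - ssd_wg                       # among groups
  df_wi <- n_ind
  df_ai <- n_ind - S
  df_as <- S - G
  df_ag <- G - 1L
  if (df_ai < 1L) return(NULL)
  sd_ <- ssd_wi / df_wi
  ms_ai <- ssd_ai / df_ai
  sc_ <- (ms_ai - sd_) / 2
  # coefficients on copy counts for the sample and group levels
  grp_list <- split(seq_len(S), grp_i)
  sum_ms2_over_mg <- sum(vapply(grp_list, function(ss) sum(ms[ss]^2), 0) /
                           vapply(grp_list, function(ss) sum(ms[ss]), 0))
  if (df_as >= 1L) {
    n1 <- (N - sum_ms2_over_mg) / df_as
    sb_ <- (ssd_as / df_as - ms_ai) / n1
  } else return(NULL)
  if (df_ag >= 1L) {
    n2 <- (sum_ms2_over_mg - sum(ms^2) / N) / df_ag
    n3 <- (N - sum(mg^2) / N) / df_ag
    sa_ <- (ssd_ag / df_ag - ms_ai - n2 * sb_) / n3
  } else sa_ <- 0
  c(sa = sa_, sb = sb_, sc = sc_, sd = sd_)
}

# Haploid analogue: items are single haplotypes per individual with a
# user-suppliable squared-distance matrix. Levels: groups / samples / within.
.amova_locus_haploid <- function(items, samp, grp, d2, nlab) {
  keep_s <- sort(unique(samp))
  S <- length(keep_s)
  samp_i <- match(samp, keep_s)
  grp_i <- as.integer(factor(grp[keep_s]))
  G <- length(unique(grp_i))
  N <- length(items)
  if (S < 2L || N <= S) return(NULL)
  cnt_sample <- unclass(table(factor(samp_i, levels = seq_len(S)),
                              factor(items, levels = seq_len(nlab))))
  ns <- rowSums(cnt_sample)
  cnt_group <- rowsum(cnt_sample, grp_i)
  ng <- rowSums(cnt_group)
  cnt_tot <- colSums(cnt_sample)
  ssd_tot <- .ssd_from_counts(cnt_tot, d2)
  ssd_ws <- sum(vapply(seq_len(S), function(s)
    .ssd_from_counts(cnt_sample[s, ], d2), 0))
  ssd_wg <- sum(vapply(seq_len(nrow(cnt_group)), function(gg)
    .ssd_from_counts(cnt_group[gg, ], d2), 0))
  df_ws <- N - S; df_as <- S - G; df_ag <- G - 1L
  if (df_ws < 1L || df_as < 1L) return(NULL)
  sc_ <- ssd_ws / df_ws
  grp_list <- split(seq_len(S), grp_i)
  sum_ns2_over_ng <- sum(vapply(grp_list, function(ss) sum(ns[ss]^2), 0) /
                           vapply(grp_list, function(ss) sum(ns[ss]), 0))
  n1 <- (N - sum_ns2_over_ng) / df_as
  sb_ <- ((ssd_wg - ssd_ws) / df_as - sc_) / n1
  if (df_ag >= 1L) {
    n2 <- (sum_ns2_over_ng - sum(ns^2) / N) / df_ag
    n3 <- (N - sum(ng^2) / N) / df_ag
    sa_ <- ((ssd_tot - ssd_wg) / df_ag - sc_ - n2 * sb_) / n3
  } else sa_ <- 0
  c(sa = sa_, sb = sb_, sc = sc_, sd = 0)
}

#' Three-level AMOVA (analysis of molecular variance)
#'
#' Partitions molecular variance among groups of samples, among samples within
#' groups, and within samples. For diploid data (`mode = "diploid_freq"`) the
#' within-sample variance carries the nested among-/within-individual levels,
#' so the two-level special case reproduces the Weir-Cockerham theta exactly.
#' For haploid data (`mode = "haploid_distance"`) squared inter-haplotype
#' distances are used (default: identity distance, all distinct haplotypes
#' equidistant) and the indices are the Phi-statistics. Negative variance
#' components are reported as estimated, never truncated.
#'
#' Permutation schemes for the p-values: whole samples among groups (F_CT),
#' individuals among samples within groups (F_SC), individuals among all
#' samples (F_ST).
#'
#' @param samples list of [genotype_table] or [haplotype_table].
#' @param groups group assignment, one per sample; `NULL` puts every sample in
#'   one group (two-level analysis, F_ST only).
#' @param mode `"diploid_freq"` or `"haploid_distance"`.
#' @param distance optional squared-distance matrix between haplotype labels
#'   (haploid mode), dimnames = haplotype labels.
#' @param n_perm number of permutations (0 skips p-values).
#' @param seed RNG seed.
#' @return object of class `amova_result` with `components` (sigma_a, sigma_b,
#'   sigma_within), `indices` (F_CT, F_SC, F_ST), `p_values`,
#'   `n_permutations`, `mode`.
#' @export
amova_three_level <- function(samples, groups = NULL,
                              mode = c("diploid_freq", "haploid_distance"),
                              distance = NULL, n_perm = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  S <- length(samples)
  if (S < 2L) stop("need >= 2 samples")
  two_level <- is.null(groups)
  grp <- if (two_level) rep(1L, S) else as.integer(factor(groups))
  if (length(grp) != S) stop("one group per sample required")
  if (!two_level) {
    if (length(unique(grp)) < 2L) stop("need >= 2 groups")
    if (any(tabulate(grp) == 0L)) stop("a group has zero samples")
  }

  if (mode == "diploid_freq") {
    loci <- samples[[1L]]$loci
    indiv_sample <- unlist(lapply(seq_len(S), function(s)
      rep.int(s, samples[[s]]$n_individuals)))
    geno <- lapply(seq_along(loci), function(l) {
      a1 <- unlist(lapply(samples, function(s) s$calls[, l, 1L]))
      a2 <- unlist(lapply(samples, function(s) s$calls[, l, 2L]))
      cbind(a1, a2)
    })
    compute <- function(samp_of_indiv, grp_of_sample) {
      acc <- c(sa = 0, sb = 0, sc = 0, sd = 0)
      for (l in seq_along(loci)) {
        gmat <- geno[[l]]
        ok <- !is.na(gmat[, 1L])
        comp <- .amova_locus_diploid(gmat[ok, , drop = FALSE],
                                     samp_of_indiv[ok], grp_of_sample)
        if (!is.null(comp)) acc <- acc + comp
      }
      acc
    }
    unit_sample <- indiv_sample
  } else {
    haps <- lapply(samples, function(s) s$haplotype[!is.na(s$haplotype)])
    labels <- sort(unique(unlist(haps)))
    nlab <- length(labels)
    d2 <- if (is.null(distance)) 1 - diag(nlab)
          else as.matrix(distance)[labels, labels]
    items_all <- match(unlist(haps), labels)
    unit_sample <- unlist(lapply(seq_len(S), function(s)
      rep.int(s, length(haps[[s]]))))
    compute <- function(samp_of_unit, grp_of_sample) {
      comp <- .amova_locus_haploid(items_all, samp_of_unit, grp_of_sample,
                                   d2, nlab)
      if (is.null(comp)) stop("degenerate haploid AMOVA design")
      comp
    }
  }

  indices_of <- function(v) {
    wth <- v[["sc"]] + v[["sd"]]
    tot <- v[["sa"]] + v[["sb"]] + wth
    c(F_CT = v[["sa"]] / tot,
      F_SC = v[["sb"]] / (v[["sb"]] + wth),
      F_ST = (v[["sa"]] + v[["sb"]]) / tot)
  }
  obs <- compute(unit_sample, grp)
  obs_idx <- indices_of(obs)
  if (two_level) obs_idx["F_CT"] <- NA_real_

  pvals <- c(F_CT = NA_real_, F_SC = NA_real_, F_ST = NA_real_)
  if (n_perm > 0L) {
    set.seed(as.integer(seed))
    ge <- c(F_CT = 0L, F_SC = 0L, F_ST = 0L)
    for (b in seq_len(n_perm)) {
      if (!two_level) {
        v <- indices_of(compute(unit_sample, sample(grp)))
        if (isTRUE(v[["F_CT"]] >= obs_idx[["F_CT"]] - 1e-12))
          ge["F_CT"] <- ge["F_CT"] + 1L
        samp_sc <- unit_sample
        for (g in unique(grp)) {
          in_g <- which(grp[unit_sample] == g)
          samp_sc[in_g] <- sample(unit_sample[in_g])
        }
        v <- indices_of(compute(samp_sc, grp))
        if (isTRUE(v[["F_SC"]] >= obs_idx[["F_SC"]] - 1e-12))
          ge["F_SC"] <- ge["F_SC"] + 1L
      }
      v <- indices_of(compute(sample(unit_sample), grp))
      if (isTRUE(v[["F_ST"]] >= obs_idx[["F_ST"]] - 1e-12))
        ge["F_ST"] <- ge["F_ST"] + 1L
    }
    pvals <- (ge + 1L) / (n_perm + 1L)
    pvals[is.na(obs_idx)] <- NA_real_
    if (two_level) pvals[c("F_CT", "F_SC")] <- NA_real_
  }
  structure(list(components = c(sigma_a = obs[["sa"]], sigma_b = obs[["sb"]],
                                sigma_within = obs[["sc"]] + obs[["sd"]]),
                 indices = obs_idx, p_values = pvals,
                 n_permutations = as.integer(n_perm), mode = mode),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  lab <- if (x$mode == "haploid_distance") c("Phi_CT", "Phi_SC", "Phi_ST")
         else c("F_CT", "F_SC", "F_ST")
  cat(sprintf("three-level AMOVA (%s), %d permutations\n", x$mode,
              x$n_permutations))
  cat(sprintf("  variance components: among groups %.5g, among samples %.5g, within %.5g\n",
              x$components[1], x$components[2], x$components[3]))
  for (i in 1:3)
    cat(sprintf("  %s = %.5f (p = %.4g)\n", lab[i], x$indices[i], x$p_values[i]))
  invisible(x)
}
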