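#' Allele counts per locus
#'
#' @param tab a [genotype_table].
#' @param locus locus name or index.
#' @return named integer vector of allele-copy counts (non-missing calls only).
#' @export
allele_counts <- function(tab, locus) {
  l <- if (is.character(locus)) match(locus, tab$loci) else as.integer(locus)
  if (is.na(l) || l < 1L || l > length(tab$loci)) stop("unknown locus")
  a <- c(tab$calls[, l, 1L], tab$calls[, l, 2L])
  a <- a[!is.na(a)]
  if (length(a) == 0L) return(integer(0))
  tb <- table(a)
  out <- as.integer(tb)
  names(out) <- names(tb)
  out
}

#' Unbiased gene (haplotype) diversity
#'
#' Nei's unbiased gene diversity for a haploid sample:
#' `h = n/(n-1) * (1 - sum(p_i^2))`, with `p_i` the haplotype frequencies and
#' `n` the number of sequences.
#'
#' @param counts haplotype counts (or a [haplotype_table]).
#' @param n optional override of total sequences (defaults to `sum(counts)`).
#' @return h in `[0, 1]`.
#' @export
unbiased_gene_diversity <- function(counts, n = NULL) {
  if (inherits(counts, "haplotype_table"))
    counts <- as.integer(table(counts$haplotype, useNA = "no"))
  counts <- counts[counts > 0]
  if (is.null(n)) n <- sum(counts)
  if (n < 2) stop("unbiased gene diversity is undefined for n < 2")
  p <- counts / sum(counts)
  h <- n / (n - 1) * (1 - sum(p^2))
  max(0, min(1, h))
}

#' Unbiased expected heterozygosity for a diploid locus
#'
#' `He = 2n/(2n-1) * (1 - sum(p_i^2))` with `2n` non-missing gene copies.
#'
#' @param counts allele-copy counts at one locus (e.g. from [allele_counts]).
#' @return He in `[0, 1]`.
#' @export
expected_het_unbiased <- function(counts) {
  counts <- counts[counts > 0]
  m <- sum(counts)                       # gene copies
  if (m < 2) stop("need at least 2 gene copies (1 individual)")
  p <- counts / m
  he <- m / (m - 1) * (1 - sum(p^2))
  max(0, min(1, he))
}

#' Observed heterozygosity at a locus
#'
#' @param tab a [genotype_table].
#' @param locus locus name or index.
#' @return proportion of heterozygous individuals among non-missing calls.
#' @export
observed_het <- function(tab, locus) {
  l <- if (is.character(locus)) match(locus, tab$loci) else as.integer(locus)
  a1 <- tab$calls[, l, 1L]; a2 <- tab$calls[, l, 2L]
  ok <- !is.na(a1)
  if (!any(ok)) stop("no non-missing calls at locus")
  mean(a1[ok] != a2[ok])
}

#' Rarefied allelic (or haplotype) richness
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies drawn without replacement from `n` observed copies:
#' `A_R(g) = sum_i [1 - C(n - n_i, g) / C(n, g)]`.
#'
#' @param counts allele/haplotype counts; `n = sum(counts)`.
#' @param g rarefaction size in gene copies (haploid: sequences), `1 <= g <= n`.
#' @return expected richness; equals the observed count when `g == n`.
#' @export
rarefied_richness <- function(counts, g) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (g < 1 || g > n) stop("g must satisfy 1 <= g <= n")
  # lchoose handles C(n - n_i, g) = 0 when n - n_i < g
  term <- ifelse(n - counts < g, 0,
                 exp(lchoose(n - counts, g) - lchoose(n, g)))
  sum(1 - term)
}

# Weir-Cockerham within-sample variance components (b, c) per allele for one
# locus of a single sample. Returns a 2-column matrix (b, c); NULL when the
# locus has < 2 usable individuals or is monomorphic.
.wc_within_components <- function(tab, l) {
  a1 <- tab$calls[, l, 1L]; a2 <- tab$calls[, l, 2L]
  ok <- !is.na(a1)
  n <- sum(ok)
  if (n < 2L) return(NULL)
  a1 <- a1[ok]; a2 <- a2[ok]
  alleles <- sort(unique(c(a1, a2)))
  if (length(alleles) < 2L) return(NULL)
  comp <- vapply(alleles, function(al) {
    p <- (sum(a1 == al) + sum(a2 == al)) / (2 * n)
    hbar <- mean((a1 == al) != (a2 == al))     # het for this allele
    b <- n / (n - 1) * (p * (1 - p) - (2 * n - 1) / (4 * n) * hbar)
    c <- hbar / 2
    c(b = b, c = c)
  }, numeric(2))
  t(comp)
}

#' Within-sample inbreeding coefficient F_IS (Weir-Cockerham)
#'
#' Per-locus and variance-component-weighted mean `F_IS = 1 - sum(c)/sum(b+c)`
#' over the within-individual (`c`) and among-individual (`b`) components.
#' Monomorphic loci are excluded from the mean.
#'
#' @param tab a [genotype_table] with >= 2 individuals.
#' @return list with `per_locus` (named vector, NA for monomorphic loci) and
#'   `mean` (weighted across loci).
#' @export
fis_within <- function(tab) {
  if (tab$n_individuals < 2L) stop("need >= 2 individuals")
  L <- length(tab$loci)
  per <- setNames(rep(NA_real_, L), tab$loci)
  sb <- sc <- 0
  for (l in seq_len(L)) {
    comp <- .wc_within_components(tab, l)
    if (is.null(comp)) next
    bl <- sum(comp[, "b"]); cl <- sum(comp[, "c"])
    if (bl + cl != 0) per[l] <- 1 - cl / (bl + cl)
    sb <- sb + bl; sc <- sc + cl
  }
  mean_fis <- if (sb + sc == 0) NA_real_ else 1 - sc / (sb + sc)
  list(per_locus = per, mean = mean_fis)
}

#' Resampling-corrected diversity
#'
#' Diversity corrected for unequal sample sizes by repeated subsampling:
#' `B` random subsamples of `n_star` individuals are drawn without replacement;
#' for each subsample, per-locus unbiased expected heterozygosity, observed
#' heterozygosity and allele number are computed on the individuals non-missing
#' at each locus, then averaged across loci. Point estimates are means over
#' subsamples; confidence intervals are empirical 2.5/97.5 percentiles of the
#' across-locus means.
#'
#' @param tab a [genotype_table].
#' @param n_star subsample size (individuals); must not exceed `n`.
#' @param B number of subsamples (the conventional choice is 1000).
#' @param seed integer seed for reproducibility.
#' @param conf confidence level for the percentile interval.
#' @return object of class `corrected_diversity`: list with `Hec`, `Hoc`,
#'   `Nac`, their `ci` (2-column matrix), per-locus means, `B`, `n_star`.
#' @export
resample_corrected <- function(tab, n_star, B = 1000L, seed = 1L, conf = 0.95) {
  n <- tab$n_individuals
  if (n_star > n) {
    warning(sprintf("sample '%s' skipped: n = %d < n_star = %d",
                    tab$sample_id, n, n_star))
    return(NULL)
  }
  if (B < 1L) stop("B must be >= 1")
  L <- length(tab$loci)
  set.seed(as.integer(seed))
  hec <- hoc <- nac <- matrix(NA_real_, nrow = B, ncol = L)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n_star, replace = FALSE)
    sub1 <- tab$calls[idx, , 1L, drop = FALSE]
    sub2 <- tab$calls[idx, , 2L, drop = FALSE]
    for (l in seq_len(L)) {
      a1 <- sub1[, l, 1L]; a2 <- sub2[, l, 1L]
      ok <- !is.na(a1)
      if (!any(ok)) next
      a1 <- a1[ok]; a2 <- a2[ok]
      cnt <- table(c(a1, a2))
      hec[b, l] <- expected_het_unbiased(as.integer(cnt))
      hoc[b, l] <- mean(a1 != a2)
      nac[b, l] <- length(cnt)
    }
  }
  al <- (1 - conf) / 2
  row_mean <- function(m) rowMeans(m, na.rm = TRUE)
  ci <- function(v) stats::quantile(v, c(al, 1 - al), names = FALSE, na.rm = TRUE)
  mh <- row_mean(hec); mo <- row_mean(hoc); mn <- row_mean(nac)
  structure(list(
    Hec = mean(mh), Hoc = mean(mo), Nac = mean(mn),
    ci = rbind(Hec = ci(mh), Hoc = ci(mo), Nac = ci(mn)),
    per_locus = rbind(Hec = colMeans(hec, na.rm = TRUE),
                      Hoc = colMeans(hoc, na.rm = TRUE),
                      Nac = colMeans(nac, na.rm = TRUE)),
    per_locus_ci = list(Hec = apply(hec, 2, ci), Hoc = apply(hoc, 2, ci),
                        Nac = apply(nac, 2, ci)),
    B = B, n_star = n_star, sample_id = tab$sample_id), class = "corrected_diversity")
}

#' @export
print.corrected_diversity <- function(x, ...) {
  cat(sprintf("corrected diversity for '%s' (B = %d subsamples of n* = %d)\n",
              x$sample_id, x$B, x$n_star))
  cat(sprintf("  Hec = %.3f [%.3f, %.3f]\n", x$Hec, x$ci["Hec", 1], x$ci["Hec", 2]))
  cat(sprintf("  Hoc = %.3f [%.3f, %.3f]\n", x$Hoc, x$ci["Hoc", 1], x$ci["Hoc", 2]))
  cat(sprintf("  Nac = %.3f [%.3f, %.3f]\n", x$Nac, x$ci["Nac", 1], x$ci["Nac", 2]))
  invisible(x)
}

#' Haplotype inventory
#'
#' Distinct-haplotype count over one or several samples, plus per-sample
#' observed haplotype numbers.
#'
#' @param tables a [haplotype_table], a list of them, or a list of named count
#'   vectors (counts per haplotype label).
#' @return list with `total` (distinct haplotypes with nonzero occurrence over
#'   all samples) and `per_sample` (named integer vector).
#' @export
haplotype_inventory <- function(tables) {
  if (inherits(tables, "haplotype_table")) tables <- list(tables)
  if (length(tables) == 0L) stop("no haplotype data supplied")
  to_counts <- function(x) {
    if (inherits(x, "haplotype_table")) {
      tb <- table(x$haplotype, useNA = "no")
      setNames(as.integer(tb), names(tb))
    } else {
      x[x > 0]
    }
  }
  counts <- lapply(tables, to_counts)
  if (all(vapply(counts, length, 1L) == 0L)) stop("no non-missing haplotypes")
  ids <- names(tables)
  if (is.null(ids))
    ids <- vapply(seq_along(tables), function(i) {
      if (inherits(tables[[i]], "haplotype_table")) tables[[i]]$sample_id
      else as.character(i)
    }, "")
  per <- setNames(vapply(counts, function(ct) length(ct[ct > 0]), 1L), ids)
  all_labels <- unique(unlist(lapply(counts, names)))
  list(total = length(all_labels), per_sample = per)
}
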