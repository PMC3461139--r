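# --- Hardy-Weinberg exact test and multiple-testing control ---------------

# Genotype counts at one locus as a symmetric k x k matrix (upper triangle
# used: entry [i, j], i <= j, counts individuals with unordered genotype i/j).
.genotype_count_matrix <- function(tab, l) {
  a1 <- tab$calls[, l, 1L]; a2 <- tab$calls[, l, 2L]
  ok <- !is.na(a1)
  a1 <- a1[ok]; a2 <- a2[ok]
  alleles <- sort(unique(c(a1, a2)))
  k <- length(alleles)
  m <- matrix(0L, k, k, dimnames = list(alleles, alleles))
  i1 <- match(pmin(a1, a2), alleles)
  i2 <- match(pmax(a1, a2), alleles)
  for (idx in seq_along(i1)) m[i1[idx], i2[idx]] <- m[i1[idx], i2[idx]] + 1L
  m
}

# Variable part of log P(genotype array | allele counts):
#   H*log(2) - sum(log(n_ij!))   (constant terms cancel between arrays)
.hwe_log_kernel <- function(gm) {
  het <- sum(gm[upper.tri(gm)])
  het * log(2) - sum(lfactorial(gm[upper.tri(gm, diag = TRUE)]))
}

# Enumerate all genotype arrays compatible with the allele counts `m`
# (vector of gene-copy counts per allele). Calls `fun(gm)` for each array.
.hwe_enumerate <- function(m, fun) {
  k <- length(m)
  types <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  types <- types[order(types[, 1L], types[, 2L]), , drop = FALSE]
  gm <- matrix(0L, k, k)
  recurse <- function(t, rem) {
    if (t > nrow(types)) {
      if (all(rem == 0L)) fun(gm)
      return(invisible())
    }
    i <- types[t, 1L]; j <- types[t, 2L]
    maxc <- if (i == j) rem[i] %/% 2L else min(rem[i], rem[j])
    for (cnt in 0:maxc) {
      gm[i, j] <<- cnt
      rem2 <- rem
      if (i == j) rem2[i] <- rem2[i] - 2L * cnt
      else { rem2[i] <- rem2[i] - cnt; rem2[j] <- rem2[j] - cnt }
      recurse(t + 1L, rem2)
    }
    gm[i, j] <<- 0L
  }
  recurse(1L, as.integer(m))
  invisible()
}

#' Exact test of Hardy-Weinberg proportions
#'
#' Conditional exact test of HWE at one locus: the p-value is the total
#' probability, conditional on the observed allele counts, of genotype arrays
#' no more probable than the observed one (ties inclusive). `mode =
#' "enumerate"` sums over all compatible arrays; `mode = "mc"` estimates the
#' same quantity by repeatedly shuffling the gene copies into random diploid
#' genotypes. `mode = "auto"` enumerates when the state space is small.
#'
#' @param x a [genotype_table] (with `locus` given) or a symmetric genotype
#'   count matrix (entry `[i, j]`, `i <= j` = individuals with genotype i/j).
#' @param locus locus name or index when `x` is a table.
#' @param mode `"auto"`, `"enumerate"` or `"mc"`.
#' @param n_batches number of Monte-Carlo shuffles for `mode = "mc"`.
#' @param seed RNG seed for the Monte-Carlo mode.
#' @return list of class `hwe_test`: `p_value`, `method`, `n_batches`,
#'   `log_kernel_obs`.
#' @export
hwe_exact_test <- function(x, locus = NULL, mode = c("auto", "enumerate", "mc"),
                           n_batches = 2000L, seed = 1L) {
  mode <- match.arg(mode)
  gm <- if (inherits(x, "genotype_table")) {
    l <- if (is.character(locus)) match(locus, x$loci) else as.integer(locus)
    .genotype_count_matrix(x, l)
  } else {
    gm0 <- as.matrix(x)
    gm0[upper.tri(gm0)] <- gm0[upper.tri(gm0)] + t(gm0)[upper.tri(gm0)]
    gm0[lower.tri(gm0)] <- 0L           # fold onto upper triangle
    storage.mode(gm0) <- "integer"
    gm0
  }
  k <- nrow(gm)
  n <- sum(gm)
  m <- integer(k)                        # allele copy counts
  for (i in seq_len(k)) m[i] <- 2L * gm[i, i] +
    sum(gm[i, seq_len(k) > i]) + sum(gm[seq_len(k) < i, i])
  if (sum(m > 0L) < 2L) {
    return(structure(list(p_value = 1, method = "monomorphic",
                          n_batches = 0L, log_kernel_obs = NA_real_),
                     class = "hwe_test"))
  }
  if (n < 2L) stop("need >= 2 individuals")
  obs <- .hwe_log_kernel(gm)
  tol <- 1e-9
  if (mode == "auto")
    mode <- if (n <= 12L && k <= 4L) "enumerate" else "mc"
  if (mode == "enumerate") {
    num <- 0; den <- 0
    .hwe_enumerate(m, function(g) {
      lk <- .hwe_log_kernel(g)
      w <- exp(lk)
      den <<- den + w
      if (lk <= obs + tol) num <<- num + w
    })
    p <- num / den
    return(structure(list(p_value = p, method = "enumerate",
                          n_batches = 0L, log_kernel_obs = obs),
                     class = "hwe_test"))
  }
  # MC: shuffle the pool of gene copies into n random genotypes
  set.seed(as.integer(seed))
  copies <- rep.int(seq_len(k), m)
  hits <- 0L
  for (b in seq_len(n_batches)) {
    perm <- sample(copies)
    i1 <- pmin(perm[seq_len(n)], perm[n + seq_len(n)])
    i2 <- pmax(perm[seq_len(n)], perm[n + seq_len(n)])
    # kernel without building the full matrix
    het <- sum(i1 != i2)
    key <- (i1 - 1L) * k + i2
    lk <- het * log(2) - sum(lfactorial(tabulate(key, k * k)))
    if (lk <= obs + tol) hits <- hits + 1L
  }
  structure(list(p_value = hits / n_batches, method = "mc",
                 n_batches = as.integer(n_batches), log_kernel_obs = obs),
            class = "hwe_test")
}

#' @export
print.hwe_test <- function(x, ...) {
  cat(sprintf("HWE exact test (%s): p = %.4g\n", x$method, x$p_value))
  invisible(x)
}

#' Permutation test for genotypic disequilibrium between two loci
#'
#' Log-likelihood-ratio G statistic on the genotype-by-genotype contingency
#' table; significance by permuting one locus's genotypes across individuals
#' (p includes the observed arrangement, so the smallest attainable value is
#' `1/(n_perm + 1)`).
#' When several samples are supplied the per-sample G statistics are summed
#' (a global test) and permutation is performed within samples.
#'
#' @param tables a [genotype_table] or list of them.
#' @param loci length-2 vector of locus names or indices.
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed.
#' @return list of class `ld_test`: `statistic` (observed G), `p_value`,
#'   `n_perm`.
#' @export
pairwise_ld_test <- function(tables, loci, n_perm = 1000L, seed = 1L) {
  if (inherits(tables, "genotype_table")) tables <- list(tables)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  g_stat <- function(f1, f2) {
    tb <- table(f1, f2)
    n <- sum(tb)
    e <- outer(rowSums(tb), colSums(tb)) / n
    idx <- tb > 0
    2 * sum(tb[idx] * log(tb[idx] / e[idx]))
  }
  geno_factor <- function(tab, l) {
    li <- if (is.character(l)) match(l, tab$loci) else as.integer(l)
    a1 <- tab$calls[, li, 1L]; a2 <- tab$calls[, li, 2L]
    paste(pmin(a1, a2), pmax(a1, a2))
  }
  pairs <- lapply(tables, function(tab) {
    f1 <- geno_factor(tab, loci[1L]); f2 <- geno_factor(tab, loci[2L])
    ok <- !grepl("NA", f1) & !grepl("NA", f2)
    if (sum(ok) < 2L) stop("fewer than 2 usable individuals in a sample")
    list(f1 = f1[ok], f2 = f2[ok])
  })
  obs <- sum(vapply(pairs, function(p) g_stat(p$f1, p$f2), 0))
  set.seed(as.integer(seed))
  ge <- 0L
  for (b in seq_len(n_perm)) {
    g <- sum(vapply(pairs, function(p) g_stat(p$f1, sample(p$f2)), 0))
    if (g >= obs - 1e-9) ge <- ge + 1L
  }
  structure(list(statistic = obs, p_value = (ge + 1L) / (n_perm + 1L),
                 n_perm = as.integer(n_perm)), class = "ld_test")
}

#' @export
print.ld_test <- function(x, ...) {
  cat(sprintf("genotypic disequilibrium G = %.3f, permutation p = %.4g (%d perms)\n",
              x$statistic, x$p_value, x$n_perm))
  invisible(x)
}

#' Sequential Bonferroni (Holm) correction
#'
#' Sorts p-values ascending and rejects `p_(i)` while
#' `p_(i) <= alpha / (k - i + 1)`, stopping at the first failure.
#'
#' @param p p-values in `[0, 1]`.
#' @param alpha family-wise error rate.
#' @return logical rejection flags in the original order.
#' @export
sequential_bonferroni <- function(p, alpha = 0.05) {
  if (length(p) == 0L) return(logical(0))
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  k <- length(p)
  ord <- order(p)
  rej <- logical(k)
  for (i in seq_len(k)) {
    if (p[ord[i]] <= alpha / (k - i + 1)) rej[ord[i]] <- TRUE else break
  }
  rej
}
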