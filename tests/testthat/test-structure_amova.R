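test_that("Weir-Cockerham theta: fixation, null and hand-oracle cases", {
  f1 <- genotype_table(array(2L, dim = c(12, 1, 2)), sample_id = "f1")
  f2 <- genotype_table(array(4L, dim = c(12, 1, 2)), sample_id = "f2")
  expect_equal(weir_cockerham_fst(list(f1, f2))$theta, 1)
  # identical frequency spectra, equal n: theta near zero (may be negative)
  s1 <- hw_table(200, c(0.5, 0.5), seed = 1, sample_id = "a")
  s2 <- hw_table(200, c(0.5, 0.5), seed = 2, sample_id = "b")
  expect_lt(abs(weir_cockerham_fst(list(s1, s2))$theta), 0.02)
  # independent brute-force evaluation of the a, b, c component formulas
  wc_oracle <- function(d1, d2) {
    dat <- list(d1, d2); r <- 2
    ns <- vapply(dat, nrow, 1L); nbar <- mean(ns)
    nc <- (r * nbar - sum(ns^2) / (r * nbar)) / (r - 1)
    tot <- c(0, 0, 0)
    for (al in sort(unique(c(d1, d2)))) {
      p <- vapply(dat, function(d) mean(d == al), 0)
      h <- vapply(dat, function(d) mean((d[, 1] == al) != (d[, 2] == al)), 0)
      pb <- sum(ns * p) / (r * nbar)
      s2v <- sum(ns * (p - pb)^2) / ((r - 1) * nbar)
      hb <- sum(ns * h) / (r * nbar)
      a <- nbar / nc * (s2v - (pb * (1 - pb) - (r - 1) / r * s2v - hb / 4) / (nbar - 1))
      b <- nbar / (nbar - 1) * (pb * (1 - pb) - (r - 1) / r * s2v -
                                  (2 * nbar - 1) / (4 * nbar) * hb)
      tot <- tot + c(a, b, hb / 2)
    }
    tot[1] / sum(tot)
  }
  d1 <- cbind(c(1, 1, 2, 2, 1, 2, 1), c(1, 2, 2, 2, 1, 1, 1))
  d2 <- cbind(c(2, 2, 2, 1, 2), c(2, 2, 1, 1, 2))
  t1 <- genotype_table(array(c(d1[, 1], d1[, 2]), dim = c(7, 1, 2)), sample_id = "x")
  t2 <- genotype_table(array(c(d2[, 1], d2[, 2]), dim = c(5, 1, 2)), sample_id = "y")
  expect_equal(weir_cockerham_fst(list(t1, t2))$theta, wc_oracle(d1, d2),
               tolerance = 1e-12)
  expect_error(weir_cockerham_fst(list(f1, f1)), "monomorphic")
})

test_that("two-level AMOVA F_ST reproduces Weir-Cockerham theta exactly", {
  tabs <- lapply(1:3, function(i) rand_table(15 + 5 * i, L = 3, k = 4,
                                             seed = 20 + i,
                                             sample_id = paste0("s", i)))
  th <- weir_cockerham_fst(tabs)$theta
  am <- amova_three_level(tabs, groups = NULL, n_perm = 0)
  expect_equal(am$indices[["F_ST"]], th, tolerance = 1e-10)
})

test_that("three-level AMOVA recovers extreme and null structure", {
  # groups fixed for disjoint alleles: F_CT ~ 1 with p at the attainable
  # floor (whole samples are the permutable units for F_CT, so the floor is
  # the chance of redrawing an equivalent partition of the 8 samples)
  mk_fixed <- function(al, sid)
    genotype_table(array(al, dim = c(10, 1, 2)), sample_id = sid)
  tabs <- c(lapply(1:4, function(i) mk_fixed(2L, paste0("a", i))),
            lapply(1:4, function(i) mk_fixed(8L, paste0("b", i))))
  am <- amova_three_level(tabs, groups = rep(c("g1", "g2"), each = 4),
                          n_perm = 400, seed = 3)
  expect_gt(am$indices[["F_CT"]], 0.95)
  expect_lt(am$p_values[["F_CT"]], 0.06)
  # panmictic pool: all indices near zero
  tabs0 <- lapply(1:4, function(i) hw_table(60, c(0.4, 0.35, 0.25),
                                            seed = 40 + i,
                                            sample_id = paste0("p", i)))
  am0 <- amova_three_level(tabs0, groups = c(1, 1, 2, 2), n_perm = 50, seed = 1)
  expect_lt(max(abs(am0$indices)), 0.03)
  expect_error(amova_three_level(tabs0, groups = c(1, 1, 1, 1)), ">= 2 groups")
})

test_that("haploid AMOVA components equal a brute-force sums-of-squares oracle", {
  set.seed(12)
  haps <- lapply(1:3, function(i)
    haplotype_table(sample(LETTERS[1:4], 8 + 2 * i, TRUE),
                    sample_id = paste0("h", i)))
  groups <- c(1, 1, 2)
  am <- amova_three_level(haps, groups, mode = "haploid_distance", n_perm = 0)
  # oracle: direct pairwise-distance sums of squares and EMS solution
  items <- unlist(lapply(haps, function(h) h$haplotype))
  samp <- rep(1:3, vapply(haps, function(h) length(h$haplotype), 1L))
  d2 <- function(a, b) as.numeric(a != b)
  ssd_set <- function(idx) {
    if (length(idx) < 2) return(0)
    pr <- utils::combn(idx, 2)
    sum(d2(items[pr[1, ]], items[pr[2, ]])) / length(idx)
  }
  N <- length(items); S <- 3; G <- 2
  ssd_tot <- ssd_set(seq_len(N))
  ssd_ws <- sum(vapply(1:3, function(s) ssd_set(which(samp == s)), 0))
  ssd_wg <- ssd_set(which(samp %in% c(1, 2))) + ssd_set(which(samp == 3))
  ns <- table(samp); ng <- c(sum(ns[1:2]), ns[3])
  sumr <- sum(ns[1:2]^2) / ng[1] + ns[3]^2 / ng[2]
  n1 <- (N - sumr) / (S - G)
  n2 <- (sumr - sum(ns^2) / N) / (G - 1)
  n3 <- (N - sum(ng^2) / N) / (G - 1)
  sc <- ssd_ws / (N - S)
  sb <- ((ssd_wg - ssd_ws) / (S - G) - sc) / n1
  sa <- ((ssd_tot - ssd_wg) / (G - 1) - sc - n2 * sb) / n3
  expect_equal(unname(am$components),
               unname(c(sa, sb, sc)), tolerance = 1e-10)
  # indices are computed from the raw (possibly negative) components
  expect_equal(am$indices[["F_CT"]], unname(sa / (sa + sb + sc)),
               tolerance = 1e-10)
})
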