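test_that("Nei-Tajima Fc matches hand evaluation and its symmetries", {
  tps <- temporal_pair_stats(list(c(0.5, 0.5)), list(c(0.6, 0.4)),
                             t = 1, S0 = 50, St = 50, ploidy = 2)
  expect_equal(temporal_fc(tps)$Fc, 0.04, tolerance = 1e-12)
  # x = y gives zero
  tps0 <- temporal_pair_stats(list(c(0.3, 0.7)), list(c(0.3, 0.7)),
                              t = 1, S0 = 50, St = 50, ploidy = 2)
  expect_equal(temporal_fc(tps0)$Fc, 0)
  # relabeling (allele order) and sample-swap invariance
  tps_r <- temporal_pair_stats(list(c(0.5, 0.5)), list(c(0.4, 0.6)),
                               t = 1, S0 = 50, St = 50, ploidy = 2)
  expect_equal(temporal_fc(tps_r)$Fc, temporal_fc(tps)$Fc, tolerance = 1e-12)
  tps_s <- temporal_pair_stats(list(c(0.6, 0.4)), list(c(0.5, 0.5)),
                               t = 1, S0 = 50, St = 50, ploidy = 2)
  expect_equal(temporal_fc(tps_s)$Fc, temporal_fc(tps)$Fc, tolerance = 1e-12)
  # alleles absent at both times are dropped, not propagated as NaN
  tps_d <- temporal_pair_stats(list(c(0.5, 0.5, 0)), list(c(0.6, 0.4, 0)),
                               t = 1, S0 = 50, St = 50, ploidy = 2)
  expect_equal(temporal_fc(tps_d)$Fc, 0.04, tolerance = 1e-12)
})

test_that("moments estimator applies the sampling and Plan I corrections", {
  tps <- temporal_pair_stats(list(c(0.5, 0.5)), list(c(0.6, 0.4)),
                             t = 1, S0 = 50, St = 50, ploidy = 2)
  est <- moments_ne(tps)
  expect_equal(est$point, 25, tolerance = 1e-12)   # F' = 0.04 - 0.02
  expect_true(est$ci_low <= est$point && est$point <= est$ci_high)
  # Plan I with enormous census converges to Plan II
  tpsI <- temporal_pair_stats(list(c(0.5, 0.5)), list(c(0.6, 0.4)), t = 1,
                              plan = "I", census_N = 1e6,
                              S0 = 50, St = 50, ploidy = 2)
  expect_lt(abs(moments_ne(tpsI)$point - 25) / 25, 1e-4)
  expect_error(temporal_pair_stats(list(c(0.5, 0.5)), list(c(0.6, 0.4)),
                                   t = 0, S0 = 50, St = 50, ploidy = 2),
               "t must")
  expect_error(temporal_pair_stats(list(c(0.5, 0.5)), list(c(0.6, 0.4)),
                                   t = 1, plan = "I", S0 = 50, St = 50,
                                   ploidy = 2),
               "census_N")
})

test_that("Fs statistic and its corrected estimator follow the pooled form", {
  tps <- temporal_pair_stats(list(c(0.5, 0.5)), list(c(0.6, 0.4)),
                             t = 1, S0 = 50, St = 50, ploidy = 2)
  est <- tempofs_ne(tps)
  expect_equal(est$Fs, 0.02 / 0.495, tolerance = 1e-12)
  expect_equal(est$flags, "single locus: jackknife CI undefined")
  # multi-locus: numerators and denominators pool, jackknife CI brackets
  xs <- list(c(0.5, 0.5), c(0.3, 0.7), c(0.25, 0.5, 0.25))
  ys <- list(c(0.58, 0.42), c(0.36, 0.64), c(0.3, 0.45, 0.25))
  tpsm <- temporal_pair_stats(xs, ys, t = 1, S0 = 60, St = 60, ploidy = 2)
  estm <- tempofs_ne(tpsm)
  num <- sum((unlist(xs) - unlist(ys))^2)
  den <- sum(((unlist(xs) + unlist(ys)) / 2) * (1 - (unlist(xs) + unlist(ys)) / 2))
  expect_equal(estm$Fs, num / den, tolerance = 1e-12)
  expect_true(estm$ci_low <= estm$point && estm$point <= estm$ci_high)
})

test_that("haploid moments estimator uses sequence-count sampling terms", {
  tps <- temporal_pair_stats(list(c(0.5, 0.5)), list(c(0.6, 0.4)),
                             t = 1, S0 = 100, St = 100, ploidy = 1)
  expect_equal(haploid_moments_nef(tps)$point, 50, tolerance = 1e-12)
  tps0 <- temporal_pair_stats(list(c(0.5, 0.5)), list(c(0.5, 0.5)),
                              t = 2, S0 = 100, St = 100, ploidy = 1)
  expect_equal(haploid_moments_nef(tps0)$point, Inf)
})

test_that("pseudo-likelihood estimator brackets the moments estimate on a toy pair", {
  tps <- temporal_pair_stats(list(c(0.5, 0.5)), list(c(0.6, 0.4)),
                             t = 1, S0 = 50, St = 50, ploidy = 2)
  est <- mlne_ne(tps, ne_grid = exp(seq(log(5), log(5000), length.out = 60)))
  expect_true(est$point > 12.5 && est$point < 50)  # within factor 2 of 25
  expect_true(est$ci_low <= est$point)
  expect_error(mlne_ne(tps, freq_bins = 32), ">= 64")
})

test_that("infinity semantics: no drift signal means +Inf, never negative", {
  x <- list(c(0.5, 0.3, 0.2), c(0.6, 0.4))
  tps <- temporal_pair_stats(x, x, t = 1, S0 = 500, St = 500, ploidy = 2)
  expect_equal(moments_ne(tps)$point, Inf)
  expect_equal(tempofs_ne(tps)$point, Inf)
  ml <- mlne_ne(tps, ne_grid = exp(seq(log(10), log(2000), length.out = 30)))
  expect_equal(ml$point, Inf)
  expect_equal(ml$flags, "maximum at upper grid bound")
  # moments point estimates are never reported negative
  for (seed in 1:20) {
    set.seed(seed)
    xr <- runif(1, 0.2, 0.8)
    tpsr <- temporal_pair_stats(list(c(xr, 1 - xr)),
                                list(c(xr, 1 - xr) + c(0.001, -0.001)),
                                t = 1, S0 = 30, St = 30, ploidy = 2)
    expect_true(moments_ne(tpsr)$point > 0)
  }
})

test_that("overlapping-generation correction rescales point and interval", {
  tps <- temporal_pair_stats(list(c(0.5, 0.5)), list(c(0.6, 0.4)),
                             t = 1, S0 = 50, St = 50, ploidy = 2)
  est <- moments_ne(tps)
  same <- overlap_correction(est, C = 1.27, G = 1.27)
  expect_equal(same$point, est$point)
  dbl <- overlap_correction(est, C = 2.54, G = 1.27)
  expect_equal(dbl$point, 2 * est$point)
  expect_equal(dbl$ci_low, 2 * est$ci_low)
  inf_est <- overlap_correction(
    moments_ne(temporal_pair_stats(list(c(0.4, 0.6)), list(c(0.4, 0.6)),
                                   t = 1, S0 = 50, St = 50, ploidy = 2)),
    C = 1.1, G = 1.27)
  expect_equal(inf_est$point, Inf)
  expect_error(overlap_correction(est, C = 0, G = 1.27), "positive")
})

test_that("broodstock effective size follows the unequal-sex-ratio formula", {
  expect_equal(broodstock_ne(10, 10), 20)
  expect_equal(broodstock_ne(1, 3), 3)
  expect_equal(broodstock_ne(1, 1), 2)
  Nm <- c(3, 7); Nf <- c(9, 2)
  expect_equal(broodstock_ne(Nm, Nf), 4 * Nm * Nf / (Nm + Nf), tolerance = 1e-15)
  expect_lte(broodstock_ne(2, 1000), 4 * 2)
  expect_error(broodstock_ne(0, 5), ">= 1")
})

test_that("LD method reproduces the bias correction and inversion arithmetic", {
  expect_equal(tempomon:::.ld_expected_r2(100), 1 / 100 + 3.19 / 1e4,
               tolerance = 1e-15)
  expect_equal(tempomon:::.ld_expected_r2(20),
               0.0018 + 0.907 / 20 + 4.44 / 400, tolerance = 1e-15)
  r2p <- 0.03 - tempomon:::.ld_expected_r2(100)
  expect_equal(r2p, 0.019681, tolerance = 1e-12)
  expect_equal(tempomon:::.ld_invert(r2p, 100), 14.52, tolerance = 5e-3)
  expect_equal(tempomon:::.ld_invert(0, 100), Inf)
  expect_equal(tempomon:::.ld_invert(0.2, 100), 0)  # below estimable minimum
  expect_error(ld_ne(rand_table(5, seed = 1)), ">= 10")
  expect_error(ld_ne(rand_table(30, L = 1, seed = 1)), "fewer than 2")
})

test_that("estimators are invariant to sample swap and recover a simulated truth", {
  cfg <- scenario_presets("isolated_wf")
  sim <- simulate_population(cfg, seed = 77)
  tps <- temporal_pair_stats(sim$genotypes[[1]], sim$genotypes[[2]], t = 2)
  tps_sw <- temporal_pair_stats(sim$genotypes[[2]], sim$genotypes[[1]], t = 2)
  expect_equal(temporal_fc(tps)$Fc, temporal_fc(tps_sw)$Fc, tolerance = 1e-12)
  # small-batch median recovery (the full-scale check lives in the
  # acceptance suite)
  meds <- vapply(1:25, function(i) {
    s <- simulate_population(cfg, seed = 500 + i)
    tp <- temporal_pair_stats(s$genotypes[[1]], s$genotypes[[2]], t = 2)
    tempofs_ne(tp)$point
  }, 0)
  expect_gt(median(meds), 60)
  expect_lt(median(meds), 160)
})
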