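test_that("CPUE transform and runoff scoring follow the published rules", {
  expect_equal(transform_cpue(0), 0)
  expect_equal(transform_cpue(99), 2)
  v <- c(3, 0.5, 12)
  expect_equal(transform_cpue(v), log10(v + 1))
  expect_error(transform_cpue(-1), "nonnegative")
  mk_flow <- function(d) c(rep(4000, d), rep(1000, 61 - d))
  expect_equal(runoff_score(mk_flow(10)), 10)
  expect_equal(runoff_score(mk_flow(20)), 15)
  expect_equal(runoff_score(mk_flow(35)), 20)
  expect_equal(runoff_score(mk_flow(14)), 10)   # boundary: d = 14 -> low class
  expect_equal(runoff_score(mk_flow(30)), 15)   # boundary: d = 30 -> mid class
  expect_error(runoff_score(rep(4000, 60)), "61")
  expect_error(runoff_score(c(NA, rep(1, 60))), "missing")
})

test_that("series alignment matches the generation-lag pairing convention", {
  # temporal estimate labelled 2000 (2000-2001 samples) pairs with env 1999
  ne <- data.frame(year = 2000:2004, value = c(115, 80, 90, 433, 120))
  env <- data.frame(year = 1998:2003, value = 1:6)
  p1 <- align_series(ne, env, lag = 1)
  expect_equal(p1$year[p1$metric == 115], 1999)
  expect_equal(p1$env, env$value[match(p1$year, env$year)])
  # LD estimate from the 2000 sample refers to 1999 parents -> env 1998
  ld <- data.frame(year = 2000, value = 500)
  p2 <- align_series(ld, env, lag = 2)
  expect_equal(p2$year, 1998)
  # lag 0 is the identity pairing
  p0 <- align_series(ne, data.frame(year = 2000:2004, value = 11:15), lag = 0)
  expect_equal(p0$metric, ne$value)
  expect_error(align_series(ne, data.frame(year = 1900:1903, value = 1:4), 1),
               "empty intersection")
})

test_that("correlation tests rank correctly and exclude infinities loudly", {
  mono <- data.frame(metric = 1:6, env = c(2, 5, 9, 11, 20, 30))
  expect_equal(correlation_tests(mono, "spearman")$statistic, 1)
  anti <- data.frame(metric = 1:6, env = rev(c(2, 5, 9, 11, 20, 30)))
  expect_equal(correlation_tests(anti, "spearman")$statistic, -1)
  # hand-ranked oracle on a 5-point table
  tb <- data.frame(metric = c(3, 10, 1, 7, 5), env = c(2.2, 0.1, 5, 1, 9))
  rho_hand <- 1 - 6 * sum((rank(tb$metric) - rank(tb$env))^2) / (5 * 24)
  expect_equal(correlation_tests(tb, "spearman")$statistic, rho_hand,
               tolerance = 1e-12)
  withinf <- data.frame(metric = c(1, 2, Inf, 4, 5), env = c(5, 4, 3, 2, 1))
  ct <- correlation_tests(withinf, "spearman")
  expect_equal(ct$n_excluded, 1)
  expect_equal(ct$n, 4)
  under <- correlation_tests(data.frame(metric = c(1, Inf, Inf), env = 1:3))
  expect_true(under$underpowered)
  expect_true(is.na(under$p_value))
  # OLS variant reports slope / r^2
  ols <- suppressWarnings(
    correlation_tests(data.frame(metric = 1:8, env = 2 * (1:8) + 3), "ols"))
  expect_equal(ols$statistic, 2, tolerance = 1e-10)
  expect_equal(ols$r_squared, 1, tolerance = 1e-10)
})

test_that("era comparison reproduces exact Mann-Whitney enumeration on 3-vs-3 toys", {
  m <- data.frame(year = c(2001:2003, 2004:2006), Hec = c(0.6, 0.55, 0.72, 0.8, 0.67, 0.74))
  res <- pre_post_comparison(m, split_year = 2004, exact = TRUE)
  expect_equal(res$p_value,
               enumerate_mw_p(m$Hec[1:3], m$Hec[4:6]), tolerance = 1e-12)
  # fully separated eras attain the minimal U and smallest p
  sep <- data.frame(year = c(2001:2003, 2004:2006), x = c(1, 2, 3, 10, 11, 12))
  rs <- pre_post_comparison(sep, 2004, exact = TRUE)
  expect_equal(rs$U, 0)
  expect_equal(rs$p_value, enumerate_mw_p(c(1, 2, 3), c(10, 11, 12)),
               tolerance = 1e-12)
  expect_error(pre_post_comparison(m[c(1, 4:6), ], 2004), ">= 2 years")
})

test_that("broodstock regression recovers a noise-free slope and screens infinities", {
  bne <- c(10, 14, 20, 26, 30, 40)
  fit <- suppressWarnings(broodstock_regression(bne, 0.5 * bne))
  expect_equal(fit$slope, 0.5, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  fit2 <- suppressWarnings(broodstock_regression(c(bne, 35), c(0.5 * bne, Inf)))
  expect_equal(fit2$n_excluded, 1)
  expect_error(broodstock_regression(rep(10, 5), runif(5)), "degenerate")
  expect_error(broodstock_regression(c(10, 20, 30), rep(Inf, 3)), "infinite")
})

test_that("simulated captive lots yield a positive broodstock-NeD relationship", {
  set.seed(31)
  batches <- vapply(1:5, function(b) {
    sizes <- cbind(Nm = sample(3:25, 10), Nf = sample(3:25, 10))
    ned <- bne <- numeric(10)
    for (i in 1:10) {
      src <- hw_table(200, rep(1 / 8, 8), seed = 100 * b + i)
      # 9-locus broodstock pool drawn from a diverse base population
      base <- rand_table(300, L = 9, k = 8, seed = 200 * b + i)
      nb <- sizes[i, 1] + sizes[i, 2]
      bidx <- sample(300, nb)
      geno <- matrix(0L, nb, 18)
      for (l in 1:9) {
        geno[, 2 * l - 1] <- base$calls[bidx, l, 1]
        geno[, 2 * l] <- base$calls[bidx, l, 2]
      }
      lot <- simulate_lot(list(geno = geno, mt = rep(1L, nb)),
                          sizes[i, 1], sizes[i, 2], lot_size = 60,
                          design = "paired")
      calls <- array(NA_integer_, dim = c(60, 9, 2))
      for (l in 1:9) {
        calls[, l, 1] <- lot$geno[, 2 * l - 1]
        calls[, l, 2] <- lot$geno[, 2 * l]
      }
      tab <- genotype_table(calls, sample_id = "lot")
      ned[i] <- ld_ne(tab, Pcrit = 0.02)$point
      bne[i] <- broodstock_ne(sizes[i, 1], sizes[i, 2])
    }
    broodstock_regression(bne, pmin(ned, 1e4))$slope
  }, 0)
  expect_gte(mean(batches > 0), 0.9)
})

test_that("Kruskal-Wallis by reach matches hand rank computation", {
  m <- data.frame(reach = rep(c("Angostura", "Isleta", "SanAcacia"), each = 3),
                  Hec = c(0.71, 0.75, 0.70, 0.80, 0.82, 0.78, 0.74, 0.77, 0.73))
  res <- kruskal_wallis_by_reach(m)
  r <- rank(m$Hec)
  H_hand <- 12 / (9 * 10) * sum(tapply(r, m$reach, sum)^2 / 3) - 3 * 10
  expect_equal(res$H, H_hand, tolerance = 1e-10)
  same <- data.frame(reach = rep(c("a", "b"), each = 4), x = rep(c(1, 2, 3, 4), 2))
  expect_lt(kruskal_wallis_by_reach(same)$H, 0.1)
  disj <- data.frame(reach = rep(c("a", "b"), each = 4), x = c(1:4, 11:14))
  expect_gt(kruskal_wallis_by_reach(disj)$H, 5)
  expect_error(kruskal_wallis_by_reach(data.frame(reach = "a", x = 1)),
               ">= 2 reaches")
})
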