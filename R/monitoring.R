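# --- Demography / environment / supplementation association tests ---------

#' Log-transform a CPUE (density) series
#'
#' Default `log10(x + 1)`; the base and offset are configurable.
#'
#' @param cpue nonnegative catch-per-unit-effort values.
#' @param base logarithm base (10 or `exp(1)`).
#' @param offset added before taking logs.
#' @return transformed vector, order preserved.
#' @export
transform_cpue <- function(cpue, base = 10, offset = 1) {
  if (any(cpue < 0, na.rm = TRUE)) stop("CPUE must be nonnegative")
  log(cpue + offset, base = base)
}

#' Categorical spring-runoff score from daily discharge
#'
#' Scores the May 1 - June 30 hydrograph by the number of days `d` with
#' discharge above `threshold` (cfs): 10 when `d <= 14`, 15 when
#' `14 < d <= 30`, 20 when `d > 30`. (A duration of exactly 30 days falls in
#' the middle class; the published rule leaves that boundary open and the
#' closed upper bound is this implementation's convention.)
#'
#' @param daily_discharge numeric vector of length 61 (May 1 - June 30 daily
#'   mean discharge, cfs).
#' @param threshold discharge threshold in cfs.
#' @return one of 10, 15, 20.
#' @export
runoff_score <- function(daily_discharge, threshold = 3000) {
  if (length(daily_discharge) != 61L)
    stop("daily_discharge must cover May 1 - June 30 (61 days)")
  if (anyNA(daily_discharge)) stop("missing days in discharge series")
  d <- sum(daily_discharge > threshold)
  if (d > 30) 20 else if (d > 14) 15 else 10
}

#' Lag-pair a genetic metric series with an environmental series
#'
#' Pairs the metric labelled year `t + lag` with the environmental record of
#' year `t`: the spawning conditions of year `t` shape the generation whose
#' effective size a temporal estimate labelled `t + 1` measures (`lag = 1`),
#' while a single-sample LD estimate labelled `t + 2` refers to parents
#' recruited under the conditions of year `t` (`lag = 2`). For example, a
#' temporal estimate from the 2000 and 2001 samples (labelled 2000) pairs
#' with the 1999 runoff and autumn-density records, and the LD estimate from
#' the 2000 sample pairs with 1998.
#'
#' @param metric data.frame with columns `year`, `value`.
#' @param env data.frame with columns `year`, `value`.
#' @param lag nonnegative integer year lag.
#' @return data.frame `(year, metric, env)` where `year` is the environment
#'   year and `metric` the metric value labelled `year + lag`; years lacking
#'   either value are dropped and the dropped count is attached as attribute
#'   `"n_dropped"`.
#' @export
align_series <- function(metric, env, lag = 1L) {
  m <- data.frame(year = metric$year - lag, metric = metric$value)
  e <- data.frame(year = env$year, env = env$value)
  out <- merge(m, e, by = "year")
  n_merged <- nrow(out)
  out <- out[stats::complete.cases(out), , drop = FALSE]
  if (nrow(out) == 0L) stop("empty intersection after lagging")
  attr(out, "n_dropped") <- n_merged - nrow(out)
  rownames(out) <- NULL
  out
}

# drop non-finite metric values with an explicit report (infinite Ne must
# never silently enter rank or OLS computations)
.finite_pairs <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  list(x = x[ok], y = y[ok], n_excluded = sum(!ok))
}

#' Correlation between a paired metric and environmental series
#'
#' Spearman rank correlation or OLS regression on the finite pairs; infinite
#' Ne entries are excluded and the exclusion count reported.
#'
#' @param paired data.frame from [align_series] (columns `metric`, `env`), or
#'   any two-column pairing.
#' @param method `"spearman"` or `"ols"`.
#' @return list with `statistic` (rho or slope), `p_value`, `n`, `df`,
#'   `n_excluded`; for `"ols"` also `intercept` and `r_squared`. When fewer
#'   than 4 finite pairs remain the test is flagged underpowered and no p is
#'   computed.
#' @export
correlation_tests <- function(paired, method = c("spearman", "ols")) {
  method <- match.arg(method)
  fp <- .finite_pairs(paired$metric, paired$env)
  n <- length(fp$x)
  if (n < 4L) {
    return(list(statistic = NA_real_, p_value = NA_real_, n = n,
                df = NA_integer_, n_excluded = fp$n_excluded,
                underpowered = TRUE))
  }
  if (method == "spearman") {
    ct <- suppressWarnings(stats::cor.test(fp$x, fp$y, method = "spearman",
                                           exact = FALSE))
    list(statistic = unname(ct$estimate), p_value = ct$p.value, n = n,
         df = n - 2L, n_excluded = fp$n_excluded, underpowered = FALSE)
  } else {
    fit <- stats::lm(y ~ x, data = data.frame(x = fp$x, y = fp$y))
    sm <- summary(fit)
    list(statistic = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = sm$r.squared,
         p_value = sm$coefficients[2L, 4L], n = n, df = n - 2L,
         n_excluded = fp$n_excluded, underpowered = FALSE)
  }
}

#' Pre- versus post-supplementation comparison of diversity metrics
#'
#' Mann-Whitney U tests of year-level diversity metrics between the era
#' before supplementation and the era from `split_year` (inclusive) onwards.
#'
#' @param metrics data.frame with a `year` column and one column per metric.
#' @param split_year first year of the "after" era.
#' @param exact logical: exact p where possible (no ties, small n), else
#'   normal approximation.
#' @return data.frame with one row per metric: `metric`, `U`, `p_value`,
#'   `n_before`, `n_after`.
#' @export
pre_post_comparison <- function(metrics, split_year = 2004L, exact = NULL) {
  before <- metrics$year < split_year
  after <- !before
  if (sum(before) < 2L || sum(after) < 2L)
    stop("each era needs >= 2 years")
  cols <- setdiff(names(metrics), "year")
  res <- lapply(cols, function(cl) {
    x <- metrics[[cl]][before]; y <- metrics[[cl]][after]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact))
    data.frame(metric = cl, U = unname(wt$statistic), p_value = wt$p.value,
               n_before = length(x), n_after = length(y))
  })
  do.call(rbind, res)
}

#' OLS regression of LD-based Ne on broodstock effective size
#'
#' Tests whether the effective number of breeders used to found captive lots
#' predicts the single-sample (LD) Ne estimated from the lots' progeny.
#' Infinite Ne estimates are excluded and counted.
#'
#' @param broodstock_ne effective broodstock size per lot (see
#'   [broodstock_ne]).
#' @param ne_d LD-based Ne estimate per lot.
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`, `df`,
#'   `n_excluded`.
#' @export
broodstock_regression <- function(broodstock_ne, ne_d) {
  fp <- .finite_pairs(broodstock_ne, ne_d)
  if (length(fp$x) == 0L) stop("all Ne estimates are infinite or missing")
  if (length(fp$x) < 3L) stop("need >= 3 lots with finite Ne")
  if (length(unique(fp$x)) < 2L) stop("degenerate design: single x value")
  fit <- stats::lm(y ~ x, data = data.frame(x = fp$x, y = fp$y))
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2L, 4L],
       df = fit$df.residual,
       n_excluded = fp$n_excluded)
}

#' Kruskal-Wallis comparison of diversity metrics across river reaches
#'
#' @param metrics data.frame with a `reach` column and one column per metric.
#' @return data.frame with one row per metric: `metric`, `H`, `df`, `p_value`.
#' @export
kruskal_wallis_by_reach <- function(metrics) {
  g <- factor(metrics$reach)
  if (nlevels(g) < 2L) stop("need >= 2 reaches")
  if (any(table(g) < 2L)) stop("each reach needs >= 2 samples")
  cols <- setdiff(names(metrics), "reach")
  res <- lapply(cols, function(cl) {
    kt <- stats::kruskal.test(metrics[[cl]], g)
    data.frame(metric = cl, H = unname(kt$statistic),
               df = unname(kt$parameter), p_value = kt$p.value)
  })
  do.call(rbind, res)
}
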