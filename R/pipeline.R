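# --- End-to-end monitoring pipeline ---------------------------------------

.fmt_ne <- function(v) ifelse(is.infinite(v), "inf",
                              ifelse(is.na(v), "NA", sprintf("%.1f", v)))

.write_tsv <- function(df, path, header_note = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_note)) writeLines(paste0("# ", header_note), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full genetic-monitoring pipeline
#'
#' Orchestrates io -> qc -> diversity -> amova -> ne -> monitor on either a
#' simulation scenario or user-supplied files, writing TSV reports and a
#' reproducibility manifest to `out_dir`.
#'
#' @param config a list. Either `scenario` (preset name) or `sim_config` (a
#'   [sim_config]) for simulated input, or `genepop` + `meta_csv` (+ optional
#'   `haplotype_csvs`, named per sample) for file input. Optional entries:
#'   `n_star` (resampling size; default smallest sample), `B` (subsamples,
#'   default 200), `pcrit` (LD screening, default 0.02), `plan` ("I"/"II",
#'   default "I"), `census_N` (Plan I census, default 1e6), `hwe_batches`
#'   (default 500), `run_mlne` (default TRUE), `mlne_grid` (default 40
#'   log-spaced 10..1e4), `overlap_C`, `overlap_G` (both set: apply
#'   overlapping-generation correction to consecutive-pair estimates),
#'   `env` (data.frame year, cpue, runoff_score) for the monitoring stage,
#'   `split_year` (default 2004).
#' @param out_dir output directory (created if needed).
#' @param seed integer seed governing every stochastic stage.
#' @return invisible list with all stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- proc.time()[["elapsed"]]
  timings <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  log_lines <- character(0)
  logit <- function(...) log_lines <<- c(log_lines, sprintf(...))

  # -- io -------------------------------------------------------------------
  dat <- stage("io", {
    if (!is.null(config$scenario) || !is.null(config$sim_config)) {
      sc <- if (!is.null(config$sim_config)) config$sim_config
            else scenario_presets(config$scenario)
      sim <- simulate_population(sc, seed = seed)
      list(genotypes = sim$genotypes, haplotypes = sim$haplotypes,
           meta = sim$meta, sim = sim)
    } else {
      gts <- read_genepop(config$genepop,
                          allele_digits = config$allele_digits %||% 3L)
      meta <- read_sample_meta_csv(config$meta_csv)
      if (length(gts) != nrow(meta))
        stop("metadata rows do not match POP blocks")
      for (i in seq_along(gts)) gts[[i]]$sample_id <- meta$sample_id[i]
      names(gts) <- meta$sample_id
      haps <- NULL
      if (!is.null(config$haplotype_csvs))
        haps <- lapply(config$haplotype_csvs, read_haplotypes_csv)
      list(genotypes = gts, haplotypes = haps, meta = meta, sim = NULL)
    }
  })
  gts <- dat$genotypes
  meta <- dat$meta
  logit("io: %d samples, %d loci", length(gts), length(gts[[1]]$loci))

  # -- qc -------------------------------------------------------------------
  qc <- stage("qc", {
    rows <- list()
    for (sid in names(gts)) {
      tab <- gts[[sid]]
      for (l in seq_along(tab$loci)) {
        ht <- hwe_exact_test(tab, l, mode = "mc",
                             n_batches = config$hwe_batches %||% 500L,
                             seed = seed + l)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, locus = tab$loci[l], p_hwe = ht$p_value)
      }
    }
    qcdf <- do.call(rbind, rows)
    qcdf$reject_seq_bonferroni <- sequential_bonferroni(qcdf$p_hwe, 0.05)
    qcdf
  })
  logit("qc: %d HWE tests, %d departures after sequential Bonferroni",
        nrow(qc), sum(qc$reject_seq_bonferroni))

  # -- diversity ------------------------------------------------------------
  n_star <- config$n_star %||% min(vapply(gts, function(g) g$n_individuals, 1L))
  B <- config$B %||% 200L
  div <- stage("diversity", {
    rows <- list()
    for (i in seq_along(gts)) {
      sid <- names(gts)[i]
      cd <- resample_corrected(gts[[i]], n_star = n_star, B = B, seed = seed + i)
      if (is.null(cd)) next
      fis <- fis_within(gts[[i]])
      hrow <- data.frame(sample_id = sid, year = meta$year[match(sid, meta$sample_id)],
                         N = gts[[i]]$n_individuals,
                         Hec = cd$Hec, Hoc = cd$Hoc, Nac = cd$Nac,
                         F_IS = fis$mean, h = NA_real_, H_R = NA_real_,
                         n_haps = NA_integer_)
      if (!is.null(dat$haplotypes[[sid]])) {
        ht <- dat$haplotypes[[sid]]
        cnt <- as.integer(table(ht$haplotype, useNA = "no"))
        if (sum(cnt) >= 2) {
          hrow$h <- unbiased_gene_diversity(cnt)
          g_r <- config$hap_rarefaction_g %||% NA
          hrow$H_R <- NA_real_
          hrow$n_haps <- length(cnt)
          hrow$.hap_n <- sum(cnt)
        }
      }
      rows[[sid]] <- hrow
    }
    df <- do.call(rbind, rows)
    # haplotype richness at the smallest haploid sample size across samples
    if (".hap_n" %in% names(df) && any(!is.na(df$.hap_n))) {
      g_def <- config$hap_rarefaction_g %||% min(df$.hap_n, na.rm = TRUE)
      for (sid in rownames(df)) {
        ht <- dat$haplotypes[[sid]]
        if (is.null(ht)) next
        cnt <- as.integer(table(ht$haplotype, useNA = "no"))
        if (sum(cnt) >= g_def) df[sid, "H_R"] <- rarefied_richness(cnt, g_def)
      }
      df$.hap_n <- NULL
    }
    df
  })
  logit("diversity: corrected to n* = %d with B = %d", n_star, B)

  # -- amova ----------------------------------------------------------------
  amova <- stage("amova", {
    grp <- meta$origin[match(names(gts), meta$sample_id)]
    if (length(unique(grp)) < 2L) {
      logit("amova: skipped (single origin group)")
      NULL
    } else {
      amova_three_level(gts, grp, mode = "diploid_freq",
                        n_perm = config$amova_perms %||% 200L, seed = seed)
    }
  })

  # -- ne -------------------------------------------------------------------
  plan <- config$plan %||% "I"
  census_N <- config$census_N %||% 1e6
  ne <- stage("ne", {
    ord <- order(meta$year[match(names(gts), meta$sample_id)])
    sids <- names(gts)[ord]
    yrs <- meta$year[match(sids, meta$sample_id)]
    rows <- list()
    cache <- new.env()
    for (i in seq_along(sids)[-1L]) {
      t_gen <- yrs[i] - yrs[i - 1L]
      tps <- temporal_pair_stats(gts[[sids[i - 1L]]], gts[[sids[i]]],
                                 t = t_gen, plan = plan, census_N = census_N)
      ests <- list(moments = moments_ne(tps), tempofs = tempofs_ne(tps))
      if (isTRUE(config$run_mlne %||% TRUE)) {
        grid <- config$mlne_grid %||% exp(seq(log(10), log(1e4), length.out = 40))
        ests$mlne <- mlne_ne(tps, ne_grid = grid, cache = cache)
      }
      if (!is.null(config$overlap_C) && !is.null(config$overlap_G) && t_gen == 1)
        ests <- lapply(ests, overlap_correction,
                       C = config$overlap_C, G = config$overlap_G)
      for (m in names(ests))
        rows[[length(rows) + 1L]] <- data.frame(
          pair = sprintf("%d-%d", yrs[i - 1L], yrs[i]), year = yrs[i - 1L],
          method = m, Ne = ests[[m]]$point,
          ci_low = ests[[m]]$ci_low, ci_high = ests[[m]]$ci_high)
    }
    for (i in seq_along(sids)) {
      est <- tryCatch(ld_ne(gts[[sids[i]]], Pcrit = config$pcrit %||% 0.02),
                      error = function(e) NULL)
      if (is.null(est)) next
      rows[[length(rows) + 1L]] <- data.frame(
        pair = sids[i], year = yrs[i], method = "ld", Ne = est$point,
        ci_low = est$ci_low, ci_high = est$ci_high)
    }
    do.call(rbind, rows)
  })
  n_inf <- sum(is.infinite(ne$Ne))
  logit("ne: %d estimates, %d infinite (excluded from downstream rank/OLS)",
        nrow(ne), n_inf)

  # -- monitor --------------------------------------------------------------
  monitor <- stage("monitor", {
    if (is.null(config$env)) {
      logit("monitor: skipped (no environmental series)")
      NULL
    } else {
      env <- config$env
      tempo <- ne[ne$method == "moments", ]
      paired <- align_series(
        data.frame(year = tempo$year, value = tempo$Ne),
        data.frame(year = env$year, value = transform_cpue(env$cpue)),
        lag = 1L)
      ct <- correlation_tests(paired, "spearman")
      data.frame(test = "logCPUE_vs_temporalNe_lag1",
                 statistic = ct$statistic, p_value = ct$p_value,
                 n = ct$n, n_excluded = ct$n_excluded)
    }
  })

  # -- reports --------------------------------------------------------------
  cfg_file <- file.path(out_dir, "config.yaml")
  cfg_ser <- config
  cfg_ser$sim_config <- if (!is.null(config$sim_config)) unclass(config$sim_config)
  yaml::write_yaml(list(config = lapply(cfg_ser, function(x)
    if (is.data.frame(x)) as.list(x) else x), seed = seed), cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  note <- sprintf("generated by tempomon run_pipeline, config md5 %s, seed %d",
                  cfg_hash, seed)
  div_out <- div
  .write_tsv(div_out, file.path(out_dir, "diversity.tsv"), note)
  ne_out <- ne
  ne_out$Ne <- .fmt_ne(ne_out$Ne)
  ne_out$ci_low <- .fmt_ne(ne_out$ci_low)
  ne_out$ci_high <- .fmt_ne(ne_out$ci_high)
  .write_tsv(ne_out, file.path(out_dir, "ne.tsv"), note)
  .write_tsv(qc, file.path(out_dir, "qc.tsv"), note)
  if (!is.null(amova))
    .write_tsv(data.frame(index = names(amova$indices),
                          value = unname(amova$indices),
                          p_value = unname(amova$p_values)),
               file.path(out_dir, "amova.tsv"), note)
  if (!is.null(monitor))
    .write_tsv(monitor, file.path(out_dir, "monitor.tsv"), note)
  manifest <- list(config_md5 = cfg_hash, seed = seed,
                   package_version = as.character(utils::packageVersion("tempomon")),
                   n_samples = length(gts),
                   stage_seconds = as.list(timings),
                   total_seconds = round(proc.time()[["elapsed"]] - t_start, 3),
                   log = log_lines)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(diversity = div, ne = ne, qc = qc, amova = amova,
                 monitor = monitor, manifest = manifest, data = dat))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
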