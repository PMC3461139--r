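# --- Forward Wright-Fisher simulator with hatchery supplementation --------

#' Simulation configuration
#'
#' Defines a forward-in-time monoecious Wright-Fisher population with
#' sweepstakes-style family-size variance (gamma-distributed parental
#' reproductive weights; the weight CV sets the Ne/Nc ratio), maternally
#' transmitted mtDNA, optional hatchery supplementation (captive lots bred
#' from small broodstocks taken from an earlier generation), and Plan I
#' temporal sampling (before reproduction, with replacement).
#'
#' @param n_generations number of generations simulated after generation 0.
#' @param Nc census size per generation: scalar or vector of length
#'   `n_generations + 1` (generations 0..n_generations).
#' @param ne_target target effective size per generation (scalar or vector;
#'   `NA`/`NULL` entries give the ideal case, Ne ~ Nc). Must satisfy
#'   `ne_target <= Nc`.
#' @param n_loci,n_alleles microsatellite loci and initial alleles per locus
#'   (initial frequencies Dirichlet-distributed).
#' @param dirichlet_conc concentration of the initial Dirichlet frequencies.
#' @param n_haplotypes initial mtDNA haplotype count.
#' @param mu_msat,mu_mt per-copy mutation rates (stepwise for microsatellites,
#'   infinite-alleles for mtDNA); 0 by default — negligible on a decadal
#'   monitoring horizon.
#' @param phi supplementation schedule: scalar or vector of length
#'   `n_generations`, `phi[g]` = fraction of the breeding pool producing
#'   generation `g` drawn from captive lots (0 = none).
#' @param broodstock_Nm,broodstock_Nf breeders per captive lot.
#' @param mating_design `"paired"` or `"communal"` lot matings.
#' @param lot_size fish per captive lot.
#' @param broodstock_lag generations between broodstock collection and
#'   release of their progeny (captive lots used at generation `g` are bred
#'   from wild adults of generation `g - 1 - broodstock_lag`).
#' @param broodstock_source_gen if set, a fixed generation from which all
#'   broodstock are drawn (a persistent captive pool founded from one egg
#'   collection, as in hatchery programs that keep a founding broodstock);
#'   overrides the sliding `broodstock_lag`.
#' @param sample_generations,sample_size Plan I sampling schedule: which
#'   generations are sampled and how many fish per sample (recycled).
#' @param first_year calendar year assigned to generation 0 (samples get
#'   `first_year + generation`).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_generations, Nc, ne_target = NULL,
                       n_loci = 9L, n_alleles = 8L, dirichlet_conc = 1,
                       n_haplotypes = 15L, mu_msat = 0, mu_mt = 0,
                       phi = 0, broodstock_Nm = 15L, broodstock_Nf = 15L,
                       mating_design = "paired", lot_size = 50L,
                       broodstock_lag = 2L, broodstock_source_gen = NULL,
                       sample_generations = integer(0), sample_size = 50L,
                       first_year = 1999L) {
  n_generations <- as.integer(n_generations)
  Nc <- rep_len(as.integer(Nc), n_generations + 1L)
  if (is.null(ne_target)) ne_target <- NA_real_
  ne_target <- rep_len(as.numeric(ne_target), n_generations + 1L)
  bad <- !is.na(ne_target) & ne_target > Nc
  if (any(bad))
    stop("unsatisfiable configuration: ne_target exceeds Nc at generation(s) ",
         paste(which(bad) - 1L, collapse = ", "))
  phi <- rep_len(as.numeric(phi), n_generations)
  if (any(phi < 0 | phi > 1)) stop("phi must lie in [0, 1]")
  sample_generations <- as.integer(sample_generations)
  if (any(sample_generations < 0L | sample_generations > n_generations))
    stop("sample_generations outside 0..n_generations")
  sample_size <- rep_len(as.integer(sample_size),
                         max(1L, length(sample_generations)))
  if (length(sample_generations) &&
      any(sample_size > Nc[sample_generations + 1L]))
    stop("sample size exceeds census size at a sampled generation")
  structure(list(
    n_generations = n_generations, Nc = Nc, ne_target = ne_target,
    n_loci = as.integer(n_loci), n_alleles = as.integer(n_alleles),
    dirichlet_conc = dirichlet_conc, n_haplotypes = as.integer(n_haplotypes),
    mu_msat = mu_msat, mu_mt = mu_mt, phi = phi,
    broodstock_Nm = as.integer(broodstock_Nm),
    broodstock_Nf = as.integer(broodstock_Nf),
    mating_design = mating_design, lot_size = as.integer(lot_size),
    broodstock_lag = as.integer(broodstock_lag),
    broodstock_source_gen = if (is.null(broodstock_source_gen)) NA_integer_
                            else as.integer(broodstock_source_gen),
    sample_generations = sample_generations, sample_size = sample_size,
    first_year = as.integer(first_year)), class = "sim_config")
}

# gamma-weight shape for a target effective size given pool size P:
# Ne ~ P / (1 + CV^2), CV^2 = 1/shape  =>  shape = Ne / (P - Ne)
.weight_shape <- function(ne_target, P) {
  if (is.na(ne_target) || ne_target >= P) return(Inf)
  ne_target / (P - ne_target)
}

# one generation of reproduction from a breeding pool.
# pool: list(geno = N x 2L int matrix, mt = int vector)
# returns list(offspring pool, realized_ne, k = family sizes)
.reproduce <- function(pool, n_offspring, shape, L, mu_msat = 0, mu_mt = 0) {
  P <- nrow(pool$geno)
  w <- if (is.infinite(shape)) NULL else stats::rgamma(P, shape = shape)
  par1 <- sample.int(P, n_offspring, replace = TRUE, prob = w)
  par2 <- sample.int(P, n_offspring, replace = TRUE, prob = w)
  geno <- matrix(0L, n_offspring, 2L * L)
  pick1 <- matrix(stats::rbinom(n_offspring * L, 1L, 0.5), n_offspring, L)
  pick2 <- matrix(stats::rbinom(n_offspring * L, 1L, 0.5), n_offspring, L)
  for (l in seq_len(L)) {
    geno[, 2L * l - 1L] <- pool$geno[cbind(par1, 2L * l - 1L + pick1[, l])]
    geno[, 2L * l]      <- pool$geno[cbind(par2, 2L * l - 1L + pick2[, l])]
  }
  if (mu_msat > 0) {
    nmut <- stats::rbinom(1L, n_offspring * 2L * L, mu_msat)
    if (nmut > 0L) {
      idx <- cbind(sample.int(n_offspring, nmut, TRUE),
                   sample.int(2L * L, nmut, TRUE))
      geno[idx] <- pmax(1L, geno[idx] + sample(c(-2L, 2L), nmut, TRUE))
    }
  }
  mt <- pool$mt[par1]                       # maternal transmission
  if (mu_mt > 0) {
    nmut <- stats::rbinom(1L, n_offspring, mu_mt)
    if (nmut > 0L) {
      idx <- sample.int(n_offspring, nmut)
      mt[idx] <- max(pool$mt, mt) + seq_len(nmut)
    }
  }
  k <- tabulate(c(par1, par2), P)
  kbar <- mean(k)
  vk <- stats::var(k)
  realized_ne <- (P * kbar - 1) / (kbar - 1 + vk / kbar)
  list(pool = list(geno = geno, mt = mt), realized_ne = realized_ne, k = k)
}

#' Breed one captive lot from a broodstock
#'
#' Produces `lot_size` offspring from `Nm` male and `Nf` female breeders by
#' paired matings (pairs formed in order, offspring spread equally over the
#' pairs at random) or communal spawning (each offspring draws a random sire
#' and dam). mtDNA follows the dam.
#'
#' @param broodstock list(geno, mt) with the first `Nm` rows male, the
#'   remaining `Nf` female.
#' @param Nm,Nf breeder counts.
#' @param lot_size offspring to produce.
#' @param design `"paired"` or `"communal"`.
#' @return list(geno, mt) for the lot.
#' @export
simulate_lot <- function(broodstock, Nm, Nf, lot_size, design = "paired") {
  if (Nm < 1L || Nf < 1L) stop("need at least one breeder of each sex")
  L <- ncol(broodstock$geno) %/% 2L
  males <- seq_len(Nm); females <- Nm + seq_len(Nf)
  if (design == "paired") {
    np <- min(Nm, Nf)
    pair <- sample(rep_len(seq_len(np), lot_size))
    sire <- males[pair]; dam <- females[pair]
  } else {
    sire <- sample(males, lot_size, replace = TRUE)
    dam <- sample(females, lot_size, replace = TRUE)
  }
  geno <- matrix(0L, lot_size, 2L * L)
  pick1 <- matrix(stats::rbinom(lot_size * L, 1L, 0.5), lot_size, L)
  pick2 <- matrix(stats::rbinom(lot_size * L, 1L, 0.5), lot_size, L)
  for (l in seq_len(L)) {
    geno[, 2L * l - 1L] <- broodstock$geno[cbind(sire, 2L * l - 1L + pick1[, l])]
    geno[, 2L * l]      <- broodstock$geno[cbind(dam, 2L * l - 1L + pick2[, l])]
  }
  list(geno = geno, mt = broodstock$mt[dam])
}

.pool_to_tables <- function(pool, idx, sample_id, loci) {
  n <- length(idx)
  calls <- array(NA_integer_, dim = c(n, length(loci), 2L))
  for (l in seq_along(loci)) {
    calls[, l, 1L] <- pool$geno[idx, 2L * l - 1L]
    calls[, l, 2L] <- pool$geno[idx, 2L * l]
  }
  gt <- genotype_table(calls, individuals = sprintf("%s_%04d", sample_id, seq_len(n)),
                       loci = loci, sample_id = sample_id)
  ht <- haplotype_table(LETTERS702()[pool$mt[idx]],
                        individuals = gt$individuals, sample_id = sample_id)
  list(genotypes = gt, haplotypes = ht)
}

# haplotype label alphabet: A..Z then AA.. (ample for any run)
LETTERS702 <- function() c(LETTERS, paste0(rep(LETTERS, each = 26), LETTERS))

#' Run the Wright-Fisher supplementation simulator
#'
#' @param config a [sim_config].
#' @param seed integer seed; identical seed and config give identical output.
#' @return list of class `sim_result`:
#'   `genotypes`, `haplotypes` — lists of [genotype_table]/[haplotype_table],
#'   one per sampled generation (Plan I: drawn with replacement before
#'   reproduction); `meta` — [sample_meta]; `truth` — data.frame of
#'   per-generation census size, supplementation fraction and realized Ne
#'   (from realized family sizes, `Ne = (N*kbar - 1)/(kbar - 1 + Vk/kbar)`);
#'   `lots` — captive lots released each supplemented generation (genotype
#'   pools plus [broodstock_record]); `frequencies` — per-generation allele
#'   frequency trajectories.
#' @export
simulate_population <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  L <- config$n_loci
  loci <- sprintf("Loc%02d", seq_len(L))
  # generation 0: Dirichlet frequencies, HWE genotypes
  rdirichlet1 <- function(k, conc) {
    g <- stats::rgamma(k, shape = conc)
    g / sum(g)
  }
  allele_labels <- lapply(seq_len(L), function(l) 100L + 2L * seq_len(config$n_alleles))
  freq0 <- lapply(seq_len(L), function(l) rdirichlet1(config$n_alleles, config$dirichlet_conc))
  N0 <- config$Nc[1L]
  geno <- matrix(0L, N0, 2L * L)
  for (l in seq_len(L)) {
    geno[, 2L * l - 1L] <- sample(allele_labels[[l]], N0, TRUE, prob = freq0[[l]])
    geno[, 2L * l]      <- sample(allele_labels[[l]], N0, TRUE, prob = freq0[[l]])
  }
  mtf0 <- rdirichlet1(config$n_haplotypes, config$dirichlet_conc)
  pool <- list(geno = geno,
               mt = sample.int(config$n_haplotypes, N0, TRUE, prob = mtf0))

  n_gen <- config$n_generations
  need_history <- any(config$phi > 0)
  history <- if (need_history) list(`0` = pool) else NULL
  truth <- data.frame(generation = 0:n_gen, Nc = config$Nc,
                      phi = c(NA_real_, config$phi),
                      realized_ne = NA_real_)
  freq_track <- vector("list", n_gen + 1L)
  track <- function(pool) {
    lapply(seq_len(L), function(l) {
      a <- c(pool$geno[, 2L * l - 1L], pool$geno[, 2L * l])
      tabulate(factor(a, levels = allele_labels[[l]]),
               config$n_alleles) / length(a)
    })
  }
  freq_track[[1L]] <- track(pool)

  out_g <- out_h <- list()
  meta_rows <- list()
  lots_out <- list()
  take_sample <- function(pool, g) {
    si <- match(g, config$sample_generations)
    S <- config$sample_size[si]
    # Plan I: distinct fish are drawn nondestructively before reproduction and
    # returned, so sampled individuals may also be parents
    idx <- sample.int(nrow(pool$geno), S, replace = FALSE)
    sid <- sprintf("gen%02d", g)
    tabs <- .pool_to_tables(pool, idx, sid, loci)
    out_g[[sid]] <<- tabs$genotypes
    out_h[[sid]] <<- tabs$haplotypes
    meta_rows[[sid]] <<- sample_meta(sid, config$first_year + g, NA, "wild")
  }
  if (0L %in% config$sample_generations) take_sample(pool, 0L)

  for (g in seq_len(n_gen)) {
    phi_g <- config$phi[g]
    breeding <- pool
    if (phi_g > 0) {
      n_capt <- round(phi_g * nrow(pool$geno))
      if (n_capt > 0L) {
        src_gen <- if (!is.na(config$broodstock_source_gen))
          min(config$broodstock_source_gen, g - 1L)
        else max(0L, g - 1L - config$broodstock_lag)
        src <- history[[as.character(src_gen)]]
        n_lots <- ceiling(n_capt / config$lot_size)
        capt_geno <- NULL; capt_mt <- NULL
        br_rec <- list()
        for (lt in seq_len(n_lots)) {
          nb <- config$broodstock_Nm + config$broodstock_Nf
          bidx <- sample.int(nrow(src$geno), nb, replace = FALSE)
          lot <- simulate_lot(list(geno = src$geno[bidx, , drop = FALSE],
                                   mt = src$mt[bidx]),
                              config$broodstock_Nm, config$broodstock_Nf,
                              config$lot_size, config$mating_design)
          capt_geno <- rbind(capt_geno, lot$geno)
          capt_mt <- c(capt_mt, lot$mt)
          br_rec[[lt]] <- list(lot = lot,
                               record = broodstock_record(
                                 sprintf("gen%02d_lot%02d", g, lt),
                                 config$broodstock_Nm, config$broodstock_Nf,
                                 config$mating_design))
        }
        keep_capt <- seq_len(min(n_capt, nrow(capt_geno)))
        n_wild <- nrow(pool$geno) - length(keep_capt)
        widx <- sample.int(nrow(pool$geno), n_wild, replace = FALSE)
        breeding <- list(geno = rbind(pool$geno[widx, , drop = FALSE],
                                      capt_geno[keep_capt, , drop = FALSE]),
                         mt = c(pool$mt[widx], capt_mt[keep_capt]))
        lots_out[[sprintf("gen%02d", g)]] <- br_rec
      }
    }
    shape <- .weight_shape(config$ne_target[g + 1L], nrow(breeding$geno))
    rep_out <- .reproduce(breeding, config$Nc[g + 1L], shape, L,
                          config$mu_msat, config$mu_mt)
    pool <- rep_out$pool
    truth$realized_ne[g + 1L] <- rep_out$realized_ne
    freq_track[[g + 1L]] <- track(pool)
    if (need_history) history[[as.character(g)]] <- pool
    if (g %in% config$sample_generations) take_sample(pool, g)
  }
  meta <- do.call(rbind, meta_rows)
  structure(list(genotypes = out_g, haplotypes = out_h, meta = meta,
                 truth = truth, lots = lots_out, frequencies = freq_track,
                 config = config, seed = as.integer(seed)),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result: %d generations, Nc %s, %d sampled generations\n",
              x$config$n_generations,
              paste(range(x$config$Nc), collapse = "-"),
              length(x$genotypes)))
  print(x$truth)
  invisible(x)
}

#' Named simulation scenario presets
#'
#' * `"isolated_wf"` — closed Wright-Fisher control: Nc = 1000, target
#'   Ne = 100 via sweepstakes weights, 9 loci x 8 alleles, samples of 50 at
#'   generations 0 and 2.
#' * `"wild_decline"` — census crash from 1e5 to 1e3 over ten generations, no
#'   supplementation, sweepstakes Ne/Nc ~ 0.01.
#' * `"supplemented_sink"` — declining, sweepstakes-recruiting wild sink
#'   supplemented at a fluctuating fraction rising to 0.8 with captive lots
#'   of 50 bred from 15-pair broodstocks drawn from a persistent captive
#'   pool founded before the crash (generation 2), mirroring a hatchery
#'   program seeded from one large pre-decline egg collection.
#'
#' @param name preset name.
#' @return a [sim_config].
#' @export
scenario_presets <- function(name) {
  presets <- c("isolated_wf", "wild_decline", "supplemented_sink")
  if (!name %in% presets)
    stop("unknown preset '", name, "'; available: ",
         paste(presets, collapse = ", "))
  switch(name,
    isolated_wf = sim_config(
      n_generations = 2L, Nc = 1000L, ne_target = 100,
      n_loci = 9L, n_alleles = 8L, phi = 0,
      sample_generations = c(0L, 2L), sample_size = 50L),
    wild_decline = sim_config(
      n_generations = 10L,
      Nc = round(10^seq(5, 3, length.out = 11)),
      ne_target = round(10^seq(5, 3, length.out = 11)) / 100,
      phi = 0,
      sample_generations = c(0L, 5L, 10L), sample_size = 100L),
    supplemented_sink = sim_config(
      n_generations = 8L,
      Nc = c(2000L, 2000L, 2000L, 1500L, 1200L, 1000L, 800L, 700L, 600L),
      ne_target = c(400, 400, 400, 200, 100, 60, 60, 60, 60),
      phi = c(0, 0, 0, 0.2, 0.5, 0.8, 0.3, 0.8),
      broodstock_Nm = 15L, broodstock_Nf = 15L, lot_size = 50L,
      mating_design = "paired", broodstock_source_gen = 2L,
      sample_generations = c(6L, 7L, 8L), sample_size = 50L))
}

#' Write / read a simulation configuration as YAML
#'
#' @param config a [sim_config].
#' @param path file path.
#' @return `read_sim_config` returns the reconstructed [sim_config].
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(sim_config, x[setdiff(names(x), c("Nc", "ne_target", "phi",
                                            "sample_generations",
                                            "sample_size"))] |>
            c(list(Nc = unlist(x$Nc), ne_target = unlist(x$ne_target),
                   phi = unlist(x$phi),
                   sample_generations = unlist(x$sample_generations),
                   sample_size = unlist(x$sample_size))))
}
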