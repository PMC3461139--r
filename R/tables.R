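#' Construct a diploid multilocus genotype table
#'
#' The central container for microsatellite data: one row per individual, one
#' column pair per locus. Allele calls are positive integer labels (repeat-size
#' codes); a missing call is `NA` for both gene copies. A half-missing call
#' (one `NA` of the two copies) is treated as fully missing for that locus.
#'
#' @param calls integer array of dimension `c(n_individuals, n_loci, 2)`, or a
#'   matrix with `2 * n_loci` columns (copy 1 and copy 2 interleaved per locus).
#' @param individuals character vector of unique individual identifiers.
#' @param loci character vector of locus names.
#' @param sample_id label for the sample (collection) the table represents.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(calls, individuals = NULL, loci = NULL,
                           sample_id = "sample") {
  if (is.matrix(calls)) {
    if (ncol(calls) %% 2L != 0L) stop("genotype matrix must have 2 columns per locus")
    L <- ncol(calls) %/% 2L
    arr <- array(NA_integer_, dim = c(nrow(calls), L, 2L))
    arr[, , 1L] <- as.integer(calls[, 2L * seq_len(L) - 1L])
    arr[, , 2L] <- as.integer(calls[, 2L * seq_len(L)])
    calls <- arr
  }
  stopifnot(length(dim(calls)) == 3L, dim(calls)[3L] == 2L)
  storage.mode(calls) <- "integer"
  n <- dim(calls)[1L]; L <- dim(calls)[2L]
  if (is.null(individuals)) individuals <- sprintf("%s_%03d", sample_id, seq_len(n))
  if (is.null(loci)) loci <- sprintf("Loc%d", seq_len(L))
  individuals <- as.character(individuals); loci <- as.character(loci)
  if (length(individuals) != n) stop("length(individuals) != number of rows")
  if (anyDuplicated(individuals)) stop("duplicate individual identifiers")
  if (length(loci) != L) stop("length(loci) != number of loci")
  if (any(calls <= 0L, na.rm = TRUE)) stop("allele labels must be positive integers")
  # enforce half-missing -> fully missing
  half <- xor(is.na(calls[, , 1L, drop = FALSE]), is.na(calls[, , 2L, drop = FALSE]))
  if (any(half)) {
    idx <- which(half, arr.ind = TRUE)
    calls[cbind(idx[, 1L], idx[, 2L], 1L)] <- NA_integer_
    calls[cbind(idx[, 1L], idx[, 2L], 2L)] <- NA_integer_
  }
  structure(
    list(calls = calls, individuals = individuals, loci = loci,
         sample_id = as.character(sample_id), n_individuals = n),
    class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table '%s': %d individuals x %d loci\n",
              x$sample_id, x$n_individuals, length(x$loci)))
  miss <- mean(is.na(x$calls[, , 1L]))
  cat(sprintf("  loci: %s\n  missing calls: %.1f%%\n",
              paste(x$loci, collapse = ", "), 100 * miss))
  invisible(x)
}

#' Construct a haploid (mtDNA) haplotype table
#'
#' @param haplotype character vector of haplotype labels, `NA` for missing.
#' @param individuals individual identifiers (default generated).
#' @param sample_id sample label.
#' @return An object of class `haplotype_table`.
#' @export
haplotype_table <- function(haplotype, individuals = NULL, sample_id = "sample") {
  haplotype <- as.character(haplotype)
  n <- length(haplotype)
  if (is.null(individuals)) individuals <- sprintf("%s_%03d", sample_id, seq_len(n))
  individuals <- as.character(individuals)
  if (anyDuplicated(individuals)) stop("duplicate individual identifiers")
  if (length(individuals) != n) stop("length(individuals) != length(haplotype)")
  structure(list(haplotype = haplotype, individuals = individuals,
                 sample_id = as.character(sample_id)),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  tb <- table(x$haplotype, useNA = "no")
  cat(sprintf("haplotype_table '%s': %d individuals, %d haplotypes\n",
              x$sample_id, length(x$individuals), length(tb)))
  print(tb)
  invisible(x)
}

#' Per-sample metadata
#'
#' @param sample_id sample labels.
#' @param year calendar year of collection.
#' @param reach river reach (`"Angostura"`, `"Isleta"`, `"SanAcacia"` or `NA`).
#' @param origin one of `"wild"`, `"wild_caught_egg"`, `"captive_spawned"`.
#' @return data.frame of class `sample_meta`.
#' @export
sample_meta <- function(sample_id, year, reach = NA_character_, origin = "wild") {
  reaches <- c("Angostura", "Isleta", "SanAcacia")
  origins <- c("wild", "wild_caught_egg", "captive_spawned")
  reach <- as.character(reach); origin <- as.character(origin)
  if (!all(is.na(reach) | reach %in% reaches))
    stop("reach must be one of ", paste(reaches, collapse = ", "), " or NA")
  if (!all(origin %in% origins))
    stop("origin must be one of ", paste(origins, collapse = ", "))
  out <- data.frame(sample_id = as.character(sample_id),
                    year = as.integer(year),
                    reach = reach, origin = origin,
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_meta", "data.frame")
  out
}

#' Broodstock census record(s)
#'
#' Counts of male and female breeders per captive lot, with the mating design
#' used to produce the lot.
#'
#' @param lot_id lot labels.
#' @param Nm,Nf male / female breeder counts (nonnegative, `Nm + Nf >= 2`).
#' @param mating_design `"paired"` or `"communal"`.
#' @return data.frame of class `broodstock_record`.
#' @export
broodstock_record <- function(lot_id, Nm, Nf, mating_design = "paired") {
  Nm <- as.integer(Nm); Nf <- as.integer(Nf)
  if (any(Nm < 0L) || any(Nf < 0L)) stop("Nm and Nf must be nonnegative")
  if (any(Nm + Nf < 2L)) stop("a usable lot needs Nm + Nf >= 2")
  if (!all(mating_design %in% c("paired", "communal")))
    stop("mating_design must be 'paired' or 'communal'")
  out <- data.frame(lot_id = as.character(lot_id), Nm = Nm, Nf = Nf,
                    mating_design = rep_len(mating_design, length(Nm)),
                    stringsAsFactors = FALSE)
  class(out) <- c("broodstock_record", "data.frame")
  out
}

#' Annual environmental series record
#'
#' @param year calendar year.
#' @param cpue mean October catch per unit effort (fish per 100 m^2), >= 0.
#' @param daily_discharge numeric vector of length 61: daily mean discharge
#'   (cfs) for May 1 - June 30, or `NULL`.
#' @param runoff_score 10, 15, 20, or `NA` (unset; computable from discharge).
#' @return list of class `env_record`.
#' @export
env_record <- function(year, cpue, daily_discharge = NULL, runoff_score = NA) {
  if (cpue < 0) stop("cpue must be nonnegative")
  if (!is.null(daily_discharge) && length(daily_discharge) != 61L)
    stop("daily_discharge must have length 61 (May 1 - June 30)")
  if (!is.na(runoff_score) && !runoff_score %in% c(10, 15, 20))
    stop("runoff_score must be 10, 15 or 20")
  structure(list(year = as.integer(year), cpue = as.numeric(cpue),
                 daily_discharge = daily_discharge,
                 runoff_score = runoff_score),
            class = "env_record")
}

#' Allele/haplotype frequencies from a count vector
#'
#' @param counts nonnegative integer counts of allele (or haplotype) copies.
#' @return list with `freq` (sums to 1) and `n` (total gene copies).
#' @export
frequencies_from_table <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  n <- sum(counts)
  if (n <= 0) stop("all-zero counts")
  list(freq = counts / n, n = n)
}

#' Integer counts from published (rounded) frequencies
#'
#' Published tables report frequencies to a few decimals; exact tests need the
#' underlying integer counts. Recovers them as `round(freq * n)` followed by a
#' largest-remainder repair so the total equals `n`. A warning is emitted when
#' any cell is adjusted by more than 1 count, and an error when the repair
#' would move any cell by more than 2 counts (frequencies and `n` are then
#' mutually inconsistent).
#'
#' @param freqs frequencies in `[0, 1]`.
#' @param n total number of gene copies (> 0).
#' @return integer vector of counts summing to `n`.
#' @export
counts_from_published_frequencies <- function(freqs, n) {
  if (any(freqs < 0) || any(freqs > 1)) stop("frequencies must be in [0, 1]")
  if (n <= 0) stop("n must be positive")
  raw <- freqs * n
  cnt <- round(raw)
  diff <- n - sum(cnt)
  adj <- integer(length(cnt))
  if (diff != 0) {
    # largest-remainder repair: push the deficit onto the cells whose rounding
    # moved them furthest in the opposite direction; ties broken by index order
    for (k in seq_len(abs(diff))) {
      resid <- raw - (cnt + adj)
      if (diff > 0) {
        i <- which.max(resid)           # most under-allocated cell
        adj[i] <- adj[i] + 1L
      } else {
        i <- which.min(resid)           # most over-allocated cell
        adj[i] <- adj[i] - 1L
      }
    }
  }
  if (any(abs(adj) > 2L))
    stop("irreconcilable rounding: adjustment exceeds 2 counts on a cell")
  if (any(abs(adj) > 1L))
    warning("count repair adjusted a cell by more than 1 count")
  out <- as.integer(cnt + adj)
  stopifnot(sum(out) == n)
  out
}
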