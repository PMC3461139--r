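#' Read a Genepop file
#'
#' Parses the standard Genepop exchange format (2- or 3-digit allele codes)
#' into one [genotype_table] per `POP` block. Allele code `"00"`/`"000"` means
#' missing; a half-missing diploid call is stored as fully missing.
#'
#' @param path path to a Genepop file.
#' @param allele_digits 2 or 3 digits per allele code.
#' @param sample_ids optional character vector of sample labels, one per POP
#'   block; defaults to the last individual label of each block (the Genepop
#'   convention) when omitted.
#' @return list of [genotype_table], one per POP block.
#' @export
read_genepop <- function(path, allele_digits = 3L, sample_ids = NULL) {
  if (!allele_digits %in% c(2L, 3L)) stop("allele_digits must be 2 or 3")
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop("parse error at line 1: empty Genepop file")
  lines <- sub("\\s+$", "", lines)
  # line 1: title. Locus names: either one per line until first 'pop', or a
  # single comma-separated line.
  pop_lines <- grep("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  if (length(pop_lines) == 0L) stop("parse error: no POP line found")
  first_pop <- pop_lines[1L]
  locus_block <- lines[2:(first_pop - 1L)]
  loci <- trimws(unlist(strsplit(locus_block, ",")))
  loci <- loci[nzchar(loci)]
  if (length(loci) == 0L) stop("parse error at line 2: no locus names")
  L <- length(loci)
  tables <- vector("list", length(pop_lines))
  bounds <- c(pop_lines, length(lines) + 1L)
  for (b in seq_along(pop_lines)) {
    block <- lines[seq.int(bounds[b] + 1L, bounds[b + 1L] - 1L)]
    block <- block[nzchar(trimws(block))]
    n <- length(block)
    ids <- character(n)
    calls <- array(NA_integer_, dim = c(n, L, 2L))
    for (i in seq_len(n)) {
      line_no <- bounds[b] + i
      parts <- strsplit(block[i], ",")[[1L]]
      if (length(parts) < 2L)
        stop(sprintf("parse error at line %d: missing ',' separator", line_no))
      ids[i] <- trimws(parts[1L])
      codes <- strsplit(trimws(paste(parts[-1L], collapse = ",")), "\\s+")[[1L]]
      codes <- codes[nzchar(codes)]
      if (length(codes) != L)
        stop(sprintf("parse error at line %d: %d genotype fields for %d loci",
                     line_no, length(codes), L))
      for (l in seq_len(L)) {
        code <- codes[l]
        if (nchar(code) != 2L * allele_digits)
          stop(sprintf("parse error at line %d: code '%s' is not %d digits",
                       line_no, code, 2L * allele_digits))
        a1 <- as.integer(substr(code, 1L, allele_digits))
        a2 <- as.integer(substr(code, allele_digits + 1L, 2L * allele_digits))
        if (is.na(a1) || is.na(a2))
          stop(sprintf("parse error at line %d: non-numeric code '%s'",
                       line_no, code))
        if (a1 > 0L && a2 > 0L) {
          calls[i, l, 1L] <- a1
          calls[i, l, 2L] <- a2
        }
      }
    }
    sid <- if (!is.null(sample_ids)) sample_ids[b] else ids[n]
    tables[[b]] <- genotype_table(calls, individuals = ids, loci = loci,
                                  sample_id = sid)
  }
  tables
}

#' Write genotype tables to a Genepop file
#'
#' Inverse of [read_genepop]: the emitted file re-reads to an identical data
#' model (lossless for allele labels representable in `allele_digits` digits).
#'
#' @param tables a [genotype_table] or list of them (one POP block each).
#' @param path output path.
#' @param allele_digits 2 or 3.
#' @param title first (title) line of the file.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(tables, path, allele_digits = 3L,
                          title = "tempomon genotype export") {
  if (inherits(tables, "genotype_table")) tables <- list(tables)
  if (!allele_digits %in% c(2L, 3L)) stop("allele_digits must be 2 or 3")
  maxlab <- 10L^allele_digits - 1L
  out <- c(title)
  if (length(tables) > 0L) {
    loci <- tables[[1L]]$loci
    for (tab in tables) {
      if (!identical(tab$loci, loci)) stop("all tables must share the locus set")
      if (any(tab$calls > maxlab, na.rm = TRUE))
        stop(sprintf("allele label exceeds %d-digit Genepop code", allele_digits))
    }
    out <- c(out, loci)
    fmt <- sprintf("%%0%dd", allele_digits)
    for (tab in tables) {
      out <- c(out, "POP")
      for (i in seq_len(tab$n_individuals)) {
        a1 <- tab$calls[i, , 1L]; a2 <- tab$calls[i, , 2L]
        a1[is.na(a1)] <- 0L; a2[is.na(a2)] <- 0L
        codes <- paste0(sprintf(fmt, a1), sprintf(fmt, a2))
        out <- c(out, paste0(tab$individuals[i], ", ", paste(codes, collapse = " ")))
      }
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read haplotype assignments from a two-column CSV
#'
#' Expected columns: `individual,haplotype` (header required); empty or `NA`
#' haplotype fields are treated as missing.
#'
#' @param path CSV path.
#' @param sample_id sample label for the resulting table.
#' @return [haplotype_table]
#' @export
read_haplotypes_csv <- function(path, sample_id = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("individual", "haplotype") %in% names(df)))
    stop("haplotype CSV needs columns 'individual' and 'haplotype'")
  hap <- as.character(df$haplotype)
  hap[!nzchar(trimws(hap))] <- NA_character_
  haplotype_table(hap, individuals = df$individual, sample_id = sample_id)
}

#' Read per-sample metadata from CSV
#'
#' Expected columns: `sample_id,year,reach,origin`.
#' @param path CSV path.
#' @return [sample_meta]
#' @export
read_sample_meta_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "year", "reach", "origin")
  if (!all(need %in% names(df)))
    stop("metadata CSV needs columns ", paste(need, collapse = ","))
  sample_meta(df$sample_id, df$year, df$reach, df$origin)
}
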