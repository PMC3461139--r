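# --- Bundled published mtDNA reference table ------------------------------

#' Published mtDNA-ND4 haplotype frequency table
#'
#' The per-sample haplotype frequency table (to three decimals) and mtDNA
#' sample sizes from the published 12-year Rio Grande silvery minnow
#' monitoring study, bundled as a reference dataset: 13 wild annual samples
#' (1987, 1999-2010), 7 wild-caught-egg stocks and 20 captive-spawned stocks
#' over a 15-haplotype alphabet.
#'
#' @return data.frame with columns `sample_id`, `origin`, `n_mtdna` and one
#'   frequency column per haplotype label.
#' @export
published_haplotype_frequencies <- function() {
  path <- system.file("extdata", "mtdna_haplotype_frequencies.csv",
                      package = "tempomon", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Integer haplotype counts recovered from the published frequencies
#'
#' Converts each row of [published_haplotype_frequencies] back to integer
#' counts with [counts_from_published_frequencies] (largest-remainder repair
#' to the published sample size).
#'
#' @return named list of named integer count vectors (zero-count haplotypes
#'   dropped), one per sample.
#' @export
published_haplotype_counts <- function() {
  df <- published_haplotype_frequencies()
  hap_cols <- setdiff(names(df), c("sample_id", "origin", "n_mtdna"))
  out <- lapply(seq_len(nrow(df)), function(i) {
    cnt <- counts_from_published_frequencies(as.numeric(df[i, hap_cols]),
                                             df$n_mtdna[i])
    names(cnt) <- hap_cols
    cnt[cnt > 0L]
  })
  names(out) <- df$sample_id
  out
}
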