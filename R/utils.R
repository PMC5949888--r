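#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef cor lm mad median plogis predict quantile rbinom
#'   rmultinom runif sd setNames wilcox.test rnorm
#' @importFrom utils adist aregexec head read.delim write.table
#' @importFrom Rcpp evalCpp
#' @useDynLib idrscreen, .registration = TRUE
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

.check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop("invalid alphabet: non-ACGT character in ", what, call. = FALSE)
  }
  invisible(x)
}

.check_peptide <- function(x, what = "peptide") {
  bad <- grepl(sprintf("[^%s]", paste(AA20, collapse = "")), x)
  if (any(bad)) {
    stop("invalid alphabet: non-standard amino acid in ", what, call. = FALSE)
  }
  invisible(x)
}

.codons <- function(dna) {
  n <- nchar(dna) %/% 3L
  if (n == 0L) return(character(0))
  substring(dna, seq(1L, by = 3L, length.out = n), seq(3L, by = 3L, length.out = n))
}

# Most frequent S. cerevisiae codon per amino acid; fixed so back-translation
# is deterministic (codon identity is irrelevant downstream except stops).
BACKTRANSLATION_TABLE <- c(
  A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
  H = "CAT", I = "ATT", K = "AAA", L = "TTG", M = "ATG", N = "AAT",
  P = "CCA", Q = "CAA", R = "AGA", S = "TCT", T = "ACT", V = "GTT",
  W = "TGG", Y = "TAT"
)

#' Back-translate a peptide with a fixed codon table
#'
#' @param peptide Amino-acid string over the 20 standard residues.
#' @return Nucleotide string, 3x the peptide length.
#' @export
back_translate <- function(peptide) {
  .check_peptide(peptide)
  if (nchar(peptide) == 0L) return("")
  paste(BACKTRANSLATION_TABLE[strsplit(peptide, "")[[1]]], collapse = "")
}

#' Translate an insert, truncating at the first stop codon
#'
#' Trailing 1-2 nt of inserts whose length is not a multiple of three are
#' dropped before translation (flagged via the returned `trimmed` field).
#'
#' @param dna Nucleotide string over ACGT.
#' @return List with `peptide` (translation up to, excluding, the first stop),
#'   `starts_with_stop` (TRUE iff the first codon is TAA/TAG/TGA) and
#'   `trimmed` (TRUE iff trailing bases were dropped).
#' @export
translate_insert <- function(dna) {
  .check_dna(dna, "insert")
  trimmed <- (nchar(dna) %% 3L) != 0L
  codons <- .codons(dna)
  if (length(codons) == 0L) {
    return(list(peptide = "", starts_with_stop = FALSE, trimmed = trimmed))
  }
  aa <- GENETIC_CODE_STD[codons]
  stop_at <- which(aa == "*")
  keep <- if (length(stop_at)) seq_len(stop_at[1L] - 1L) else seq_along(aa)
  list(
    peptide = paste(aa[keep], collapse = ""),
    starts_with_stop = codons[1L] %in% STOP_CODONS,
    trimmed = trimmed
  )
}

# standard genetic code, keyed by DNA codon
GENETIC_CODE_STD <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("U", "T", names(gc))
  gc
})

.revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(
    x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""), ""
  ))
}

#' Round to two decimals, halves away from zero
#'
#' Growth estimates are reported at two-decimal resolution; finer digits
#' reflect regression noise. Unlike [round()], halves go away from zero
#' (-0.125 -> -0.13).
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
round_estimate <- function(x, digits = 2L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
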