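#' @importFrom methods is
#' @importFrom stats setNames
#' @importFrom utils head write.table
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Kyte-Doolittle hydropathy, used to pick conservative (non-silent) PAM edits
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

charge_class <- function(aa) {
  ifelse(aa %in% c("D", "E"), "negative",
         ifelse(aa %in% c("K", "R", "H"), "positive", "neutral"))
}

#' Reverse-complement a DNA string
#'
#' @param x A character scalar over the alphabet A, C, G, T, N.
#' @return The reverse complement, same alphabet.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Translate an in-frame DNA string
#'
#' Standard genetic code; stops render as `*`.
#'
#' @param nt In-frame DNA string (length divisible by 3).
#' @return Amino-acid string.
#' @export
translate_dna <- function(nt) {
  stopifnot(nchar(nt) %% 3 == 0)
  if (nchar(nt) == 0L) return("")
  codons <- substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
  aa <- Biostrings::GENETIC_CODE[codons]
  if (anyNA(aa)) stop("non-ACGT codon in translation: ",
                      paste(codons[is.na(aa)], collapse = ", "))
  paste(aa, collapse = "")
}

codons_for_aa <- function(aa) {
  names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == aa]
}

# split a string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# 0-based half-open substring of a plain character scalar
substr0 <- function(x, start0, end0) {
  stopifnot(start0 >= 0, end0 <= nchar(x), start0 <= end0)
  substr(x, start0 + 1L, end0)
}

`substr0<-` <- function(x, start0, end0, value) {
  stopifnot(nchar(value) == end0 - start0)
  paste0(substr(x, 1L, start0), value, substr(x, end0 + 1L, nchar(x)))
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(chars(a) != chars(b))
}

is_stop_codon <- function(codon) codon %in% STOP_CODONS

# well labels A1..H12 in row-major order (A1, A2, ..., A12, B1, ...)
plate_wells <- function() {
  as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
}
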