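#' @importFrom rlang %||% abort .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange bind_rows filter group_by left_join mutate n
#'   rename select slice summarise ungroup distinct
#' @importFrom stats median rbinom rpois runif setNames lm t.test coef qnorm sd
#' @importFrom utils head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Sample a random DNA sequence with a target GC content
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = gc/2, so the expected GC fraction
#' of the emitted sequence equals `gc`.
#'
#' @param n Sequence length in bp.
#' @param gc Target GC fraction in `[0, 1]`.
#' @return A single character string of length `n`.
#' @keywords internal
random_dna <- function(n, gc) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p[DNA_BASES]), collapse = "")
}

#' GC fraction of a sequence, ignoring ambiguity codes
#'
#' @param seq Character vector of DNA sequences (or a `DNAStringSet`).
#' @return Numeric vector: (G+C) / (A+C+G+T) per sequence. Ambiguous bases are
#'   excluded from the denominator.
#' @export
gc_content <- function(seq) {
  x <- Biostrings::DNAStringSet(as.character(seq))
  fr <- Biostrings::letterFrequency(x, letters = DNA_BASES, OR = 0)
  unname((fr[, "G"] + fr[, "C"]) / rowSums(fr))
}

#' Reverse complement of plain character sequences
#' @keywords internal
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

## Split a character CDS into its codon triplets.
codon_split <- function(seq) {
  n <- nchar(seq)
  stopifnot(n %% 3 == 0)
  if (n == 0) return(character(0))
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

## Translate character CDS via codon-table lookup (terminal stop dropped;
## codons with ambiguity codes become X). Vectorised over sequences.
translate_cds <- function(seq) {
  code <- Biostrings::GENETIC_CODE
  vapply(seq, function(s) {
    aa <- unname(code[codon_split(s)])
    aa[is.na(aa)] <- "X"
    sub("\\*$", "", paste(aa, collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

is_valid_cds <- function(seq) {
  n <- nchar(seq)
  if (n %% 3 != 0 || n < 6) return(FALSE)
  cod <- codon_split(seq)
  stops <- c("TAA", "TAG", "TGA")
  cod[1] == "ATG" && !any(cod[-length(cod)] %in% stops) &&
    cod[length(cod)] %in% stops
}
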