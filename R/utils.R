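#' Convert a Phred quality score to an error probability
#'
#' @param qual Numeric vector of Phred-scaled quality scores.
#' @return Numeric vector of error probabilities \code{10^(-qual/10)}.
#' @examples
#' phredToError(30)  # 0.001
#' @export
phredToError <- function(qual) 10^(-qual / 10)

BASES <- c("A", "C", "G", "T")

#' Reverse-complement a character vector of bases
#'
#' Thin wrapper around \code{Biostrings::reverseComplement} that keeps plain
#' character input/output, which is what the per-site observation tables use.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse-complemented sequences.
#' @export
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complementBase <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[b]
}

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom stats pbinom rbinom runif rnorm setNames p.adjust
#' @importFrom utils write.table read.table head tail
#' @importFrom methods new validObject is slot
NULL
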