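#' @importFrom stats median rbinom rpois runif setNames rmultinom wilcox.test
#'   chisq.test hclust cutree as.dist complete.cases
#' @importFrom utils write.table read.table head modifyList
NULL

#' Reverse complement of a nucleotide string
#'
#' @param s A character scalar over \{A,C,G,T,N\}.
#' @return The reverse complement as a character scalar.
#' @keywords internal
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Round half away from zero
#'
#' Base R `round()` rounds half to even; printed percentage tables in this
#' package use the conventional half-up rule (e.g. 18.15 -> 18.2) so that
#' worked examples are bit-reproducible.
#'
#' @param x Numeric vector (non-negative in all internal uses).
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Derive a stage-specific RNG seed from a master seed
#'
#' A single pipeline seed fans out to per-stage seeds via a stable string
#' hash, so each stage is individually reproducible. Result is kept below
#' 2^31 - 1.
#'
#' @param seed Integer master seed.
#' @param stage Character stage label.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1000003L
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# validate a DNA string, returning uppercase; non-ACGT beyond `budget`
# (fraction) is an input error. Ns are tolerated but never match.
check_dna <- function(s, budget = 0.01, what = "sequence") {
  s <- toupper(s)
  bad <- nchar(gsub("[ACGTN]", "", s))
  nonacgt <- nchar(gsub("[ACGT]", "", s))
  if (bad > 0 || nonacgt / max(1L, nchar(s)) > budget) {
    stop(sprintf("%s contains %d non-ACGT characters (budget %.3f)",
                 what, nonacgt + bad, budget), call. = FALSE)
  }
  s
}

# stable paste key for allele vectors (no NA allowed by callers)
allele_key <- function(v) paste(v, collapse = "|")
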