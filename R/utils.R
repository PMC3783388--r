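# Internal helpers: alphabets, encodings, reverse complement, seeded RNG.

#' Reverse complement of a nucleotide string
#'
#' @param x a character scalar over A/C/G/T/N.
#' @return the reverse complement as a character scalar.
#' @keywords internal
revcomp <- function(x) {
  if (nchar(x) == 0L) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# split a string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# encode a peptide string as 0-based integer codes for the C++ kernels:
# 0..19 amino acids (AA_ALPHABET order), 20 = '*', 21 = anything else (X)
pep_encode <- function(pep) {
  cc <- chars(pep)
  code <- match(cc, AA_ALPHABET)
  code[is.na(code) & cc == "*"] <- 21L
  code[is.na(code)] <- 22L
  code - 1L
}

# deterministic child seed derived from a parent seed and a label,
# kept inside the 32-bit integer range
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# run code under a local RNG state so library calls never disturb user RNG
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
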