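# Shared low-level helpers: PHRED encoding, reverse complement, seeded RNG.

DNA_BASES <- c("A", "C", "G", "T")

#' Convert PHRED+33 quality strings to integer vectors
#'
#' @param qual character vector of PHRED+33 encoded quality strings.
#' @return A list of integer vectors (one per input string).
#' @examples
#' phred_to_int("II5")
#' @export
phred_to_int <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

#' Convert integer PHRED values to a PHRED+33 string
#'
#' @param q integer vector of PHRED scores (0-60).
#' @return A single quality string.
#' @export
int_to_phred <- function(q) {
  stopifnot(all(q >= 0 & q <= 60))
  intToUtf8(as.integer(q) + 33L)
}

# vectorized reverse complement of plain character DNA (IUPAC-aware)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# vectorized string reversal (used for quality strings)
str_reverse <- function(x) {
  as.character(Biostrings::reverse(Biostrings::BStringSet(x)))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# random DNA strings of the given lengths
random_dna <- function(lengths) {
  vapply(lengths, function(L)
    paste(sample(DNA_BASES, L, replace = TRUE), collapse = ""), character(1))
}
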