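# Shared fixtures and independent oracles for the test suite.

# small hand-built barcode set matching the classification examples
toy_barcode_set <- function() {
  pairs <- data.frame(sample_id = c("S1", "S2"),
                      forward = c("AAGGTCA", "GGTTACA"),
                      reverse = c("CCATGTC", "TTCAGGC"),
                      stringsAsFactors = FALSE)
  out <- list(pairs = pairs,
              forward = setNames(pairs$forward, c("F01", "F02")),
              reverse = setNames(pairs$reverse, c("R01", "R02")),
              length = 7L, min_distance = 2L, max_homopolymer = 3L,
              primer_pair = primer_defaults(), seed = NA)
  class(out) <- "barcode_set"
  out
}

# a read pair whose mates start with the given tags
tagged_pair <- function(tag1, tag2, insert_len = 40, seed = 1) {
  set.seed(seed)
  body1 <- paste(sample(c("A", "C", "G", "T"), insert_len, TRUE),
                 collapse = "")
  body2 <- paste(sample(c("A", "C", "G", "T"), insert_len, TRUE),
                 collapse = "")
  data.frame(id = "p1",
             seq1 = paste0(tag1, body1),
             qual1 = strrep("I", nchar(tag1) + insert_len),
             seq2 = paste0(tag2, body2),
             qual2 = strrep("I", nchar(tag2) + insert_len),
             stringsAsFactors = FALSE)
}

rc_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# split an amplicon into a 2x`readlen` mate pair with flat qualities
amplicon_to_pair <- function(amplicon, readlen = 250, q = "I") {
  data.frame(id = "r",
             seq1 = substr(amplicon, 1, readlen),
             qual1 = strrep(q, readlen),
             seq2 = rc_chr(substr(amplicon, nchar(amplicon) - readlen + 1,
                                  nchar(amplicon))),
             qual2 = strrep(q, readlen),
             stringsAsFactors = FALSE)
}

str_reverse_test <- function(x) {
  paste(rev(strsplit(x, "")[[1]]), collapse = "")
}

# exhaustive self-complementarity oracle: concrete stems only
oracle_selfcomp_fails <- function(construct, min_stem) {
  n <- nchar(construct)
  if (n < min_stem) return(FALSE)
  for (i in 1:(n - min_stem + 1)) {
    stem <- substr(construct, i, i + min_stem - 1)
    if (grepl("[^ACGT]", stem)) next
    rc <- rc_chr(stem)
    if (grepl(rc, construct, fixed = TRUE)) return(TRUE)
  }
  FALSE
}

# straightforward re-implementation of the transformed Bray-Curtis pipeline
oracle_bray_curtis <- function(tab) {
  x <- sqrt(tab)
  x <- sweep(x, 2, apply(x, 2, max), "/")
  x <- sweep(x, 1, rowSums(x), "/")
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(tab), rownames(tab)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- sum(abs(x[i, ] - x[j, ])) / sum(x[i, ] + x[j, ])
  }
  d
}

# independent pairwise identity oracle (Biostrings aligner, not the
# package's banded DP): fraction of identical positions over the global
# alignment
oracle_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       gapOpening = 2, gapExtension = 2)
  Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

# noise-free run configuration used by several joint tests
quiet_config <- function(...) {
  run_config(error_rate_scale = 0, degraded_fraction = 0, n_rate = 0, ...)
}
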