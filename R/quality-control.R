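# Post-assembly quality-control cascade, applied in a fixed order:
#   1. both primers present (IUPAC-aware, 0 mismatches) -> trimmed
#   2. no undetermined bases ('N')
#   3. sliding-window mean PHRED >= threshold
#   4. overlap region not longer than the cutoff
# A read is charged to the first filter it fails, so the per-filter removal
# counts partition the batch.

# degenerate IUPAC primer -> anchored regex character classes
iupac_regex <- function(primer) {
  map <- Biostrings::IUPAC_CODE_MAP
  chars <- strsplit(primer, "")[[1]]
  if (any(!chars %in% names(map)))
    stop("non-IUPAC character in primer: ", primer)
  paste0(vapply(chars, function(ch) {
    s <- map[[ch]]
    if (nchar(s) == 1) s else paste0("[", s, "]")
  }, character(1)), collapse = "")
}

#' Match and trim both primers on assembled reads
#'
#' The forward primer must match at position 0 and the reverse complement of
#' the reverse primer at the 3' end, with 0 mismatches; degenerate IUPAC
#' positions are satisfied by any base in the code's set. On success both
#' primer regions are trimmed from sequence and quality.
#'
#' @param reads a data.frame of assembled reads (`sequence`, `quality`).
#' @param primers a list with `forward` and `reverse` degenerate primers.
#' @return The input data.frame with a logical `primer_ok` column; rows that
#'   match have `sequence`/`quality` trimmed.
#' @export
match_primers <- function(reads, primers = primer_defaults()) {
  fwd_re <- paste0("^", iupac_regex(primers$forward))
  rev_rc <- revcomp(primers$reverse)
  rev_re <- paste0(iupac_regex(rev_rc), "$")
  ok <- grepl(fwd_re, reads$sequence) & grepl(rev_re, reads$sequence)
  nf <- nchar(primers$forward)
  nr <- nchar(primers$reverse)
  len <- nchar(reads$sequence)
  ok <- ok & (len >= nf + nr + 1)
  reads$sequence[ok] <- substr(reads$sequence[ok], nf + 1L, len[ok] - nr)
  reads$quality[ok] <- substr(reads$quality[ok], nf + 1L, len[ok] - nr)
  reads$primer_ok <- ok
  reads
}

#' Does a sequence contain undetermined bases?
#'
#' @param sequence character vector of DNA sequences.
#' @return Logical vector, `TRUE` where the letter `N` occurs.
#' @export
contains_undetermined <- function(sequence) {
  grepl("N", sequence, fixed = TRUE)
}

#' Sliding-window quality filter
#'
#' Fails a read when any window of `window` consecutive bases has a mean
#' PHRED score below `threshold`. Reads shorter than the window are judged on
#' a single window covering the whole read.
#'
#' @param qualities integer vector of PHRED scores, or a PHRED+33 string.
#' @param window window width in bp (default 10).
#' @param threshold minimum acceptable window mean (default 5).
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @export
sliding_window_filter <- function(qualities, window = 10, threshold = 5) {
  stopifnot(window >= 1)
  if (is.character(qualities)) qualities <- utf8ToInt(qualities) - 33L
  n <- length(qualities)
  if (n == 0) return(TRUE)
  if (n <= window) return(mean(qualities) >= threshold)
  cs <- cumsum(c(0, qualities))
  means <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  min(means) >= threshold
}

#' Apply the quality-control cascade
#'
#' Filters are applied in order: primer presence/trim, undetermined bases,
#' sliding-window quality, overlap-length cutoff. Each read is charged to the
#' first filter it fails, so removals plus survivors equal the input count.
#'
#' @param reads a data.frame of assembled reads with `sequence`, `quality`
#'   and `overlap_length` columns.
#' @param primers primer pair (see [primer_defaults()]).
#' @param max_overlap_length reject reads whose assembly overlap exceeds this
#'   many bp (default 100).
#' @param window,min_mean_q sliding-window parameters (defaults 10 and 5).
#' @return A list with `passed` (the surviving, primer-trimmed data.frame)
#'   and `counts` (named integer vector: input, no_primer, undetermined,
#'   low_quality, long_overlap, passed).
#' @export
apply_qc <- function(reads, primers = primer_defaults(),
                     max_overlap_length = 100, window = 10, min_mean_q = 5) {
  n <- nrow(reads)
  counts <- c(input = n, no_primer = 0L, undetermined = 0L,
              low_quality = 0L, long_overlap = 0L, passed = 0L)
  cur <- match_primers(reads, primers)
  counts["no_primer"] <- sum(!cur$primer_ok)
  cur <- cur[cur$primer_ok, , drop = FALSE]

  has_n <- contains_undetermined(cur$sequence)
  counts["undetermined"] <- sum(has_n)
  cur <- cur[!has_n, , drop = FALSE]

  if (nrow(cur)) {
    ok <- vapply(cur$quality, sliding_window_filter, logical(1),
                 window = window, threshold = min_mean_q, USE.NAMES = FALSE)
  } else ok <- logical(0)
  counts["low_quality"] <- sum(!ok)
  cur <- cur[ok, , drop = FALSE]

  long <- cur$overlap_length > max_overlap_length
  counts["long_overlap"] <- sum(long)
  cur <- cur[!long, , drop = FALSE]

  counts["passed"] <- nrow(cur)
  cur$primer_ok <- NULL
  rownames(cur) <- NULL
  list(passed = cur, counts = counts)
}
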