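# Overlap assembly of mate pairs into full amplicon sequences.
#
# The V3-V4 amplicon is short enough that 2x250 bp mates always overlap. The
# reverse mate is reverse-complemented and all ungapped suffix/prefix
# overlaps between min_overlap and max_overlap are scored; the best one
# (matches - mismatches, ties to the longer overlap) is kept. The alignment
# score is the identity fraction of that overlap and pairs scoring below the
# threshold (default 0.6, i.e. short alignments or a high proportion of
# mismatches) are discarded as low quality.

#' Find the best ungapped overlap between a forward read and a
#' reverse-complemented mate
#'
#' @param fwd forward-mate sequence.
#' @param rev_rc reverse mate, already reverse-complemented.
#' @param min_overlap smallest overlap length considered (default 10 bp).
#' @param max_overlap largest overlap length considered; `NULL` means up to
#'   the full length of the shorter read.
#' @return A list with `overlap_length`, `matches` and `mismatches`, or
#'   `NULL` when no candidate overlap of at least `min_overlap` exists or
#'   even the best candidate mismatches at most of its positions (no
#'   credible overlap).
#' @examples
#' find_best_overlap("AAAACCCC", "CCCCGGGG", min_overlap = 4)
#' @export
find_best_overlap <- function(fwd, rev_rc, min_overlap = 10,
                              max_overlap = NULL) {
  stopifnot(min_overlap >= 1)
  if (is.null(max_overlap)) max_overlap <- min(nchar(fwd), nchar(rev_rc))
  r <- cpp_best_overlap(fwd, rev_rc, as.integer(min_overlap),
                        as.integer(max_overlap))
  if (length(r) == 0) return(NULL)
  list(overlap_length = r[1], matches = r[2], mismatches = r[3])
}

#' Merge demultiplexed mate pairs into assembled amplicons
#'
#' The reverse mate of each pair is reverse-complemented and merged onto the
#' forward mate over the best ungapped overlap. The consensus takes, at
#' disagreeing overlap positions, the base with the higher PHRED score (ties
#' go to mate 1), with consensus quality the maximum of the two PHREDs where
#' the bases agree and the minimum where they disagree.
#'
#' @param pairs a data.frame with `seq1`, `qual1`, `seq2`, `qual2` (barcodes
#'   already trimmed, mate 1 forward); extra columns (`id`, `sample`) are
#'   carried through.
#' @param min_overlap minimum overlap length (default 10 bp).
#' @param max_overlap maximum candidate overlap; `NULL` for unrestricted.
#' @param score_threshold identity-fraction threshold below which the merge
#'   is rejected as `low_quality` (default 0.6).
#' @return A data.frame with `id`, `sample` (when present in the input),
#'   `status` (`assembled`/`low_quality`/`unassembled`), `sequence`,
#'   `quality`, `overlap_length`, `mismatches` and `score`.
#' @export
merge_pairs <- function(pairs, min_overlap = 10, max_overlap = NULL,
                        score_threshold = 0.6) {
  stopifnot(min_overlap >= 1)
  n <- nrow(pairs)
  if (n == 0) {
    return(data.frame(id = character(0), status = character(0),
                      sequence = character(0), quality = character(0),
                      overlap_length = integer(0), mismatches = integer(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  rc2 <- revcomp(pairs$seq2)
  q2r <- str_reverse(pairs$qual2)
  res <- cpp_merge_pairs(pairs$seq1, pairs$qual1, rc2, q2r,
                         as.integer(min_overlap),
                         as.integer(if (is.null(max_overlap)) -1L
                                    else max_overlap),
                         score_threshold)
  out <- data.frame(
    id = if ("id" %in% names(pairs)) pairs$id else sprintf("pair%06d", 1:n),
    status = c("assembled", "low_quality", "unassembled")[res$status + 1L],
    sequence = res$sequence, quality = res$quality,
    overlap_length = res$overlap_length, mismatches = res$mismatches,
    score = res$score, stringsAsFactors = FALSE)
  if ("sample" %in% names(pairs)) out$sample <- pairs$sample
  out
}

#' Merge one read pair
#'
#' Single-pair convenience wrapper around [merge_pairs()].
#'
#' @inheritParams merge_pairs
#' @param pair a list or one-row data.frame with `seq1`, `qual1`, `seq2`,
#'   `qual2`.
#' @return A one-row data.frame (see [merge_pairs()]).
#' @export
merge_pair <- function(pair, min_overlap = 10, max_overlap = NULL,
                       score_threshold = 0.6) {
  merge_pairs(as.data.frame(pair, stringsAsFactors = FALSE), min_overlap,
              max_overlap, score_threshold)
}
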