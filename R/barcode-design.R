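# Design of sample barcode sets for dual-indexed amplicon libraries.
#
# Barcodes are short tags (7 bp by default) prepended to the PCR primers so
# that pooled samples can be demultiplexed afterwards. The design constraints
# are: fixed length over {A,C,G,T}, no homopolymer runs, a minimum pairwise
# Hamming distance across the whole set (both families), and no
# self-complementary stem once the barcode is fused to its primer.

#' Default V3-V4 primer pair
#'
#' The degenerate bacterial 16S rRNA V3-V4 primers Bakt_341F
#' (`CCTACGGGNGGCWGCAG`) and Bakt_805R (`GACTACHVGGGTATCTAATCC`).
#'
#' @return A list with elements `forward` and `reverse` (IUPAC DNA strings).
#' @export
primer_defaults <- function() {
  list(forward = "CCTACGGGNGGCWGCAG", reverse = "GACTACHVGGGTATCTAATCC")
}

#' Hamming distance between two equal-length DNA strings
#'
#' @param a,b character scalars of equal length.
#' @return Integer count of positions at which `a` and `b` differ.
#' @examples
#' hamming_distance("ACGTACG", "TGCATGC")
#' @export
hamming_distance <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  if (length(ra) != length(rb))
    stop("hamming_distance(): sequences have unequal lengths (",
         length(ra), " vs ", length(rb), ")")
  sum(ra != rb)
}

# IUPAC bitmask encoding (A=1, C=2, G=4, T=8) for degeneracy-aware matching
iupac_mask_table <- function() {
  map <- Biostrings::IUPAC_CODE_MAP
  bit <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  vapply(strsplit(map, ""), function(b) sum(bit[b]), integer(1))
}

iupac_masks <- function(x) {
  tab <- iupac_mask_table()
  m <- tab[strsplit(x, "")[[1]]]
  if (anyNA(m)) stop("non-IUPAC character in sequence: ", x)
  unname(m)
}

# complement of a bitmask vector: A<->T (bits 1<->8), C<->G (bits 2<->4)
comp_mask <- function(m) {
  bitwOr(bitwOr(bitwShiftL(bitwAnd(m, 1L), 3L), bitwShiftR(bitwAnd(m, 8L), 3L)),
         bitwOr(bitwShiftL(bitwAnd(m, 2L), 1L), bitwShiftR(bitwAnd(m, 4L), 1L)))
}

#' Screen a barcode + primer construct for self-complementary stems
#'
#' Fails when the fused construct contains a subsequence of length
#' `min_stem` whose reverse complement also occurs in the construct
#' (including palindromes, which are their own reverse complement). This is a
#' sequence-level proxy for hairpin formation and self-annealing during PCR.
#' Only guaranteed pairings count: a stem position pairs with its partner
#' only when both are concrete (A/C/G/T) and complementary, so degenerate
#' primer positions (mixed-base synthesis) never form part of a stem.
#'
#' @param barcode DNA string (the candidate tag).
#' @param primer degenerate IUPAC DNA string the barcode is fused to.
#' @param min_stem minimum stem length considered able to anneal (>= 3).
#' @return A list with `pass` (logical) and `stem` (the offending subsequence,
#'   or `NA` when the construct passes).
#' @examples
#' screen_self_complementarity("GATTCAG", "CCTACGGGNGGCWGCAG")
#' @export
screen_self_complementarity <- function(barcode, primer, min_stem = 6) {
  stopifnot(min_stem >= 3)
  construct <- paste0(barcode, primer)
  masks <- iupac_masks(construct)
  n <- length(masks)
  k <- as.integer(min_stem)
  if (n < k) return(list(pass = TRUE, stem = NA_character_))
  nw <- n - k + 1L
  win <- vapply(seq_len(nw), function(i) masks[i:(i + k - 1L)], integer(k))
  concrete <- matrix(win %in% c(1L, 2L, 4L, 8L), nrow = k)
  for (i in seq_len(nw)) {
    rc <- rev(comp_mask(win[, i]))
    rc_concrete <- rc %in% c(1L, 2L, 4L, 8L)
    # rc occurs iff some window equals it position-wise with both sides
    # concrete (guaranteed base pairing)
    compat <- (win == rc) & concrete & rc_concrete
    hits <- colSums(compat) == k
    if (any(hits))
      return(list(pass = FALSE, stem = substr(construct, i, i + k - 1L)))
  }
  list(pass = TRUE, stem = NA_character_)
}

#' Design a dual-index barcode set
#'
#' Enumerates all k-mers over ACGT, removes those with homopolymer runs
#' longer than `max_homopolymer`, greedily retains (in lexicographic order) a
#' subset whose pairwise Hamming distances are all `>= min_distance`, screens
#' every survivor for self-complementarity against both primers, and finally
#' draws `n_pairs` forward and `n_pairs` reverse barcodes at random from the
#' surviving pool. Forward and reverse pools are disjoint, so family
#' membership is unambiguous at demultiplexing.
#'
#' @param n_pairs number of samples (forward/reverse barcode pairs).
#' @param length barcode length in bp (default 7).
#' @param min_distance minimum pairwise Hamming distance across the whole set
#'   (default 2; allows error detection at demultiplexing).
#' @param max_homopolymer longest allowed homopolymer run (default 2, i.e. no
#'   run of 3 identical bases).
#' @param primer_pair list with `forward` and `reverse` degenerate primers.
#' @param min_stem stem length for the self-complementarity screen.
#' @param seed integer seed; the same seed reproduces the same set.
#' @return An object of class `barcode_set`: a list with `pairs` (data.frame
#'   of sample_id/forward/reverse with barcode labels as attributes),
#'   `forward` and `reverse` (named sequence vectors), and the design
#'   parameters.
#' @examples
#' bs <- design_barcode_set(4, length = 7, seed = 1)
#' bs$pairs
#' @export
design_barcode_set <- function(n_pairs, length = 7, min_distance = 2,
                               max_homopolymer = 2,
                               primer_pair = primer_defaults(),
                               min_stem = 6, seed = 1) {
  stopifnot(n_pairs >= 1, length >= 4)
  if (4^length > 5e6)
    stop("barcode length ", length, " is too long to enumerate")
  # lexicographic enumeration of all k-mers
  grid <- do.call(expand.grid,
                  c(rep(list(DNA_BASES), length), stringsAsFactors = FALSE))
  grid <- grid[, rev(seq_len(length)), drop = FALSE]
  kmers <- sort(do.call(paste0, grid))
  # homopolymer filter: forbid any run of max_homopolymer + 1 identical bases
  hp <- grepl(paste0("([ACGT])\\1{", max_homopolymer, ",}"), kmers)
  cands <- kmers[!hp]
  if (base::length(cands) < 2 * n_pairs)
    stop("capacity error: only ", base::length(cands), " candidates survive ",
         "the homopolymer filter but ", 2 * n_pairs, " sequences are needed")
  # greedy minimum-distance packing in lexicographic order
  keep <- cpp_greedy_mindist(cands, as.integer(min_distance))
  cands <- cands[keep]
  if (base::length(cands) < 2 * n_pairs)
    stop("capacity error: only ", base::length(cands), " candidates survive ",
         "the min-distance filter but ", 2 * n_pairs, " sequences are needed")
  # self-complementarity screen against both primers
  ok <- vapply(cands, function(b) {
    screen_self_complementarity(b, primer_pair$forward, min_stem)$pass &&
      screen_self_complementarity(b, primer_pair$reverse, min_stem)$pass
  }, logical(1))
  cands <- cands[ok]
  if (base::length(cands) < 2 * n_pairs)
    stop("capacity error: only ", base::length(cands), " candidates survive ",
         "the self-complementarity screen but ", 2 * n_pairs,
         " sequences are needed")
  drawn <- with_seed(seed, sample(cands, 2 * n_pairs))
  fwd <- drawn[seq_len(n_pairs)]
  rev <- drawn[n_pairs + seq_len(n_pairs)]
  ids <- sprintf("S%02d", seq_len(n_pairs))
  names(fwd) <- sprintf("F%02d", seq_len(n_pairs))
  names(rev) <- sprintf("R%02d", seq_len(n_pairs))
  out <- list(pairs = data.frame(sample_id = ids, forward = unname(fwd),
                                 reverse = unname(rev),
                                 stringsAsFactors = FALSE),
              forward = fwd, reverse = rev,
              length = as.integer(length),
              min_distance = as.integer(min_distance),
              max_homopolymer = as.integer(max_homopolymer),
              primer_pair = primer_pair, seed = seed)
  class(out) <- "barcode_set"
  validate_barcode_set(out)
  out
}

#' Exhaustively validate a barcode set
#'
#' Checks every invariant of the design: uniform length, ACGT alphabet, no
#' homopolymer run longer than allowed, all pairwise Hamming distances (across
#' both families) at or above the minimum, unique sample ids, and distinct
#' forward/reverse sequences within each pair.
#'
#' @param x a `barcode_set`.
#' @return Invisibly, the minimum pairwise Hamming distance found.
#' @export
validate_barcode_set <- function(x) {
  stopifnot(inherits(x, "barcode_set"))
  seqs <- c(x$pairs$forward, x$pairs$reverse)
  if (anyDuplicated(seqs)) stop("barcode sequences are not unique")
  if (anyDuplicated(x$pairs$sample_id)) stop("sample ids are not unique")
  if (any(x$pairs$forward == x$pairs$reverse))
    stop("a pair uses the same sequence for both families")
  if (any(nchar(seqs) != x$length)) stop("barcode length is not uniform")
  if (any(grepl("[^ACGT]", seqs))) stop("barcode contains non-ACGT character")
  if (any(grepl(paste0("([ACGT])\\1{", x$max_homopolymer, ",}"), seqs)))
    stop("barcode contains a homopolymer run that is too long")
  invisible(min_pairwise_distance(seqs, fail_below = x$min_distance))
}

#' Minimum pairwise Hamming distance over a set of equal-length sequences
#'
#' @param seqs character vector of equal-length sequences (>= 2).
#' @param fail_below if non-NULL, error when the minimum falls below it.
#' @return The minimum pairwise Hamming distance (integer).
#' @export
min_pairwise_distance <- function(seqs, fail_below = NULL) {
  stopifnot(length(seqs) >= 2)
  mat <- do.call(rbind, strsplit(seqs, ""))
  n <- nrow(mat)
  dmin <- ncol(mat)
  for (i in seq_len(n - 1)) {
    d <- rowSums(mat[(i + 1):n, , drop = FALSE] !=
                   matrix(mat[i, ], n - i, ncol(mat), byrow = TRUE))
    dmin <- min(dmin, d)
  }
  if (!is.null(fail_below) && dmin < fail_below)
    stop("minimum pairwise distance ", dmin, " is below ", fail_below)
  as.integer(dmin)
}

#' @export
print.barcode_set <- function(x, ...) {
  cat("barcode_set:", nrow(x$pairs), "sample pairs, length", x$length,
      "bp, min distance", x$min_distance, "\n")
  print(head(x$pairs, 5))
  if (nrow(x$pairs) > 5) cat("...", nrow(x$pairs) - 5, "more pairs\n")
  invisible(x)
}

#' Write a barcode set to a TSV mapping file
#'
#' Columns: sample_id, forward_barcode, reverse_barcode.
#'
#' @param x a `barcode_set`.
#' @param path output file.
#' @export
write_barcode_tsv <- function(x, path) {
  stopifnot(inherits(x, "barcode_set"))
  df <- data.frame(sample_id = x$pairs$sample_id,
                   forward_barcode = x$pairs$forward,
                   reverse_barcode = x$pairs$reverse)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a barcode TSV mapping file
#'
#' @param path TSV with columns sample_id, forward_barcode, reverse_barcode.
#' @param min_distance,max_homopolymer design parameters recorded on the
#'   returned object (used by [validate_barcode_set()]).
#' @return A `barcode_set`.
#' @export
read_barcode_tsv <- function(path, min_distance = 2, max_homopolymer = 2) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "forward_barcode", "reverse_barcode")
                %in% names(df)))
  n <- nrow(df)
  fwd <- setNames(df$forward_barcode, sprintf("F%02d", seq_len(n)))
  rev <- setNames(df$reverse_barcode, sprintf("R%02d", seq_len(n)))
  out <- list(pairs = data.frame(sample_id = df$sample_id,
                                 forward = unname(fwd), reverse = unname(rev),
                                 stringsAsFactors = FALSE),
              forward = fwd, reverse = rev,
              length = nchar(df$forward_barcode[1]),
              min_distance = as.integer(min_distance),
              max_homopolymer = as.integer(max_homopolymer),
              primer_pair = primer_defaults(), seed = NA)
  class(out) <- "barcode_set"
  out
}

#' Write barcoded full primers as FASTA
#'
#' Each record is the concatenation barcode + primer, one forward and one
#' reverse per sample.
#'
#' @param x a `barcode_set`.
#' @param path output FASTA file.
#' @export
write_barcoded_primers_fasta <- function(x, path) {
  stopifnot(inherits(x, "barcode_set"))
  seqs <- c(paste0(x$pairs$forward, x$primer_pair$forward),
            paste0(x$pairs$reverse, x$primer_pair$reverse))
  names(seqs) <- c(paste0(x$pairs$sample_id, "_F"),
                   paste0(x$pairs$sample_id, "_R"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
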