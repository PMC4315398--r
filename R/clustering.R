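# Greedy centroid OTU clustering at 97% identity, plus dereplication,
# OTU-table construction, cross-platform trimming and length-class binning.

#' Dereplicate sequences
#'
#' Collapses exact duplicates into unique sequences with abundances, sorted
#' by decreasing size (ties broken lexicographically by sequence).
#'
#' @param sequences character vector of DNA sequences.
#' @return A list with `unique` (data.frame of `sequence`, `size`) and `map`
#'   (integer vector assigning every input read to a row of `unique`).
#' @examples
#' dereplicate(c("ACGT", "ACGT", "AAAA"))$unique
#' @export
dereplicate <- function(sequences) {
  if (length(sequences) == 0) {
    return(list(unique = data.frame(sequence = character(0),
                                    size = integer(0)),
                map = integer(0)))
  }
  tab <- table(sequences)
  df <- data.frame(sequence = names(tab), size = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$size, df$sequence), , drop = FALSE]
  rownames(df) <- NULL
  list(unique = df, map = match(sequences, df$sequence))
}

#' Greedy centroid clustering of dereplicated sequences
#'
#' Scans unique sequences in decreasing abundance order; each joins the first
#' existing centroid whose identity with it reaches the threshold, otherwise
#' it founds a new centroid. Identity is the fraction of matching columns of
#' a global end-free (free terminal gap) pairwise alignment, computed by
#' banded dynamic programming. With `discard_singletons`, unique sequences of
#' size 1 may join existing centroids but never found new ones (the UPARSE
#' convention); unjoined singletons are discarded.
#'
#' @param derep data.frame with `sequence` and `size`, sorted by decreasing
#'   size (as from [dereplicate()]; re-sorted defensively).
#' @param identity_threshold minimum identity to join a centroid
#'   (default 0.97, i.e. a minimum difference of 3% between cluster centers).
#' @param discard_singletons if `TRUE`, size-1 sequences cannot found
#'   centroids.
#' @param band half-width of the alignment band (default 16; widened
#'   automatically when two sequences differ more than that in length).
#' @return A list with `otus` (data.frame `id`, `centroid`, `size` where size
#'   sums member abundances) and `membership` (integer OTU index per row of
#'   `derep`, `NA` for discarded singletons).
#' @export
greedy_otu_cluster <- function(derep, identity_threshold = 0.97,
                               discard_singletons = FALSE, band = 16) {
  perm <- order(-derep$size, derep$sequence)
  df <- derep[perm, , drop = FALSE]
  cl <- cpp_greedy_cluster(df$sequence, as.integer(df$size),
                           identity_threshold, as.integer(band),
                           discard_singletons)
  membership_sorted <- cl$membership
  centroids <- df$sequence[cl$centroid_index + 1L]
  csize <- as.integer(tapply(df$size, factor(membership_sorted,
                                             levels = seq_along(centroids)),
                             sum, default = 0L))
  membership <- rep(NA_integer_, nrow(derep))
  membership[perm] <- membership_sorted
  otus <- data.frame(id = sprintf("OTU_%d", seq_along(centroids)),
                     centroid = centroids, size = csize,
                     stringsAsFactors = FALSE)
  list(otus = otus, membership = membership)
}

#' Build a samples x OTUs count table
#'
#' @param otu_ids character vector: OTU id per read (`NA` for discarded
#'   reads).
#' @param samples character vector: sample label per read; every label must
#'   occur in `sample_levels` when that is supplied.
#' @param sample_levels optional ordered sample labels (rows of the table).
#' @return An integer matrix (samples x OTUs); all-zero OTU columns are
#'   dropped.
#' @export
build_otu_table <- function(otu_ids, samples, sample_levels = NULL) {
  stopifnot(length(otu_ids) == length(samples))
  if (anyNA(samples)) stop("unknown (NA) sample label")
  if (is.null(sample_levels)) sample_levels <- unique(samples)
  if (!all(samples %in% sample_levels))
    stop("unknown sample label(s): ",
         paste(setdiff(samples, sample_levels), collapse = ", "))
  keep <- !is.na(otu_ids)
  otu_levels <- unique(otu_ids[keep])
  tab <- table(factor(samples[keep], levels = sample_levels),
               factor(otu_ids[keep], levels = otu_levels))
  m <- matrix(as.integer(tab), nrow = length(sample_levels),
              dimnames = list(sample_levels, otu_levels))
  m[, colSums(m) > 0, drop = FALSE]
}

#' Trim sequences to a fixed length
#'
#' Sequences longer than `target` keep their first `target` bases; shorter
#' sequences are discarded (padding would fabricate bases). Used to
#' harmonize reads from platforms with different read lengths before joint
#' clustering.
#'
#' @param sequences character vector.
#' @param target target length in bp (default 400).
#' @return A list with `sequences` (trimmed survivors) and `n_discarded`.
#' @export
trim_to_length <- function(sequences, target = 400) {
  stopifnot(target >= 1)
  keep <- nchar(sequences) >= target
  list(sequences = substr(sequences[keep], 1, target),
       n_discarded = sum(!keep))
}

#' Bin sequences into low / mid / high length fractions
#'
#' The three amplicon length classes observed for the V3-V4 region: low
#' (<= 446 bp, archaeal), mid (447-464 bp) and high (>= 465 bp).
#'
#' @param sequences character vector.
#' @param low_max upper bound of the low class (default 446).
#' @param mid_max upper bound of the mid class (default 464).
#' @return A list with `bin` (factor low/mid/high per sequence) and the three
#'   partitions `low`, `mid`, `high`.
#' @export
bin_length_fractions <- function(sequences, low_max = 446, mid_max = 464) {
  stopifnot(low_max < mid_max)
  len <- nchar(sequences)
  bin <- cut(len, breaks = c(-Inf, low_max, mid_max, Inf),
             labels = c("low", "mid", "high"))
  list(bin = bin,
       low = sequences[bin == "low"],
       mid = sequences[bin == "mid"],
       high = sequences[bin == "high"])
}
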