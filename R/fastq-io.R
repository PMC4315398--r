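# Paired FASTQ input/output (PHRED+33), via Biostrings.

#' Read a pair of synchronized FASTQ files
#'
#' Records are paired by file order. The two files must contain the same
#' number of records and matching ids (the id token before any space or
#' `/1`/`/2` suffix).
#'
#' @param path1,path2 paths to the R1 and R2 FASTQ files.
#' @return A `read_pairs` data.frame with columns `id`, `seq1`, `qual1`,
#'   `seq2`, `qual2` (qualities PHRED+33 encoded).
#' @export
read_paired_fastq <- function(path1, path2) {
  r1 <- Biostrings::readDNAStringSet(path1, format = "fastq",
                                     with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(path2, format = "fastq",
                                     with.qualities = TRUE)
  if (length(r1) != length(r2))
    stop("paired FASTQ files are desynchronized: ", length(r1),
         " records in R1 vs ", length(r2), " in R2")
  id1 <- sub("[/ ].*$", "", names(r1))
  id2 <- sub("[/ ].*$", "", names(r2))
  bad <- which(id1 != id2)
  if (length(bad))
    stop("paired FASTQ ids differ at record ", bad[1], ": '",
         id1[bad[1]], "' vs '", id2[bad[1]], "'")
  out <- data.frame(id = id1,
                    seq1 = as.character(r1),
                    qual1 = as.character(S4Vectors::mcols(r1)$qualities),
                    seq2 = as.character(r2),
                    qual2 = as.character(S4Vectors::mcols(r2)$qualities),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write read pairs to two FASTQ files
#'
#' @param pairs a `read_pairs` data.frame (see [read_paired_fastq()]).
#' @param path1,path2 output FASTQ paths for R1 and R2.
#' @export
write_paired_fastq <- function(pairs, path1, path2) {
  write_fastq(pairs$seq1, pairs$qual1, pairs$id, path1)
  write_fastq(pairs$seq2, pairs$qual2, pairs$id, path2)
  invisible(c(path1, path2))
}

#' Write single-end records to a FASTQ file
#'
#' @param seq,qual,id parallel character vectors.
#' @param path output FASTQ path.
#' @export
write_fastq <- function(seq, qual, id, path) {
  x <- Biostrings::DNAStringSet(seq)
  names(x) <- id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
  invisible(path)
}
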