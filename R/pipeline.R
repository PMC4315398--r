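# End-to-end pipeline orchestration with a per-step loss ledger.
#
# The ledger partitions every input read over the processing chain:
# demultiplexing -> assembly -> quality control -> (optional) chimera
# removal -> clustering. At every step reads_out + reads_removed = reads_in,
# and step k's reads_in equals step k-1's reads_out.

new_ledger <- function() {
  structure(list(steps = data.frame(step = character(0),
                                    reads_in = integer(0),
                                    reads_out = integer(0),
                                    reads_removed = integer(0),
                                    stringsAsFactors = FALSE),
                 breakdown = list()),
            class = "loss_ledger")
}

ledger_add <- function(ledger, step, reads_in, reads_out, breakdown) {
  removed <- reads_in - reads_out
  if (removed != sum(breakdown))
    stop("ledger breakdown for '", step, "' does not sum to the removals")
  k <- nrow(ledger$steps)
  if (k > 0 && ledger$steps$reads_out[k] != reads_in)
    stop("ledger chain broken at '", step, "'")
  ledger$steps <- rbind(ledger$steps,
                        data.frame(step = step, reads_in = reads_in,
                                   reads_out = reads_out,
                                   reads_removed = removed,
                                   stringsAsFactors = FALSE))
  ledger$breakdown[[step]] <- breakdown
  ledger
}

#' Validate loss-ledger conservation and chaining
#'
#' Asserts that at every step `reads_out + reads_removed = reads_in`, that
#' consecutive steps chain (`reads_in[k] = reads_out[k-1]`), and that every
#' removal breakdown sums to the step's removals.
#'
#' @param ledger a `loss_ledger` as returned in [run_pipeline()] results.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_ledger <- function(ledger) {
  s <- ledger$steps
  stopifnot(all(s$reads_out + s$reads_removed == s$reads_in))
  if (nrow(s) > 1)
    stopifnot(all(s$reads_in[-1] == s$reads_out[-nrow(s)]))
  for (step in s$step)
    stopifnot(sum(ledger$breakdown[[step]]) ==
                s$reads_removed[s$step == step])
  invisible(TRUE)
}

#' @export
print.loss_ledger <- function(x, ...) {
  cat("loss ledger:\n")
  s <- x$steps
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s in %8d  out %8d  removed %8d\n", s$step[i],
                s$reads_in[i], s$reads_out[i], s$reads_removed[i]))
    b <- x$breakdown[[s$step[i]]]
    b <- b[b > 0]
    if (length(b))
      cat("    ", paste(sprintf("%s=%d", names(b), b), collapse = ", "),
          "\n")
  }
  if (nrow(s) > 0 && s$reads_in[1] > 0)
    cat(sprintf("  retention: %.1f%%\n",
                100 * s$reads_out[nrow(s)] / s$reads_in[1]))
  invisible(x)
}

#' Run the full amplicon processing pipeline
#'
#' Executes demultiplexing, overlap assembly, the QC cascade, an optional de
#' novo chimera scan, dereplication + greedy OTU clustering, and (when the
#' surviving table allows it) rarefaction and alpha/beta diversity, while
#' maintaining the loss ledger. All thresholds default to the protocol
#' values: assembly score 0.6, QC window 10 at mean PHRED 5, overlap cutoff
#' 100 bp, clustering identity 0.97.
#'
#' @param pairs a `read_pairs` data.frame (or a `sim_run`, whose `$pairs` is
#'   used).
#' @param barcodes a `barcode_set`.
#' @param primers primer pair used for QC (see [primer_defaults()]).
#' @param min_overlap,score_threshold assembly parameters.
#' @param window,min_mean_q,max_overlap_length QC parameters.
#' @param identity_threshold,discard_singletons clustering parameters.
#' @param chimera_check run [denovo_chimera_scan()] and drop chimeric reads.
#' @param rarefy `"min"` to rarefy to the smallest sample, a number for an
#'   explicit depth, or `NULL` to skip rarefaction and diversity.
#' @param seed RNG seed for rarefaction.
#' @return A list of class `pipeline_result` with `demux` (summary),
#'   `otu_table`, `otus` (centroids), `alpha` (per-sample estimator
#'   data.frame), `beta` (transformed Bray-Curtis matrix) and `ledger`.
#' @export
run_pipeline <- function(pairs, barcodes, primers = primer_defaults(),
                         min_overlap = 10, score_threshold = 0.6,
                         window = 10, min_mean_q = 5,
                         max_overlap_length = 100,
                         identity_threshold = 0.97,
                         discard_singletons = FALSE,
                         chimera_check = FALSE, rarefy = "min", seed = 1) {
  if (inherits(pairs, "sim_run")) pairs <- pairs$pairs
  n0 <- nrow(pairs)
  ledger <- new_ledger()

  dm <- demultiplex_run(pairs, barcodes)
  ledger <- ledger_add(ledger, "demultiplex", n0, nrow(dm$matched),
                       dm$category_counts[setdiff(names(dm$category_counts),
                                                  "MATCHED")])

  asm <- merge_pairs(dm$matched, min_overlap = min_overlap,
                     score_threshold = score_threshold)
  ok <- asm$status == "assembled"
  ledger <- ledger_add(ledger, "assembly", nrow(asm), sum(ok),
                       c(low_quality = sum(asm$status == "low_quality"),
                         unassembled = sum(asm$status == "unassembled")))
  asm <- asm[ok, , drop = FALSE]

  qc <- apply_qc(asm, primers, max_overlap_length = max_overlap_length,
                 window = window, min_mean_q = min_mean_q)
  ledger <- ledger_add(ledger, "quality_control", nrow(asm),
                       qc$counts[["passed"]],
                       qc$counts[c("no_primer", "undetermined",
                                   "low_quality", "long_overlap")])
  reads <- qc$passed

  if (chimera_check && nrow(reads) > 0) {
    dr <- dereplicate(reads$sequence)
    verdict <- denovo_chimera_scan(dr$unique)
    chim_read <- verdict$chimeric[dr$map]
    ledger <- ledger_add(ledger, "chimera", nrow(reads),
                         sum(!chim_read), c(chimeric = sum(chim_read)))
    reads <- reads[!chim_read, , drop = FALSE]
  }

  otu_table <- NULL
  otus <- NULL
  if (nrow(reads) > 0) {
    dr <- dereplicate(reads$sequence)
    cl <- greedy_otu_cluster(dr$unique,
                             identity_threshold = identity_threshold,
                             discard_singletons = discard_singletons)
    otu_id <- cl$otus$id[cl$membership[dr$map]]
    otu_table <- build_otu_table(otu_id, reads$sample,
                                 sample_levels = barcodes$pairs$sample_id)
    otu_table <- otu_table[rowSums(otu_table) > 0, , drop = FALSE]
    otus <- cl$otus
    ledger <- ledger_add(ledger, "clustering", nrow(reads), sum(otu_table),
                         c(discarded_singletons =
                             nrow(reads) - sum(otu_table)))
  } else {
    ledger <- ledger_add(ledger, "clustering", 0L, 0L,
                         c(discarded_singletons = 0L))
  }
  validate_ledger(ledger)

  alpha <- NULL
  beta <- NULL
  if (!is.null(rarefy) && !is.null(otu_table) && nrow(otu_table) >= 2) {
    depth <- if (identical(rarefy, "min")) min(rowSums(otu_table))
             else as.numeric(rarefy)
    rt <- rarefy_table(otu_table, depth = depth, seed = seed)
    if (nrow(rt) >= 2) {
      alpha <- as.data.frame(t(apply(rt, 1, function(r)
        c(richness_estimators(r), evenness_indices(r)))))
      alpha <- cbind(sample = rownames(rt), alpha)
      rownames(alpha) <- NULL
      beta <- bray_curtis_matrix(rt)
    }
  }

  structure(list(demux = dm[c("category_counts", "sample_counts", "rsd",
                              "pair_counts")],
                 otu_table = otu_table, otus = otus,
                 alpha = alpha, beta = beta, ledger = ledger),
            class = "pipeline_result")
}

#' Render a human-readable + JSON-ready pipeline report
#'
#' Summarizes the demultiplexing category percentages, the per-barcode yield
#' distribution (with its relative standard deviation), the per-filter
#' losses, and the cumulative retention fraction.
#'
#' @param ledger a `loss_ledger`.
#' @param category_counts named integer vector over the five demultiplexing
#'   categories.
#' @param sample_counts named integer vector of per-sample MATCHED yields.
#' @return A list of class `pipeline_report` with `category_counts`,
#'   `category_pct`, `sample_counts`, `sample_rsd`, `steps` (ledger table),
#'   `breakdown` and `retention`.
#' @export
render_report <- function(ledger, category_counts, sample_counts) {
  total <- sum(category_counts)
  pct <- if (total > 0) 100 * category_counts / total else
    setNames(rep(0, length(category_counts)), names(category_counts))
  rsd <- if (length(sample_counts) && mean(sample_counts) > 0)
    sd(sample_counts) / mean(sample_counts) else NA_real_
  s <- ledger$steps
  retention <- if (nrow(s) > 0 && s$reads_in[1] > 0)
    s$reads_out[nrow(s)] / s$reads_in[1] else NA_real_
  structure(list(category_counts = as.list(category_counts),
                 category_pct = as.list(round(pct, 2)),
                 sample_counts = as.list(sample_counts),
                 sample_rsd = rsd,
                 steps = s, breakdown = ledger$breakdown,
                 retention = retention),
            class = "pipeline_report")
}

#' Write a pipeline report as JSON
#'
#' @param report a `pipeline_report`.
#' @param path output JSON path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       dataframe = "rows", digits = NA)
  invisible(path)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline report\n")
  for (k in names(x$category_pct))
    cat(sprintf("  %-12s %6.2f%% (%d reads)\n", k, x$category_pct[[k]],
                x$category_counts[[k]]))
  if (!is.na(x$sample_rsd))
    cat(sprintf("  per-sample RSD: %.1f%%\n", 100 * x$sample_rsd))
  for (i in seq_len(nrow(x$steps)))
    cat(sprintf("  %-16s removed %d of %d\n", x$steps$step[i],
                x$steps$reads_removed[i], x$steps$reads_in[i]))
  if (!is.na(x$retention))
    cat(sprintf("  overall retention: %.1f%%\n", 100 * x$retention))
  invisible(x)
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$ledger)
  if (!is.null(x$otu_table))
    cat("OTU table:", nrow(x$otu_table), "samples x", ncol(x$otu_table),
        "OTUs\n")
  invisible(x)
}
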