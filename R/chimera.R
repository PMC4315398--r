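# Chimera and barcode-crossover diagnostics.
#
# Two independent diagnostics for inter-sample chimera formation during
# pooled library preparation:
#   * a regression of mismatching ordered barcode-pair frequencies against
#     the relative yield of the first barcode; barcodes whose points deviate
#     strongly from the fitted line are suspicious
#   * a simplified abundance-aware de novo chimera scan: a query is chimeric
#     when it splits into a prefix from one abundant parent and a suffix from
#     another.

#' Mismatch-regression points for the barcode-crossover diagnostic
#'
#' For every ordered pair of distinct barcodes (excluding self pairs and
#' correct sample pairings; `B^2 - 2B` points for `B` barcodes), computes
#' \itemize{
#'   \item x: correct matches whose sample involves the first barcode,
#'     divided by all correct matches
#'   \item y: reads observed with this ordered barcode pair, divided by all
#'     mismatching reads involving the second barcode (in either position)
#' }
#' Points whose y denominator is zero (no mismatch involves the second
#' barcode) are omitted with a message.
#'
#' @param pair_counts data.frame `first`/`second`/`count` of ordered
#'   barcode-label pair observations, as produced by [demultiplex_run()]
#'   (`$pair_counts`); must include the correct pairings so the x
#'   denominators can be formed.
#' @param barcodes a `barcode_set`.
#' @return A data.frame with columns `first`, `second`, `x`, `y`, `count`.
#' @export
mismatch_regression_points <- function(pair_counts, barcodes) {
  stopifnot(inherits(barcodes, "barcode_set"))
  lut <- barcode_lookup(barcodes)
  labels <- lut$label
  sample_of <- setNames(lut$sample, lut$label)
  family_of <- setNames(lut$family, lut$label)

  bad <- setdiff(unique(c(pair_counts$first, pair_counts$second)), labels)
  if (length(bad)) stop("unknown barcode labels: ", paste(bad, collapse = ", "))

  grid <- expand.grid(first = labels, second = labels,
                      stringsAsFactors = FALSE)
  key <- paste(grid$first, grid$second)
  cnt <- setNames(rep(0L, nrow(grid)), key)
  obs <- paste(pair_counts$first, pair_counts$second)
  cnt[obs] <- as.integer(pair_counts$count)
  grid$count <- unname(cnt)

  self <- grid$first == grid$second
  correct <- !self &
    sample_of[grid$first] == sample_of[grid$second] &
    family_of[grid$first] != family_of[grid$second]

  total_correct <- sum(grid$count[correct])
  if (total_correct == 0) stop("no correct matches in pair_counts")
  correct_by_sample <- tapply(grid$count[correct],
                              sample_of[grid$first[correct]], sum)

  mism <- grid[!self & !correct, , drop = FALSE]
  # mismatching reads involving each barcode, in either position
  inv <- tapply(c(mism$count, mism$count), c(mism$first, mism$second), sum)
  involving <- setNames(rep(0, length(labels)), labels)
  involving[names(inv)] <- inv

  denom <- involving[mism$second]
  zero <- denom == 0
  if (any(zero))
    message(sum(zero), " point(s) omitted: no mismatches involve the ",
            "second barcode")
  mism <- mism[!zero, , drop = FALSE]
  denom <- denom[!zero]
  out <- data.frame(first = mism$first, second = mism$second,
                    x = unname(correct_by_sample[sample_of[mism$first]] /
                                 total_correct),
                    y = unname(mism$count / denom),
                    count = mism$count, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Flag barcodes whose crossover behaviour deviates from the regression
#'
#' Fits a least-squares line y ~ x through the mismatch-regression points and
#' flags every point whose absolute residual exceeds
#' `residual_sd_multiplier` residual standard deviations; the barcodes
#' appearing in flagged points are implicated.
#'
#' @param points data.frame from [mismatch_regression_points()].
#' @param residual_sd_multiplier flagging threshold in residual SDs
#'   (default 3).
#' @return A list with `points` (input plus `residual` and `flagged`
#'   columns) and `barcodes` (sorted labels implicated by flagged points).
#' @export
flag_crossover_outliers <- function(points, residual_sd_multiplier = 3) {
  stopifnot(nrow(points) >= 3)
  points$residual <- NA_real_
  points$flagged <- FALSE
  if (length(unique(points$x)) < 2) {
    warning("degenerate fit: all x values equal; nothing flagged")
    return(list(points = points, barcodes = character(0)))
  }
  fit <- lm(y ~ x, data = points)
  res <- residuals(fit)
  s <- sd(res)
  points$residual <- unname(res)
  # an (numerically) exact fit has no outliers
  if (is.na(s) || s <= 1e-10 * (1 + max(abs(points$y)))) {
    return(list(points = points, barcodes = character(0)))
  }
  points$flagged <- abs(points$residual) > residual_sd_multiplier * s
  list(points = points,
       barcodes = sort(unique(c(points$first[points$flagged],
                                points$second[points$flagged]))))
}

#' Simplified abundance-aware de novo chimera scan
#'
#' A dereplicated query is called chimeric when some breakpoint splits it
#' into a prefix matching one parent and a suffix matching another (ungapped,
#' each segment at least `min_segment` bp and at least 99% identical to the
#' parent over the segment), with both parents at least `min_parent_fold`
#' times as abundant as the query. A query at least 99% identical to a single
#' more abundant parent over its full length is clean (a point mutant, not a
#' chimera). This is a deliberately simple two-parent breakpoint model.
#'
#' @param derep data.frame with `sequence` and `size` columns (dereplicated,
#'   see [dereplicate()]).
#' @param min_parent_fold minimum parent/query abundance ratio (default 2).
#' @param min_segment minimum matched segment length in bp (default 30).
#' @param max_divergence maximum per-segment mismatch fraction (default 0.01,
#'   i.e. segments must be >= 99% identical).
#' @return The input data.frame with added columns `chimeric` (logical),
#'   `breakpoint`, `parent1`, `parent2` (row indices into `derep`, `NA` for
#'   clean sequences).
#' @export
denovo_chimera_scan <- function(derep, min_parent_fold = 2, min_segment = 30,
                                max_divergence = 0.01) {
  n <- nrow(derep)
  derep$chimeric <- logical(n)
  derep$breakpoint <- NA_integer_
  derep$parent1 <- NA_integer_
  derep$parent2 <- NA_integer_
  if (n == 0) return(derep)
  raws <- lapply(derep$sequence, charToRaw)
  lens <- lengths(raws)
  for (q in seq_len(n)) {
    Lq <- lens[q]
    cand <- which(derep$size >= min_parent_fold * derep$size[q])
    cand <- setdiff(cand, q)
    if (length(cand) == 0) next
    qr <- raws[[q]]
    # single-parent explanation: >= 99% identity over the full length
    single <- FALSE
    for (p in cand) {
      if (lens[p] == Lq &&
          sum(qr != raws[[p]]) <= floor(max_divergence * Lq)) {
        single <- TRUE; break
      }
    }
    if (single) next
    if (Lq < 2 * min_segment) next
    # cumulative mismatches aligned at the start and at the end
    mlen <- pmin(lens[cand], Lq)
    pref <- lapply(seq_along(cand), function(i) {
      m <- mlen[i]
      cumsum(qr[1:m] != raws[[cand[i]]][1:m])
    })
    suf <- lapply(seq_along(cand), function(i) {
      m <- mlen[i]
      p <- raws[[cand[i]]]
      Lp <- lens[cand[i]]
      cumsum(rev(qr)[1:m] != rev(p)[1:m])
    })
    best <- NULL
    for (b in min_segment:(Lq - min_segment)) {
      sl <- Lq - b
      p1ok <- which(vapply(seq_along(cand), function(i)
        b <= mlen[i] && pref[[i]][b] <= floor(max_divergence * b),
        logical(1)))
      if (!length(p1ok)) next
      p2ok <- which(vapply(seq_along(cand), function(i)
        sl <= mlen[i] && suf[[i]][sl] <= floor(max_divergence * sl),
        logical(1)))
      if (!length(p2ok)) next
      # pick a distinct parent pair minimizing total segment mismatches
      for (i in p1ok) for (j in p2ok) {
        if (cand[i] == cand[j]) next
        tot <- pref[[i]][b] + suf[[j]][sl]
        if (is.null(best) || tot < best$tot) {
          best <- list(b = b, p1 = cand[i], p2 = cand[j], tot = tot)
        }
      }
    }
    if (!is.null(best)) {
      derep$chimeric[q] <- TRUE
      derep$breakpoint[q] <- best$b
      derep$parent1[q] <- best$p1
      derep$parent2[q] <- best$p2
    }
  }
  derep
}
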