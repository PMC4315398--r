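# Mock-community simulator for dual-indexed paired-end amplicon runs.
#
# Emulates the failure modes of a real MiSeq amplicon experiment with full
# ground truth: uneven per-barcode yield (log-normal depths), three amplicon
# length classes, position-dependent substitution errors with the reverse
# read of lower quality and decaying toward the 3' end, a small fraction of
# quality-crashed reverse reads, rare undetermined bases, barcode crossover
# at the read-pair level (the library-preparation hypothesis), two-parent
# chimeric amplicons, and corrupted-barcode read pairs.
#
# Substitution-only error model (no indels): substitutions dominate MiSeq
# errors and the assembler is ungapped. Errors never hit the 7 bp barcode
# region: barcode mis-assignment is controlled exclusively by the crossover /
# no-barcode / one-barcode rates, so the recorded ground-truth category of
# every read pair is exact.

#' Build a mock amplicon community
#'
#' Random amplicons flanked by the true (instantiated) primer sequences, with
#' total lengths drawn within the three observed V3-V4 length classes (low
#' <= 446 bp, mid 447-464 bp, high 465-476 bp) and log-normal relative
#' abundances. Degenerate primer positions are instantiated per taxon.
#' Distinct random inserts make taxa mutually far more than 3% divergent by
#' construction.
#'
#' @param n_taxa number of taxa (>= 1).
#' @param class_mix named numeric vector of relative weights for the
#'   `low`/`mid`/`high` length classes.
#' @param abundance_sdlog log-normal sd of the relative abundances
#'   (default 1).
#' @param primer_pair degenerate primer pair (see [primer_defaults()]).
#' @param seed RNG seed; the same seed reproduces the same community.
#' @return A `mock_community`: data.frame with `id`, `sequence`, `length`,
#'   `class` and `abundance` (summing to 1), with the primer pair attached as
#'   an attribute.
#' @export
build_mock_community <- function(n_taxa,
                                 class_mix = c(low = 0.15, mid = 0.55,
                                               high = 0.30),
                                 abundance_sdlog = 1,
                                 primer_pair = primer_defaults(),
                                 seed = 1) {
  stopifnot(n_taxa >= 1)
  if (!all(c("low", "mid", "high") %in% names(class_mix)))
    stop("class_mix must have names low, mid, high")
  if (any(class_mix < 0) || sum(class_mix) <= 0)
    stop("impossible class mix")
  ranges <- list(low = c(430L, 446L), mid = c(447L, 464L),
                 high = c(465L, 476L))
  with_seed(seed, {
    cls <- sample(c("low", "mid", "high"), n_taxa, replace = TRUE,
                  prob = class_mix / sum(class_mix))
    lens <- vapply(cls, function(k)
      sample(ranges[[k]][1]:ranges[[k]][2], 1), integer(1))
    fwd <- vapply(seq_len(n_taxa), function(i)
      instantiate_primer(primer_pair$forward), character(1))
    rev <- vapply(seq_len(n_taxa), function(i)
      instantiate_primer(primer_pair$reverse), character(1))
    insert_len <- lens - nchar(primer_pair$forward) -
      nchar(primer_pair$reverse)
    stopifnot(all(insert_len > 0))
    inserts <- random_dna(insert_len)
    seqs <- paste0(fwd, inserts, revcomp(rev))
    ab <- rlnorm(n_taxa, meanlog = 0, sdlog = abundance_sdlog)
    out <- data.frame(id = sprintf("T%03d", seq_len(n_taxa)),
                      sequence = seqs, length = nchar(seqs),
                      class = unname(cls), abundance = ab / sum(ab),
                      stringsAsFactors = FALSE)
    attr(out, "primer_pair") <- primer_pair
    class(out) <- c("mock_community", "data.frame")
    out
  })
}

# draw a concrete base at every degenerate position of an IUPAC primer
instantiate_primer <- function(primer) {
  map <- Biostrings::IUPAC_CODE_MAP
  chars <- strsplit(primer, "")[[1]]
  paste(vapply(chars, function(ch) {
    opts <- strsplit(map[[ch]], "")[[1]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1)), collapse = "")
}

#' Simulation run configuration
#'
#' @param mean_depth mean read pairs per sample.
#' @param depth_rsd relative standard deviation of the log-normal per-sample
#'   depths (default 0.55, the unevenness observed on real dual-indexed
#'   runs); 0 gives equal depths.
#' @param read_length mate length in bp (default 250).
#' @param crossover_rate probability that a read pair's two barcodes come
#'   from different samples (library-prep crossover).
#' @param chimera_rate probability that an amplicon is a two-parent splice.
#' @param no_barcode_fraction,one_barcode_fraction probabilities that both /
#'   exactly one barcode is corrupted into an unrecognizable tag.
#' @param error_rate_scale multiplies the per-base substitution error
#'   probabilities implied by the quality profiles; 0 disables base-call
#'   errors.
#' @param degraded_fraction fraction of read pairs whose reverse mate has a
#'   quality-crashed 3' tail (default 0.02).
#' @param n_rate per-base probability of an undetermined (N) call.
#' @param chimera_margin minimum distance of a chimeric breakpoint from
#'   either amplicon end (default 50 bp; partial extension products need a
#'   minimal annealing stretch).
#' @param seed RNG seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(mean_depth = 1000, depth_rsd = 0.55,
                       read_length = 250, crossover_rate = 0,
                       chimera_rate = 0, no_barcode_fraction = 0,
                       one_barcode_fraction = 0, error_rate_scale = 1,
                       degraded_fraction = 0.02, n_rate = 5e-6,
                       chimera_margin = 50, seed = 1) {
  rates <- c(crossover_rate, chimera_rate, no_barcode_fraction,
             one_barcode_fraction, degraded_fraction, n_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (crossover_rate + no_barcode_fraction + one_barcode_fraction > 1)
    stop("barcode corruption fractions sum to more than 1")
  stopifnot(mean_depth >= 0, depth_rsd >= 0, read_length >= 50)
  structure(list(mean_depth = mean_depth, depth_rsd = depth_rsd,
                 read_length = read_length, crossover_rate = crossover_rate,
                 chimera_rate = chimera_rate,
                 no_barcode_fraction = no_barcode_fraction,
                 one_barcode_fraction = one_barcode_fraction,
                 error_rate_scale = error_rate_scale,
                 degraded_fraction = degraded_fraction, n_rate = n_rate,
                 chimera_margin = chimera_margin, seed = seed),
            class = "run_config")
}

# position-dependent quality profiles: forward reads average PHRED ~36,
# reverse ~33, both declining toward the 3' end; the crashed profile decays
# to Q2 over the second half of the read
phred_profiles <- function(read_length) {
  list(fwd = as.integer(round(seq(38, 34, length.out = read_length))),
       rev = as.integer(round(seq(39, 27, length.out = read_length))),
       crashed = as.integer(round(c(
         seq(36, 20, length.out = floor(read_length * 0.4)),
         seq(20, 2, length.out = read_length - floor(read_length * 0.4))))))
}

#' Simulate a dual-indexed paired-end amplicon run
#'
#' Draws per-sample depths (log-normal unevenness), samples amplicons from
#' the community by abundance, splices in chimeras, attaches barcodes (with
#' crossover and corrupted-barcode events at the configured rates), emits
#' fixed-length mates in random amplicon orientation with
#' position-dependent substitution errors, and records exact ground truth
#' for every read pair.
#'
#' @param community a `mock_community`.
#' @param barcodes a `barcode_set`; every sample in the set is sequenced.
#' @param config a `run_config`.
#' @return A list of class `sim_run` with `pairs` (a `read_pairs`
#'   data.frame), `truth` (data.frame `id`, `sample`, `taxon`, `category`,
#'   `chimera`) and `depths` (named integer vector of true per-sample
#'   depths).
#' @export
simulate_run <- function(community, barcodes, config = run_config()) {
  stopifnot(inherits(barcodes, "barcode_set"), inherits(config, "run_config"))
  rl <- config$read_length
  L <- barcodes$length
  samples <- barcodes$pairs$sample_id
  ns <- length(samples)
  prof <- phred_profiles(rl)
  with_seed(config$seed, {
    depths <- draw_depths(ns, config$mean_depth, config$depth_rsd)
    names(depths) <- samples
    n <- sum(depths)
    sample_of <- rep(samples, depths)
    taxon_i <- sample.int(nrow(community), n, replace = TRUE,
                          prob = community$abundance)
    taxon <- community$id[taxon_i]
    ampl <- community$sequence[taxon_i]
    chim <- runif(n) < config$chimera_rate
    if (any(chim)) {
      spliced <- splice_chimeras(community, sum(chim), config$chimera_margin)
      ampl[chim] <- spliced$sequence
      taxon[chim] <- spliced$taxon
    }
    # barcode tags; fate: crossover / no-barcode / one-barcode corruption
    tag1 <- barcodes$pairs$forward[match(sample_of, samples)]
    tag2 <- barcodes$pairs$reverse[match(sample_of, samples)]
    u <- runif(n)
    cross <- u < config$crossover_rate
    nobar <- u >= config$crossover_rate &
      u < config$crossover_rate + config$no_barcode_fraction
    onebar <- u >= config$crossover_rate + config$no_barcode_fraction &
      u < config$crossover_rate + config$no_barcode_fraction +
        config$one_barcode_fraction
    all_tags <- c(barcodes$pairs$forward, barcodes$pairs$reverse)
    if (any(cross)) {
      # replace the reverse-side tag with any other barcode except the
      # sample's own pair (another sample's reverse -> CROSS_SAMPLE; any
      # forward -> SAME_FAMILY)
      tag2[cross] <- vapply(which(cross), function(i) {
        pool <- setdiff(all_tags, c(tag1[i], tag2[i]))
        sample(pool, 1)
      }, character(1))
    }
    if (any(nobar)) {
      tag1[nobar] <- junk_tags(sum(nobar), L, all_tags)
      tag2[nobar] <- junk_tags(sum(nobar), L, all_tags)
    }
    if (any(onebar)) {
      side <- runif(sum(onebar)) < 0.5
      j <- which(onebar)
      tag1[j[side]] <- junk_tags(sum(side), L, all_tags)
      tag2[j[!side]] <- junk_tags(sum(!side), L, all_tags)
    }
    category <- truth_category(tag1, tag2, barcodes)

    frag <- paste0(tag1, ampl, revcomp(tag2))
    # orientation: which fragment end is sequenced first is random
    flip <- runif(n) < 0.5
    frag_rc <- revcomp(frag)
    top <- ifelse(flip, frag_rc, frag)
    bottom <- ifelse(flip, frag, frag_rc)
    seq1 <- substr(top, 1, rl)
    seq2 <- substr(bottom, 1, rl)
    # qualities: mate 1 always carries the (better) forward-read profile
    degraded <- runif(n) < config$degraded_fraction
    qual1 <- rep(int_to_phred(prof$fwd), n)
    qual2 <- ifelse(degraded, int_to_phred(prof$crashed),
                    int_to_phred(prof$rev))
    if (config$error_rate_scale > 0) {
      seq1 <- inject_errors(seq1, prof$fwd, config$error_rate_scale,
                            protect = L)
      seq2[!degraded] <- inject_errors(seq2[!degraded], prof$rev,
                                       config$error_rate_scale, protect = L)
      seq2[degraded] <- inject_errors(seq2[degraded], prof$crashed,
                                      config$error_rate_scale, protect = L)
    }
    if (config$n_rate > 0) {
      seq1 <- inject_ns(seq1, config$n_rate, protect = L)
      seq2 <- inject_ns(seq2, config$n_rate, protect = L)
    }
    ids <- sprintf("read%07d", seq_len(n))
    pairs <- data.frame(id = ids, seq1 = seq1, qual1 = qual1,
                        seq2 = seq2, qual2 = qual2, stringsAsFactors = FALSE)
    truth <- data.frame(id = ids, sample = sample_of, taxon = taxon,
                        category = category, chimera = chim,
                        stringsAsFactors = FALSE)
    structure(list(pairs = pairs, truth = truth, depths = depths,
                   config = config), class = "sim_run")
  })
}

# log-normal per-sample depths with the requested mean and RSD
draw_depths <- function(ns, mean_depth, rsd) {
  if (mean_depth == 0) return(rep(0L, ns))
  if (rsd == 0) return(rep(as.integer(round(mean_depth)), ns))
  sdlog <- sqrt(log(1 + rsd^2))
  meanlog <- log(mean_depth) - sdlog^2 / 2
  pmax(1L, as.integer(round(rlnorm(ns, meanlog, sdlog))))
}

# two-parent splices at uniform interior breakpoints
splice_chimeras <- function(community, n, margin) {
  pick <- function() sample.int(nrow(community), 2, replace = FALSE,
                                prob = community$abundance)
  seqs <- character(n)
  tax <- character(n)
  for (k in seq_len(n)) {
    ij <- pick()
    s1 <- community$sequence[ij[1]]
    s2 <- community$sequence[ij[2]]
    hi <- min(nchar(s1), nchar(s2)) - margin
    b <- if (hi <= margin) floor(min(nchar(s1), nchar(s2)) / 2) else
      sample(margin:hi, 1)
    seqs[k] <- paste0(substr(s1, 1, b), substr(s2, b + 1, nchar(s2)))
    tax[k] <- paste0(community$id[ij[1]], "x", community$id[ij[2]])
  }
  list(sequence = seqs, taxon = tax)
}

# random tags guaranteed not to collide with any real barcode
junk_tags <- function(n, L, all_tags) {
  out <- random_dna(rep(L, n))
  bad <- out %in% all_tags
  while (any(bad)) {
    out[bad] <- random_dna(rep(L, sum(bad)))
    bad <- out %in% all_tags
  }
  out
}

# ground-truth category from the two tags actually attached to a fragment
truth_category <- function(tag1, tag2, barcodes) {
  lut <- barcode_lookup(barcodes)
  i1 <- match(tag1, lut$sequence)
  i2 <- match(tag2, lut$sequence)
  cat <- character(length(tag1))
  cat[is.na(i1) & is.na(i2)] <- "NO_BARCODE"
  cat[xor(is.na(i1), is.na(i2))] <- "ONE_BARCODE"
  both <- !is.na(i1) & !is.na(i2)
  same_fam <- both & lut$family[i1] == lut$family[i2]
  matched <- both & !same_fam & lut$sample[i1] == lut$sample[i2]
  cat[same_fam] <- "SAME_FAMILY"
  cat[matched] <- "MATCHED"
  cat[both & !same_fam & !matched] <- "CROSS_SAMPLE"
  cat
}

# position-dependent substitution errors; the first `protect` bases (the
# barcode region) are never touched
inject_errors <- function(seqs, qprofile, scale, protect) {
  n <- length(seqs)
  if (n == 0) return(seqs)
  rl <- length(qprofile)
  perr <- pmin(1, 10^(-qprofile / 10) * scale)
  for (i in (protect + 1):rl) {
    k <- rbinom(1, n, perr[i])
    if (k == 0) next
    idx <- sample.int(n, k)
    cur <- substr(seqs[idx], i, i)
    repl <- vapply(cur, function(b) sample(setdiff(DNA_BASES, b), 1),
                   character(1), USE.NAMES = FALSE)
    substr(seqs[idx], i, i) <- repl
  }
  seqs
}

# rare undetermined base calls
inject_ns <- function(seqs, n_rate, protect) {
  n <- length(seqs)
  if (n == 0) return(seqs)
  rl <- nchar(seqs[1])
  usable <- rl - protect
  total <- rbinom(1, n * usable, n_rate)
  if (total == 0) return(seqs)
  reads <- sample.int(n, total, replace = TRUE)
  pos <- protect + sample.int(usable, total, replace = TRUE)
  for (k in seq_len(total)) substr(seqs[reads[k]], pos[k], pos[k]) <- "N"
  seqs
}

#' @export
print.sim_run <- function(x, ...) {
  cat("sim_run:", nrow(x$pairs), "read pairs over", length(x$depths),
      "samples\n")
  tab <- table(x$truth$category)
  for (k in names(tab)) cat(sprintf("  %-12s %d\n", k, tab[[k]]))
  cat("  chimeric fragments:", sum(x$truth$chimera), "\n")
  invisible(x)
}
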