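test_that("dereplication groups exact duplicates, size-sorted", {
  got <- dereplicate(c("ACGT", "ACGT", "AAAA"))
  expect_identical(got$unique$sequence, c("ACGT", "AAAA"))
  expect_identical(got$unique$size, c(2L, 1L))
  expect_identical(got$map, c(1L, 1L, 2L))
  distinct <- dereplicate(c("TT", "GG", "AA"))
  expect_identical(distinct$unique$size, rep(1L, 3))
  expect_identical(distinct$unique$sequence, sort(c("TT", "GG", "AA")))
  empty <- dereplicate(character(0))
  expect_identical(nrow(empty$unique), 0L)
})

test_that("greedy clustering honors the 97% identity threshold", {
  set.seed(21)
  base <- random_seq(400)
  mutate <- function(s, k) {
    pos <- sample(nchar(s), k)
    for (p in pos) substr(s, p, p) <- chartr("ACGT", "CATG",
                                             substr(s, p, p))
    s
  }
  near <- mutate(base, 8)    # 2% divergent -> joins
  far <- mutate(base, 40)    # 10% divergent -> separate OTU
  dr <- dereplicate(c(rep(base, 5), rep(near, 2), rep(far, 3)))
  cl <- greedy_otu_cluster(dr$unique)
  expect_identical(nrow(cl$otus), 2L)
  expect_identical(cl$otus$centroid[1], base)
  expect_identical(cl$otus$size, c(7L, 3L))
  # identical sequences collapse into one OTU at dereplication
  two <- greedy_otu_cluster(dereplicate(c("ACGTACGT", "ACGTACGT"))$unique)
  expect_identical(nrow(two$otus), 1L)
  expect_identical(two$otus$size, 2L)
})

test_that("singleton discarding follows the UPARSE convention", {
  set.seed(22)
  base <- random_seq(300)
  lone <- random_seq(300)
  near_single <- base
  substr(near_single, 5, 5) <- chartr("ACGT", "CATG", substr(base, 5, 5))
  dr <- dereplicate(c(rep(base, 4), near_single, lone))
  cl <- greedy_otu_cluster(dr$unique, discard_singletons = TRUE)
  expect_identical(nrow(cl$otus), 1L)           # lone singleton founds nothing
  expect_identical(cl$otus$size, 5L)            # near-singleton still maps
  expect_true(is.na(cl$membership[dr$unique$sequence == lone]))
})

test_that("membership radius and centroid separation hold against an
           independent aligner", {
  set.seed(23)
  bases <- replicate(8, random_seq(320))
  seqs <- character(0)
  sizes <- integer(0)
  for (b in bases) {
    seqs <- c(seqs, b)
    sizes <- c(sizes, sample(10:20, 1))
    for (k in 1:4) {
      m <- b
      for (p in sample(320, sample(2:6, 1)))
        substr(m, p, p) <- chartr("ACGT", "CATG", substr(m, p, p))
      seqs <- c(seqs, m)
      sizes <- c(sizes, sample(2:5, 1))
    }
  }
  derep <- data.frame(sequence = seqs, size = sizes,
                      stringsAsFactors = FALSE)
  derep <- derep[!duplicated(derep$sequence), ]
  cl <- greedy_otu_cluster(derep)
  derep_sorted <- derep[order(-derep$size, derep$sequence), ]
  memb <- cl$membership[order(-derep$size, derep$sequence)]
  # every member within the identity radius of its centroid
  for (i in seq_len(nrow(derep_sorted))) {
    if (is.na(memb[i])) next
    id <- oracle_identity(derep_sorted$sequence[i],
                          cl$otus$centroid[memb[i]])
    expect_gte(id, 0.97)
  }
  # centroids mutually below the threshold
  nc <- nrow(cl$otus)
  for (i in seq_len(nc - 1)) for (j in (i + 1):nc) {
    expect_lt(oracle_identity(cl$otus$centroid[i], cl$otus$centroid[j]),
              0.97)
  }
})

test_that("clustering duplicates inflates sizes but keeps the centroids", {
  set.seed(24)
  seqs <- replicate(6, random_seq(250))
  dr1 <- dereplicate(seqs)
  dr2 <- dereplicate(c(seqs, seqs))
  cl1 <- greedy_otu_cluster(dr1$unique)
  cl2 <- greedy_otu_cluster(dr2$unique)
  expect_setequal(cl1$otus$centroid, cl2$otus$centroid)
  expect_identical(sort(cl2$otus$size), sort(2L * cl1$otus$size))
})

test_that("OTU tables have correct marginals and drop empty columns", {
  ids <- c("OTU_1", "OTU_1", "OTU_1", "OTU_2", NA)
  samp <- c("A", "A", "B", "B", "B")
  tab <- build_otu_table(ids, samp)
  expect_identical(dim(tab), c(2L, 2L))
  expect_identical(unname(rowSums(tab)), c(2, 2))
  expect_identical(unname(tab["A", "OTU_1"]), 2L)
  single <- build_otu_table(rep("OTU_9", 3), rep("A", 3))
  expect_identical(unname(single[1, 1]), 3L)
  # all-NA OTU columns never appear
  expect_identical(ncol(build_otu_table(c("OTU_1", NA), c("A", "A"),
                                        sample_levels = c("A", "B"))), 1L)
  expect_error(build_otu_table("OTU_1", "C", sample_levels = c("A", "B")),
               "unknown sample")
})

test_that("reads are conserved through clustering and table building", {
  bs <- design_barcode_set(4, seed = 19)
  comm <- build_mock_community(10, seed = 19)
  run <- simulate_run(comm, bs, run_config(mean_depth = 200, seed = 19))
  dm <- demultiplex_run(run$pairs, bs)
  asm <- merge_pairs(dm$matched)
  asm <- asm[asm$status == "assembled", ]
  qc <- apply_qc(asm)
  dr <- dereplicate(qc$passed$sequence)
  cl <- greedy_otu_cluster(dr$unique, discard_singletons = TRUE)
  otu_id <- cl$otus$id[cl$membership[dr$map]]
  tab <- build_otu_table(otu_id, qc$passed$sample)
  expect_identical(sum(tab) + sum(is.na(otu_id)), nrow(qc$passed))
})

test_that("trimming to length keeps prefixes and discards short reads", {
  got <- trim_to_length(c(strrep("A", 450), strrep("C", 400),
                          strrep("G", 350)), target = 400)
  expect_identical(nchar(got$sequences), c(400L, 400L))
  expect_identical(got$n_discarded, 1L)
  expect_identical(got$sequences[2], strrep("C", 400))
})

test_that("length-fraction bins split at 446 and 464 bp", {
  seqs <- c(strrep("A", 440), strrep("C", 446), strrep("G", 447),
            strrep("T", 455), strrep("A", 464), strrep("C", 465),
            strrep("G", 470))
  got <- bin_length_fractions(seqs)
  expect_identical(as.character(got$bin),
                   c("low", "low", "mid", "mid", "mid", "high", "high"))
  expect_identical(length(got$low) + length(got$mid) + length(got$high),
                   length(seqs))
})
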