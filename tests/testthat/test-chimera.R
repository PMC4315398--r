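test_that("mismatch-regression coordinates reproduce the hand-computed toy", {
  bs <- toy_barcode_set()
  pc <- data.frame(first = c("F01", "F02", "F01", "R01"),
                   second = c("R01", "R02", "R02", "R02"),
                   count = c(90L, 10L, 5L, 5L), stringsAsFactors = FALSE)
  pts <- mismatch_regression_points(pc, bs)
  p <- pts[pts$first == "F01" & pts$second == "R02", ]
  expect_identical(nrow(p), 1L)
  expect_identical(p$x, 0.9)   # 90 of 100 correct matches involve F01
  expect_identical(p$y, 0.5)   # 5 of 10 mismatches involve R02
})

test_that("complete count tables yield B^2 - 2B points", {
  bs <- design_barcode_set(5, seed = 4)   # B = 10 barcodes
  labels <- c(names(bs$forward), names(bs$reverse))
  grid <- expand.grid(first = labels, second = labels,
                      stringsAsFactors = FALSE)
  grid$count <- 1L
  # make the correct pairings dominant so x denominators are sensible
  correct <- grid$first %in% names(bs$forward) &
    grid$second == sub("F", "R", grid$first)
  correct_rev <- grid$first %in% names(bs$reverse) &
    grid$second == sub("R", "F", grid$first)
  grid$count[correct | correct_rev] <- 50L
  pts <- mismatch_regression_points(grid, bs)
  expect_identical(nrow(pts), 80L)
  expect_true(all(pts$x >= 0 & pts$x <= 1))
  expect_true(all(pts$y >= 0 & pts$y <= 1))
  # per-second-barcode shares never sum above 1
  agg <- tapply(pts$y, pts$second, sum)
  expect_true(all(agg <= 1 + 1e-12))
})

test_that("runs without crossover yield an empty point list", {
  bs <- toy_barcode_set()
  pc <- data.frame(first = c("F01", "F02"), second = c("R01", "R02"),
                   count = c(10L, 10L), stringsAsFactors = FALSE)
  expect_message(pts <- mismatch_regression_points(pc, bs), "omitted")
  expect_identical(nrow(pts), 0L)
})

test_that("outlier flagging reacts to displacement, not to on-line points", {
  set.seed(3)
  n <- 200
  x <- runif(n)
  exact <- data.frame(first = sprintf("F%02d", rep(1:20, 10)),
                      second = sprintf("R%02d", rep(1:10, 20)),
                      x = x, y = 0.3 * x + 0.1,
                      count = 1L, stringsAsFactors = FALSE)
  none <- flag_crossover_outliers(exact)
  expect_length(none$barcodes, 0L)
  noisy <- exact
  noisy$y <- noisy$y + rnorm(n, sd = 0.01)
  s <- sd(residuals(lm(y ~ x, noisy)))
  noisy$y[7] <- noisy$y[7] + 10 * s
  got <- flag_crossover_outliers(noisy)
  expect_true(got$points$flagged[7])
  expect_true(noisy$first[7] %in% got$barcodes)
  # under pure noise the flag rate stays near the 3-sigma expectation
  calm <- exact
  calm$y <- calm$y + rnorm(n, sd = 0.01)
  expect_lte(sum(flag_crossover_outliers(calm)$points$flagged), n * 0.02)
  # degenerate fit warns and flags nothing
  flat <- exact
  flat$x <- 0.5
  expect_warning(res <- flag_crossover_outliers(flat), "degenerate")
  expect_length(res$barcodes, 0L)
})

test_that("two-parent splices are recovered with their breakpoint", {
  set.seed(12)
  a <- random_seq(450)
  b <- random_seq(450)
  chim <- paste0(substr(a, 1, 200), substr(b, 201, 450))
  derep <- data.frame(sequence = c(a, b, chim), size = c(20L, 20L, 1L),
                      stringsAsFactors = FALSE)
  got <- denovo_chimera_scan(derep)
  expect_identical(got$chimeric, c(FALSE, FALSE, TRUE))
  expect_lte(abs(got$breakpoint[3] - 200L), 5L)
  expect_setequal(c(got$parent1[3], got$parent2[3]), c(1L, 2L))
})

test_that("point mutants and low-abundance parents stay clean", {
  set.seed(13)
  a <- random_seq(400)
  mutant <- a
  substr(mutant, 100, 100) <- chartr("ACGT", "CATG", substr(a, 100, 100))
  derep <- data.frame(sequence = c(a, mutant), size = c(50L, 2L),
                      stringsAsFactors = FALSE)
  expect_identical(denovo_chimera_scan(derep)$chimeric, c(FALSE, FALSE))
  # parents less abundant than the query cannot explain it
  b <- random_seq(400)
  chim <- paste0(substr(a, 1, 150), substr(b, 151, 400))
  weak <- data.frame(sequence = c(chim, a, b), size = c(10L, 5L, 5L),
                     stringsAsFactors = FALSE)
  expect_identical(denovo_chimera_scan(weak)$chimeric[1], FALSE)
})

test_that("the scan recovers injected chimeras on a simulated run", {
  bs <- design_barcode_set(5, seed = 31)
  comm <- build_mock_community(12, abundance_sdlog = 0.7, seed = 31)
  cfg <- quiet_config(mean_depth = 500, chimera_rate = 0.05, seed = 31)
  run <- simulate_run(comm, bs, cfg)
  dm <- demultiplex_run(run$pairs, bs)
  asm <- merge_pairs(dm$matched)
  asm <- asm[asm$status == "assembled", ]
  dr <- dereplicate(asm$sequence)
  verdict <- denovo_chimera_scan(dr$unique)
  # a unique sequence is truly chimeric iff its reads were spliced
  truth_by_read <- setNames(run$truth$chimera, run$truth$id)
  true_chim <- tapply(truth_by_read[asm$id], dr$map, any)
  true_chim <- unname(true_chim[order(as.integer(names(true_chim)))])
  recall <- sum(verdict$chimeric & true_chim) / sum(true_chim)
  fpr <- sum(verdict$chimeric & !true_chim) / sum(!true_chim)
  expect_gte(recall, 0.9)
  expect_lte(fpr, 0.05)
})
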