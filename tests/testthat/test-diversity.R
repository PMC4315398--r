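test_that("richness estimators reproduce their closed forms", {
  got <- richness_estimators(c(1, 1, 2, 3))
  expect_identical(unname(got["observed"]), 4)
  expect_identical(unname(got["chao1"]), 6)       # 4 + 2^2 / (2*1)
  no_singletons <- richness_estimators(c(2, 2, 2))
  expect_identical(unname(no_singletons["chao1"]), 3)
  abundant <- richness_estimators(c(20, 30, 40))
  expect_identical(unname(abundant["ace"]), 3)    # no rare class
  all_single <- richness_estimators(c(1, 1, 1))
  expect_true(is.na(all_single["ace"]))           # zero rare-class coverage
  expect_error(richness_estimators(c(0, 0)), "all zero")
})

test_that("chao1 dominates observed richness, with equality iff F1 = 0", {
  set.seed(31)
  for (i in 1:50) {
    x <- rpois(sample(5:40, 1), sample(1:6, 1))
    x <- x[x > 0]
    if (!length(x)) next
    got <- richness_estimators(x)
    expect_gte(got[["chao1"]], got[["observed"]])
    if (sum(x == 1) == 0) expect_identical(got[["chao1"]], got[["observed"]])
    else expect_gt(got[["chao1"]], got[["observed"]])
  }
})

test_that("ACE agrees with the vegan implementation", {
  set.seed(32)
  for (i in 1:20) {
    x <- rpois(40, 4)
    x <- x[x > 0]
    mine <- richness_estimators(x)[["ace"]]
    ref <- unname(vegan::estimateR(x)["S.ACE"])
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("evenness indices match their formulas and scale invariance", {
  got <- evenness_indices(c(10, 10, 10, 10))
  expect_equal(unname(got["shannon"]), log(4))
  expect_equal(unname(got["pielou"]), 1)
  single <- evenness_indices(c(42))
  expect_identical(unname(single["simpson"]), 0)
  expect_true(is.na(single["pielou"]))
  set.seed(33)
  x <- rpois(20, 5) + 1
  expect_equal(evenness_indices(x), evenness_indices(7 * x))
})

test_that("estimators are invariant under OTU column permutation", {
  set.seed(34)
  x <- rpois(30, 3)
  x <- x[x > 0]
  perm <- sample(x)
  expect_identical(richness_estimators(x), richness_estimators(perm))
  expect_equal(evenness_indices(x), evenness_indices(perm))
})

test_that("rarefaction subsamples to exact depth, deterministically", {
  tab <- rbind(A = c(10L, 0L), B = c(6L, 14L))
  colnames(tab) <- c("o1", "o2")
  one <- rarefy_table(tab, depth = 5, seed = 4)
  expect_identical(unname(rowSums(one)), c(5, 5))
  expect_identical(unname(one["A", "o1"]), 5L)    # only one species present
  expect_identical(rarefy_table(tab, depth = 5, seed = 4), one)
  full <- rarefy_table(tab, depth = 10, seed = 1)
  expect_identical(unname(full["A", ]), c(10L, 0L)[1:ncol(full)])
  expect_error(rarefy_table(tab, depth = 0), "positive")
  expect_warning(dropped <- rarefy_table(rbind(tab, C = c(1L, 1L)),
                                         depth = 5, seed = 1),
                 "below depth")
  expect_identical(nrow(dropped), 2L)
})

test_that("rarefaction converges on hypergeometric expectations and
           richness is monotone in depth", {
  tab <- matrix(c(60L, 30L, 10L), 1, dimnames = list("A", c("x", "y", "z")))
  means <- Reduce(`+`, lapply(1:300, function(s) {
    r <- rarefy_table(tab, depth = 20, seed = s)
    v <- setNames(numeric(3), c("x", "y", "z"))
    v[colnames(r)] <- r[1, ]
    v
  })) / 300
  means <- unname(means)
  expect_equal(means, c(12, 6, 2), tolerance = 0.12)
  set.seed(35)
  big <- matrix(rpois(40, 2L), 2, 20,
                dimnames = list(c("A", "B"), sprintf("o%d", 1:20)))
  big <- big[, colSums(big) > 0]
  storage.mode(big) <- "integer"
  obs <- vapply(c(5, 10, 15, 20), function(d) {
    r <- rarefy_table(big, depth = d, seed = 9)
    min(rowSums(r > 0))
  }, numeric(1))
  expect_true(all(diff(obs) >= 0))
})

test_that("transformed Bray-Curtis matches an independent implementation", {
  set.seed(36)
  for (i in 1:5) {
    tab <- matrix(rpois(40, 6), 5, 8,
                  dimnames = list(sprintf("s%d", 1:5), sprintf("o%d", 1:8)))
    tab[tab == 0] <- 1L
    got <- bray_curtis_matrix(tab)
    expect_equal(got, oracle_bray_curtis(tab), tolerance = 1e-12)
  }
  ident <- rbind(A = c(3L, 4L), B = c(3L, 4L))
  colnames(ident) <- c("o1", "o2")
  expect_equal(max(abs(bray_curtis_matrix(ident))), 0)
  disjoint <- rbind(A = c(5L, 0L), B = c(0L, 7L))
  colnames(disjoint) <- c("o1", "o2")
  expect_equal(bray_curtis_matrix(disjoint)["A", "B"], 1)
})

test_that("weighted UniFrac matches closed forms on star trees", {
  star2 <- ape::read.tree(text = "(o1:1,o2:1);")
  tab <- rbind(A = c(10L, 0L), B = c(0L, 5L))
  colnames(tab) <- c("o1", "o2")
  expect_equal(unname(weighted_unifrac(tab, star2,
                                       normalized = FALSE)["A", "B"]), 2)
  expect_equal(unname(weighted_unifrac(tab, star2)["A", "B"]), 1)
  expect_equal(unname(weighted_unifrac(tab, star2)["A", "A"]), 0)
  # star tree with unit branches: raw distance = L1 on proportions
  set.seed(37)
  k <- 6
  star <- ape::read.tree(
    text = paste0("(", paste(sprintf("o%d:1", 1:k), collapse = ","), ");"))
  tab2 <- matrix(rpois(2 * k, 8) + 1L, 2, k,
                 dimnames = list(c("A", "B"), sprintf("o%d", 1:k)))
  p <- tab2 / rowSums(tab2)
  l1 <- sum(abs(p[1, ] - p[2, ]))
  expect_equal(unname(weighted_unifrac(tab2, star,
                                       normalized = FALSE)["A", "B"]), l1)
  expect_equal(unname(weighted_unifrac(tab2, star)["A", "B"]), l1 / 2)
  # proportions only: scaling one sample changes nothing
  tab3 <- tab2
  tab3[1, ] <- tab3[1, ] * 13L
  expect_equal(weighted_unifrac(tab3, star), weighted_unifrac(tab2, star))
  expect_error(weighted_unifrac(cbind(tab2, extra = c(1L, 1L)), star),
               "missing from tree")
})

test_that("UPGMA is ultrametric and reconstructs ultrametric inputs", {
  d2 <- matrix(c(0, 0.8, 0.8, 0), 2, dimnames = list(c("A", "B"),
                                                     c("A", "B")))
  tr <- upgma_tree(d2)
  expect_equal(sort(tr$edge.length), c(0.4, 0.4))
  # a matrix derived from a known ultrametric tree comes back exactly
  ref <- ape::read.tree(text = "((A:1,B:1):2,(C:2.5,D:2.5):0.5);")
  dref <- cophenetic(ref)
  rec <- upgma_tree(dref)
  expect_equal(cophenetic(rec)[rownames(dref), colnames(dref)], dref)
  expect_true(ape::is.ultrametric(rec))
  expect_error(upgma_tree(matrix(0, 1, 1)), "at least 2")
})

test_that("PERMANOVA agrees with vegan::adonis2 and detects structure", {
  set.seed(38)
  m <- matrix(rnorm(60), 12, 5)
  d <- as.matrix(dist(m))
  g <- rep(c("a", "b"), each = 6)
  mine <- permanova(d, g, n_permutations = 99, seed = 1)
  ref <- vegan::adonis2(as.dist(d) ~ g, permutations = 99)
  expect_equal(mine$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_equal(mine$R2, ref$R2[1], tolerance = 1e-10)
  expect_true(mine$R2 >= 0 && mine$R2 <= 1)
  # planted structure: two well-separated clouds (10 + 10 so permutation
  # ties cannot floor the p-value above 1/(1+999))
  sep <- rbind(matrix(rnorm(50), 10), matrix(rnorm(50, mean = 8), 10))
  ds <- as.matrix(dist(sep))
  strong <- permanova(ds, rep(c("a", "b"), each = 10),
                      n_permutations = 999, seed = 2)
  expect_lte(strong$p, 0.001)
  expect_error(permanova(d, c(rep("a", 11), "b")), "at least 2 members")
})

test_that("permutational ANOVA behaves on null, shifted and constant data", {
  set.seed(39)
  g <- rep(c("a", "b"), each = 8)
  null <- perm_anova_alpha(rnorm(16), g, n_permutations = 199, seed = 1)
  expect_true(null$p > 0.01)
  shifted <- perm_anova_alpha(c(rnorm(8), rnorm(8, mean = 5)), g,
                              n_permutations = 999, seed = 1)
  expect_lte(shifted$p, 0.005)
  expect_gt(shifted$R2, 0.5)
  flat <- perm_anova_alpha(rep(3, 16), g)
  expect_identical(flat$R2, 0)
  expect_identical(flat$p, 1)
  same_means <- perm_anova_alpha(rep(c(1, 2), 8), g, n_permutations = 99,
                                 seed = 1)
  expect_lt(same_means$R2, 0.05)
})

test_that("Mantel correlation is exact for identical and scaled matrices", {
  set.seed(40)
  m <- matrix(rnorm(50), 10, 5)
  d1 <- as.matrix(dist(m))
  expect_equal(mantel_test(d1, d1, n_permutations = 99, seed = 1)$r, 1)
  expect_equal(mantel_test(d1, 2 * d1, n_permutations = 99, seed = 1)$r, 1)
  ref <- vegan::mantel(as.dist(d1), as.dist(sqrt(d1)), permutations = 99)
  expect_equal(mantel_test(d1, sqrt(d1), n_permutations = 99, seed = 1)$r,
               unname(ref$statistic), tolerance = 1e-10)
  expect_warning(mantel_test(matrix(0, 3, 3), d1[1:3, 1:3]), "constant")
})

test_that("occupancy-accumulation curves are monotone with exact endpoints", {
  tab <- rbind(A = c(5L, 1L, 0L), B = c(2L, 0L, 3L))
  colnames(tab) <- c("core", "rare1", "rare2")
  got <- occupancy_accumulation(tab)
  expect_equal(got$reads[got$occupancy_pct == 0], sum(tab))
  expect_equal(got$reads[got$occupancy_pct == 100], 7)  # core only
  expect_true(all(diff(got$reads) <= 0))
  flat <- occupancy_accumulation(matrix(c(3L, 2L), 1,
                                        dimnames = list("A", c("x", "y"))))
  expect_true(all(flat$reads == 5))
})
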