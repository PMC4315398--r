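# Alpha and beta diversity statistics for OTU tables: rarefaction, richness
# (observed, Chao1, ACE) and evenness (Shannon, Simpson, Pielou) estimators,
# transformed Bray-Curtis and weighted UniFrac distance matrices, UPGMA
# dendrograms, permutation tests (PERMANOVA on distance matrices,
# permutational ANOVA on univariate responses, Mantel) and
# occupancy-accumulation curves.

#' Rarefy an OTU table to even depth
#'
#' Each sample is subsampled uniformly without replacement to exactly
#' `depth` reads. Samples with fewer reads than `depth` are dropped with a
#' warning (samples with too few sequences cannot be rarefied and are better
#' excluded from depth-sensitive comparisons).
#'
#' @param table integer matrix, samples x OTUs.
#' @param depth target depth; defaults to the smallest row sum.
#' @param seed integer seed; the same seed reproduces the same subsample.
#' @return The rarefied table (row sums all equal to `depth`); all-zero OTU
#'   columns are dropped.
#' @export
rarefy_table <- function(table, depth = min(rowSums(table)), seed = 1) {
  if (depth <= 0) stop("rarefaction depth must be positive")
  low <- rowSums(table) < depth
  if (any(low)) {
    warning("dropping ", sum(low), " sample(s) below depth ", depth, ": ",
            paste(rownames(table)[low], collapse = ", "))
    table <- table[!low, , drop = FALSE]
  }
  out <- with_seed(seed, t(apply(table, 1, function(r) {
    take <- sample(rep.int(seq_along(r), r), depth)
    tabulate(take, nbins = length(r))
  })))
  dimnames(out) <- dimnames(table)
  out <- out[, colSums(out) > 0, drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

#' Richness estimators: observed, Chao1 and ACE
#'
#' Chao1 uses the classic form `S_obs + F1^2 / (2 F2)` with the
#' `S_obs + F1 (F1 - 1) / 2` fallback when no doubletons exist. ACE is the
#' abundance-based coverage estimator with the rare class at abundance
#' <= 10; it is undefined (NA) when the sample coverage of the rare class is
#' zero (all rare individuals are singletons).
#'
#' @param x non-negative integer abundance vector, not all zero.
#' @return Named numeric vector `observed`, `chao1`, `ace`.
#' @examples
#' richness_estimators(c(1, 1, 2, 3))  # chao1 = 4 + 4/2 = 6
#' @export
richness_estimators <- function(x) {
  x <- x[x > 0]
  if (length(x) == 0) stop("abundance vector is all zero")
  s_obs <- length(x)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  chao1 <- if (f2 > 0) s_obs + f1^2 / (2 * f2) else
    s_obs + f1 * (f1 - 1) / 2
  # ACE, rare-abundance cutoff 10
  rare <- x[x <= 10]
  s_abund <- sum(x > 10)
  s_rare <- length(rare)
  n_rare <- sum(rare)
  if (s_rare == 0) {
    ace <- s_obs  # no rare class
  } else {
    c_ace <- 1 - f1 / n_rare
    if (c_ace <= 0) {
      ace <- NA_real_
    } else {
      i <- 1:10
      fi <- vapply(i, function(k) sum(rare == k), numeric(1))
      g2 <- max(s_rare / c_ace * sum(i * (i - 1) * fi) /
                  (n_rare * (n_rare - 1)) - 1, 0)
      if (!is.finite(g2)) g2 <- 0
      ace <- s_abund + s_rare / c_ace + f1 / c_ace * g2
    }
  }
  c(observed = s_obs, chao1 = chao1, ace = ace)
}

#' Evenness indices: Shannon, Simpson and Pielou
#'
#' Shannon is `H = -sum p log p` (natural log), Simpson is reported as the
#' probability of interspecific encounter `1 - sum p^2` (values near 1 for
#' even communities), and Pielou is `H / log(S_obs)` (undefined for a single
#' species, reported as NA; Simpson is then 0).
#'
#' @param x non-negative abundance vector, not all zero. Results depend only
#'   on proportions.
#' @return Named numeric vector `shannon`, `simpson`, `pielou`.
#' @export
evenness_indices <- function(x) {
  x <- x[x > 0]
  if (length(x) == 0) stop("abundance vector is all zero")
  p <- x / sum(x)
  h <- -sum(p * log(p))
  simpson <- 1 - sum(p^2)
  pielou <- if (length(x) > 1) h / log(length(x)) else NA_real_
  c(shannon = h, simpson = simpson, pielou = pielou)
}

#' Transformed Bray-Curtis distance matrix
#'
#' Counts are square-root transformed, Wisconsin double standardized (each
#' OTU divided by its maximum, then each sample by its total) and the
#' Bray-Curtis dissimilarity `sum |x_i - y_i| / sum (x_i + y_i)` is computed
#' between all sample pairs. Intended for rarefied tables.
#'
#' @param table samples x OTUs matrix.
#' @param transform `"sqrt"` (default) or `"none"`.
#' @return A symmetric distance matrix with sample labels, values in
#'   \[0, 1\].
#' @export
bray_curtis_matrix <- function(table, transform = c("sqrt", "none")) {
  transform <- match.arg(transform)
  x <- if (transform == "sqrt") sqrt(table) else table
  zero <- rowSums(x) == 0
  if (any(zero))
    stop("sample(s) with zero total after transform: ",
         paste(rownames(table)[zero], collapse = ", "))
  w <- vegan::wisconsin(x)
  d <- as.matrix(vegan::vegdist(w, method = "bray"))
  dimnames(d) <- list(rownames(table), rownames(table))
  d
}

#' Weighted UniFrac distance matrix
#'
#' For samples A and B, the raw weighted UniFrac distance is
#' `sum_b l_b |p_A(b) - p_B(b)|` over all branches b, where `l_b` is the
#' branch length and `p(b)` the fraction of the sample's reads descending
#' from the branch; the normalized variant divides by
#' `sum_b l_b (p_A(b) + p_B(b))` so values lie in \[0, 1\].
#'
#' @param table samples x OTUs matrix; column names must be tree tips.
#' @param tree a rooted `phylo` tree whose tips cover all table OTUs.
#' @param normalized return the normalized variant (default `TRUE`).
#' @return A symmetric distance matrix with sample labels.
#' @export
weighted_unifrac <- function(table, tree, normalized = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  missing <- setdiff(colnames(table), tree$tip.label)
  if (length(missing))
    stop("OTU(s) missing from tree: ", paste(missing, collapse = ", "))
  ns <- nrow(table)
  rel <- table / rowSums(table)
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  # node masses per sample, accumulated tips -> root
  mass <- matrix(0, nnode, ns)
  idx <- match(tr$tip.label, colnames(table))
  has <- !is.na(idx)
  mass[which(has), ] <- t(rel[, idx[has], drop = FALSE])
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]
    child <- tr$edge[e, 2]
    mass[parent, ] <- mass[parent, ] + mass[child, ]
  }
  w <- tr$edge.length
  m_child <- mass[tr$edge[, 2], , drop = FALSE]       # branches x samples
  raw <- as.matrix(dist(t(m_child * w), method = "manhattan"))
  if (!normalized) {
    dimnames(raw) <- list(rownames(table), rownames(table))
    return(raw)
  }
  s <- colSums(m_child * w)
  denom <- outer(s, s, "+")
  d <- raw / denom
  d[denom == 0] <- 0
  diag(d) <- 0
  dimnames(d) <- list(rownames(table), rownames(table))
  d
}

#' UPGMA dendrogram from a distance matrix
#'
#' Average-linkage agglomerative clustering; the result is ultrametric (all
#' tips equidistant from the root).
#'
#' @param d symmetric distance matrix (or `dist`) over >= 2 samples.
#' @return An ultrametric `phylo` tree.
#' @export
upgma_tree <- function(d) {
  d <- as.dist(d)
  if (attr(d, "Size") < 2) stop("UPGMA needs at least 2 samples")
  ape::as.phylo(hclust(d, method = "average"))
}

#' PERMANOVA on a distance matrix
#'
#' Partitions the squared distances: `SS_total = sum_{i<j} d_ij^2 / n`,
#' `SS_within` summed over within-group pairs (each group divided by its
#' size), `pseudo-F = (SS_between / (g - 1)) / (SS_within / (n - g))` and
#' `R^2 = SS_between / SS_total`. The p-value is estimated by shuffling the
#' group labels: `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_permutations)`.
#'
#' @param d symmetric distance matrix with labels matching `groups` order.
#' @param groups group label per sample; >= 2 groups of >= 2 members.
#' @param n_permutations number of label permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return A list with `pseudo_F`, `R2` and `p`.
#' @export
permanova <- function(d, groups, n_permutations = 999, seed = 1) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(length(groups) == n)
  groups <- as.factor(groups)
  sizes <- table(groups)
  if (length(sizes) < 2) stop("PERMANOVA needs at least 2 groups")
  if (any(sizes < 2)) stop("every group needs at least 2 members")
  g <- length(sizes)
  d2 <- d^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_stat <- function(lab) {
    ssw <- 0
    for (lev in levels(lab)) {
      i <- which(lab == lev)
      ssw <- ssw + sum(d2[i, i]) / (2 * length(i))
    }
    ssw
  }
  ssw_obs <- ss_stat(groups)
  ssb_obs <- ss_total - ssw_obs
  f_obs <- (ssb_obs / (g - 1)) / (ssw_obs / (n - g))
  r2 <- ssb_obs / ss_total
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_permutations), function(i) {
      lab <- groups[sample.int(n)]
      ssw <- ss_stat(lab)
      f <- ((ss_total - ssw) / (g - 1)) / (ssw / (n - g))
      f >= f_obs
    }, logical(1)))
  })
  list(pseudo_F = f_obs, R2 = r2, p = (1 + hits) / (1 + n_permutations))
}

#' Permutational ANOVA on a univariate response
#'
#' Between-group / total sum-of-squares ratio with a permutation p-value
#' (group labels shuffled). A constant response yields `R2 = 0` and `p = 1`
#' by convention.
#'
#' @param values numeric response per sample.
#' @param groups group label per sample; >= 2 groups of >= 2 members.
#' @param n_permutations,seed as in [permanova()].
#' @return A list with `R2` and `p`.
#' @export
perm_anova_alpha <- function(values, groups, n_permutations = 999, seed = 1) {
  stopifnot(length(values) == length(groups))
  groups <- as.factor(groups)
  sizes <- table(groups)
  if (length(sizes) < 2) stop("needs at least 2 groups")
  if (any(sizes < 2)) stop("every group needs at least 2 members")
  ss_total <- sum((values - mean(values))^2)
  if (ss_total == 0) return(list(R2 = 0, p = 1))
  ssb <- function(lab) {
    mg <- tapply(values, lab, mean)
    sum(table(lab) * (mg - mean(values))^2)
  }
  ssb_obs <- ssb(groups)
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_permutations), function(i)
      ssb(groups[sample.int(length(values))]) >= ssb_obs, logical(1)))
  })
  list(R2 = ssb_obs / ss_total, p = (1 + hits) / (1 + n_permutations))
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower-triangle entries; significance by
#' simultaneous row/column permutation of one matrix.
#'
#' @param d1,d2 symmetric distance matrices over the same samples in the
#'   same order.
#' @param n_permutations,seed as in [permanova()].
#' @return A list with `r` and `p` (`r` is NA for constant matrices).
#' @export
mantel_test <- function(d1, d2, n_permutations = 999, seed = 1) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  stopifnot(all(dim(d1) == dim(d2)))
  n <- nrow(d1)
  lt <- lower.tri(d1)
  v1 <- d1[lt]; v2 <- d2[lt]
  if (sd(v1) == 0 || sd(v2) == 0) {
    warning("constant distance matrix: Mantel r undefined")
    return(list(r = NA_real_, p = NA_real_))
  }
  r_obs <- cor(v1, v2)
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_permutations), function(i) {
      p <- sample.int(n)
      cor(v1, d2[p, p][lt]) >= r_obs
    }, logical(1)))
  })
  list(r = r_obs, p = (1 + hits) / (1 + n_permutations))
}

#' Occupancy-accumulation curve
#'
#' For every occupancy threshold X in 0..100 (percent of samples), sums the
#' reads of all OTUs present in at least X% of samples. The curve is
#' non-increasing in X; X = 0 gives the grand total, X = 100 the reads of
#' core OTUs present in every sample.
#'
#' @param table samples x OTUs matrix.
#' @return A data.frame with `occupancy_pct` (0..100) and `reads`.
#' @export
occupancy_accumulation <- function(table) {
  if (nrow(table) == 0 || ncol(table) == 0)
    stop("empty OTU table")
  occ <- 100 * colSums(table > 0) / nrow(table)
  tot <- colSums(table)
  xs <- 0:100
  reads <- vapply(xs, function(x) sum(tot[occ >= x]), numeric(1))
  data.frame(occupancy_pct = xs, reads = reads)
}
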