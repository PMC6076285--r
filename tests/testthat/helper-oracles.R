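# Small fixtures and independent oracles used across the suite.

# genotype_table from a dosage matrix with an evenly spaced map
toy_gt <- function(geno, breed, chrom = "1", spacing_kb = 100) {
  geno <- as.matrix(geno)
  if (is.null(rownames(geno))) rownames(geno) <- sprintf("i%03d", seq_len(nrow(geno)))
  if (is.null(colnames(geno))) colnames(geno) <- sprintf("s%04d", seq_len(ncol(geno)))
  chrom <- rep_len(chrom, ncol(geno))
  pos <- stats::ave(rep(spacing_kb, ncol(geno)), chrom, FUN = cumsum)
  genotype_table(geno, breed,
                 data.frame(snp = colnames(geno), chrom = chrom, pos_kb = pos))
}

# coancestry of two genotypes by enumerating the four ordered allele pairs
brute_coancestry <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  stopifnot(any(ok))
  mean(mapply(function(xi, yi) {
    ax <- c(rep(1L, 2 - xi), rep(2L, xi))
    ay <- c(rep(1L, 2 - yi), rep(2L, yi))
    sum(outer(ax, ay, "==")) / 4
  }, x[ok], y[ok]))
}

# equally-population-weighted mean pairwise coancestry, within-population
# means taken over all ordered pairs including an individual with itself
brute_fbar <- function(gt, pops = gt$fam$breed) {
  units <- sort(unique(pops))
  X <- gt$geno
  acc <- 0
  for (u in units) {
    for (v in units) {
      ii <- which(pops == u); jj <- which(pops == v)
      s <- 0
      for (a in ii) for (b in jj) s <- s + brute_coancestry(X[a, ], X[b, ])
      acc <- acc + s / (length(ii) * length(jj))
    }
  }
  acc / length(units)^2
}

# exhaustive rarefaction: mean distinct-allele count over all C(N, g) subsets
enum_richness <- function(counts, g) {
  genes <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(genes), g)
  mean(apply(subs, 2, function(ix) length(unique(genes[ix]))))
}

# exact two-sample KS p-value by enumerating all label assignments
enum_ks <- function(x, y) {
  d_stat <- function(a, b) {
    v <- sort(unique(c(a, b)))
    max(abs(stats::ecdf(a)(v) - stats::ecdf(b)(v)))
  }
  pool <- c(x, y)
  n1 <- length(x)
  d_obs <- d_stat(x, y)
  splits <- utils::combn(length(pool), n1)
  ds <- apply(splits, 2, function(ix) d_stat(pool[ix], pool[-ix]))
  list(D = d_obs, p = mean(ds >= d_obs - 1e-12))
}

# Hudson-style Fst between two breeds (ratio of locus sums), used as the
# independent calibration oracle for the Balding-Nichols generator
hudson_fst <- function(gt, breed1, breed2) {
  g1 <- gt$geno[gt$fam$breed == breed1, , drop = FALSE]
  g2 <- gt$geno[gt$fam$breed == breed2, , drop = FALSE]
  n1 <- nrow(g1); n2 <- nrow(g2)
  p1 <- colMeans(g1, na.rm = TRUE) / 2
  p2 <- colMeans(g2, na.rm = TRUE) / 2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# literal one-window application of the pruning rule: repeatedly drop the
# lower-MAF member (tie: later position) of the strongest pair at or above
# the threshold
ref_prune_one_window <- function(g, maf, thr) {
  keep <- seq_len(ncol(g))
  repeat {
    r2 <- suppressWarnings(stats::cor(g[, keep, drop = FALSE]))^2
    diag(r2) <- NA
    if (all(is.na(r2)) || max(r2, na.rm = TRUE) < thr) break
    w <- which(r2 == max(r2, na.rm = TRUE), arr.ind = TRUE)[1, ]
    pair <- keep[c(w[1], w[2])]
    drop <- if (maf[pair[1]] < maf[pair[2]]) pair[1]
    else if (maf[pair[2]] < maf[pair[1]]) pair[2] else max(pair)
    keep <- setdiff(keep, drop)
  }
  keep
}

# random small metapopulation with optional missingness, for property loops
random_metapop <- function(seed, max_pops = 5, max_ind = 6, max_loci = 60,
                           missing_rate = 0) {
  set.seed(seed)
  n_pops <- sample(2:max_pops, 1)
  sim <- simulate_metapopulation(
    n_breeds = n_pops,
    n_per_breed = sample(2:max_ind, n_pops, replace = TRUE),
    n_snps = sample(10:max_loci, 1),
    F_pop = stats::runif(n_pops, 0, 0.4),
    f_ind = stats::runif(n_pops, 0, 0.3),
    seed = seed)
  gt <- sim$gt
  if (missing_rate > 0) {
    drop <- which(stats::runif(length(gt$geno)) < missing_rate)
    gt$geno[drop] <- NA_integer_
  }
  gt
}
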