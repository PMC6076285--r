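test_that("molecular coancestry and Nei distance enumerate allele identities", {
  expect_equal(molecular_coancestry(0L, 0L), 1)    # AA vs AA
  expect_equal(molecular_coancestry(0L, 2L), 0)    # AA vs aa
  expect_equal(molecular_coancestry(1L, 1L), 0.5)  # Aa vs Aa
  expect_equal(self_coancestry(1L), 0.5)
  expect_equal(self_coancestry(0L), 1)
  expect_equal(nei_min_distance(0L, 0L), 0)
  expect_equal(nei_min_distance(0L, 2L), 1)
  expect_equal(nei_min_distance(0L, 1L), 0.25)     # (1 + 0.5)/2 - 0.5
  expect_error(molecular_coancestry(NA_integer_, 1L), "no locus")
  # multi-locus, missing-tolerant, matches the allele-pair enumeration oracle
  set.seed(51)
  for (k in 1:20) {
    x <- sample(c(0:2, NA), 30, replace = TRUE)
    y <- sample(c(0:2, NA), 30, replace = TRUE)
    if (!any(!is.na(x) & !is.na(y))) next
    expect_equal(molecular_coancestry(x, y), brute_coancestry(x, y))
  }
})

test_that("coancestry matrix equals the pairwise definition applied to every pair", {
  gt <- random_metapop(52, missing_rate = 0.05)
  f <- suppressWarnings(coancestry_matrix(gt))
  n <- n_individuals(gt)
  for (i in sample(n, 4)) {
    for (j in sample(n, 4)) {
      expect_equal(f[i, j], brute_coancestry(gt$geno[i, ], gt$geno[j, ]),
                   tolerance = 1e-12)
    }
  }
  expect_true(all(diag(f) >= 0.5 - 1e-12 & diag(f) <= 1 + 1e-12))
})

test_that("worked partitions: clones give no between-population diversity; fixed opposite pops split evenly", {
  # n identical clone populations
  g <- matrix(rep(c(0L, 1L, 2L, 1L), 6), 6, 4, byrow = TRUE)
  gt <- toy_gt(g, rep(c("P1", "P2", "P3"), each = 2))
  p <- partition_diversity(gt, min_overlap = 1)
  expect_equal(p$partition$GD_BS, 0, tolerance = 1e-12)
  # two populations fixed for opposite alleles at one locus
  gt2 <- toy_gt(matrix(c(0L, 0L, 2L, 2L), 4, 1), c("A", "A", "B", "B"))
  p2 <- partition_diversity(gt2, min_overlap = 1)
  expect_equal(p2$partition$GD_WS, 0)
  expect_equal(p2$partition$GD_BS, 0.5)
  expect_equal(p2$partition$GD_T, 0.5)
})

test_that("the average global coancestry equals the brute-force mean pairwise coancestry", {
  for (seed in c(53, 54, 55)) {
    gt <- random_metapop(seed, max_pops = 4, max_ind = 4, max_loci = 40)
    p <- suppressWarnings(partition_diversity(gt))
    expect_equal(p$stats$f_bar, brute_fbar(gt), tolerance = 1e-12)
  }
})

test_that("population order permutation leaves the partition unchanged", {
  gt <- random_metapop(56)
  p1 <- suppressWarnings(partition_diversity(gt))
  perm <- sample(n_individuals(gt))
  gt2 <- subset_genotypes(gt, individuals = perm)
  p2 <- suppressWarnings(partition_diversity(gt2))
  expect_equal(p1$partition, p2$partition, tolerance = 1e-12)
})

test_that("leave-one-out contributions carry the documented sign and weighting conventions", {
  # identical clone populations: no unit changes the between component
  g <- matrix(rep(c(0L, 1L, 2L, 1L, 0L), 8), 8, 5, byrow = TRUE)
  gt <- toy_gt(g, rep(c("P1", "P2", "P3", "P4"), each = 2))
  tab <- leave_one_out_contributions(gt, min_overlap = 1)
  expect_true(all(abs(tab$dGD_BS) < 1e-9))
  # a population fixed for a private allele raises GD_BS: removing it drops it
  g2 <- rbind(matrix(rep(c(0L, 1L, 0L, 1L), 4), 4, 4, byrow = TRUE),
              matrix(rep(c(0L, 1L, 0L, 1L), 4), 4, 4, byrow = TRUE),
              matrix(2L, 4, 4))
  gt2 <- toy_gt(g2, rep(c("A", "B", "C"), each = 4))
  tab2 <- leave_one_out_contributions(gt2, min_overlap = 1)
  expect_gt(tab2$dGD_BS[tab2$unit == "C"], 0)
  # lambda = 0 collapses the total onto the within component
  gt3 <- random_metapop(57, max_pops = 4)
  t0 <- suppressWarnings(leave_one_out_contributions(gt3, lambda = 0))
  expect_equal(t0$dGD_T, t0$dGD_WS, tolerance = 1e-12)
  t1 <- suppressWarnings(leave_one_out_contributions(gt3, lambda = 1))
  expect_equal(t1$dGD_T, t1$dGD_WS + t1$dGD_BS, tolerance = 1e-9)
  # removal must leave at least two populations
  gt4 <- toy_gt(matrix(c(0L, 2L, 1L, 1L), 4, 1), c("A", "A", "B", "B"))
  expect_error(leave_one_out_contributions(gt4, min_overlap = 1), "at least 3")
})
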