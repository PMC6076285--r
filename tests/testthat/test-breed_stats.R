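test_that("heterozygosity estimators match direct counting", {
  # one locus {AA, AG, GG, AG} -> Ho = 0.5
  gt <- toy_gt(cbind(s1 = c(0L, 1L, 2L, 1L)), rep("X", 4))
  expect_equal(observed_heterozygosity(gt, "X"), 0.5)
  # p = 0.25, n = 4 -> unbiased He = 2 * 0.25 * 0.75 * 8/7
  gt_he <- toy_gt(cbind(s1 = c(0L, 0L, 1L, 1L)), rep("X", 4))
  expect_equal(expected_heterozygosity(gt_he, "X"),
               2 * 0.25 * 0.75 * 8 / 7)
  expect_equal(expected_heterozygosity(gt_he, "X", unbiased = FALSE), 0.375)
  all_het <- toy_gt(matrix(1L, 3, 5), rep("X", 3))
  expect_equal(observed_heterozygosity(all_het, "X"), 1)
  all_hom <- toy_gt(matrix(2L, 3, 5), rep("X", 3))
  expect_equal(observed_heterozygosity(all_hom, "X"), 0)
  expect_equal(expected_heterozygosity(all_hom, "X"), 0)  # monomorphic
  # direct-counting oracle on a random small table with missing data
  set.seed(21)
  g <- matrix(sample(c(0:2, NA), 60, replace = TRUE), 6, 10)
  gt2 <- toy_gt(g, rep("X", 6))
  ho_oracle <- mean(apply(g, 2, function(x) {
    x <- x[!is.na(x)]; if (!length(x)) return(NA); mean(x == 1)
  }), na.rm = TRUE)
  expect_equal(observed_heterozygosity(gt2, "X"), ho_oracle)
})

test_that("multilocus FIS uses the ratio-of-sums over polymorphic loci", {
  # no heterozygotes anywhere but He > 0 -> FIS = 1
  g <- cbind(s1 = c(0L, 2L, 0L, 2L), s2 = c(2L, 2L, 0L, 0L))
  expect_equal(fis(toy_gt(g, rep("X", 4)), "X"), 1)
  # Ho == He at every locus -> 0 (construct via direct sums)
  set.seed(22)
  g2 <- matrix(sample(0:2, 200, replace = TRUE), 20, 10)
  gt2 <- toy_gt(g2, rep("X", 20))
  ho_l <- apply(g2, 2, function(x) mean(x == 1))
  n <- nrow(g2)
  p <- colMeans(g2) / 2
  he_l <- 2 * p * (1 - p) * (2 * n) / (2 * n - 1)
  keep <- he_l > 0
  expect_equal(fis(gt2, "X"), 1 - sum(ho_l[keep]) / sum(he_l[keep]))
  expect_error(fis(toy_gt(matrix(0L, 3, 4), rep("X", 3)), "X"), "monomorphic")
})

test_that("FIS recovers simulated within-breed inbreeding with the right sign", {
  sim <- simulate_metapopulation(1, 150, 800, F_pop = 0, f_ind = 0.15, seed = 23)
  f <- fis(sim$gt, "B01")
  expect_gt(f, 0)
  expect_lt(abs(f - 0.15), 0.05)
})

test_that("LD-Ne bias-corrected formulas and binning follow the published forms", {
  # closed-form branch evaluation
  expect_equal(metadiv:::ne_from_r2_drift(0.01, 40),
               (1 / 3 + sqrt(1 / 9 - 2.76 * 0.01)) / 0.02)
  expect_equal(metadiv:::ne_from_r2_drift(0.01, 20),
               (0.308 + sqrt(0.308^2 - 2.08 * 0.01)) / 0.02)
  expect_identical(metadiv:::ne_from_r2_drift(0, 40), Inf)
  expect_identical(metadiv:::ne_from_r2_drift(-0.005, 40), Inf)
  # monotone decreasing in the drift r2
  r2s <- c(0.002, 0.005, 0.01, 0.02, 0.035)
  nes <- vapply(r2s, metadiv:::ne_from_r2_drift, 0, S = 40)
  expect_true(all(diff(nes) < 0))
  # sampling expectation switches between the small- and large-S forms
  gt <- simulate_wright_fisher(50, 10, 120, sample_n = 40, seed = 24)
  est <- estimate_ne_ld(gt, pcrit = 0.05)
  expect_equal(est$r2_expected_sampling, 1 / est$S + 3.19 / est$S^2)
  expect_equal(est$r2_drift, est$r2_mean - est$r2_expected_sampling)
  expect_gte(est$n_pairs, 1)
  # categories as printed, boundaries included
  expect_equal(bin_ne(100), "Ne <= 100")
  expect_equal(bin_ne(150), "100 < Ne < 200")
  expect_equal(bin_ne(200), "Ne >= 200")
  expect_equal(bin_ne(Inf), "Ne >= 200")
})

test_that("r2_mean <= sampling expectation yields an infinite Ne estimate", {
  # two individuals' worth of signal removed: tiny panel with no drift LD
  set.seed(25)
  gt <- simulate_metapopulation(1, 400, 60, F_pop = 0, seed = 25)$gt
  est <- suppressWarnings(estimate_ne_ld(gt, "B01", pcrit = 0.05))
  # unlinked HWE draws: drift r2 hovers near 0; Ne must be large or infinite
  expect_true(est$Ne_hat > 500)
  expect_error(estimate_ne_ld(subset_genotypes(gt, snps = "snp000001"),
                              pcrit = 0.05), "fewer than 2 loci")
})

test_that("breed_diversity assembles one row per breed", {
  sim <- simulate_metapopulation(3, 25, 150, F_pop = c(0.05, 0.1, 0.3), seed = 26)
  tab <- breed_diversity(sim$gt, prune = NULL)
  expect_equal(tab$breed, c("B01", "B02", "B03"))
  expect_true(all(tab$H_O >= 0 & tab$H_O <= 1))
  expect_true(all(tab$H_E >= 0 & tab$H_E <= 1))
  expect_true(all(tab$F_IS >= -1 & tab$F_IS <= 1))
  expect_true(all(is.na(tab$Ne_hat) | tab$Ne_hat > 0))
})
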