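het_background_gt <- function(n_ind = 3, n_snps = 2000, spacing_kb = 10) {
  g <- matrix(1L, n_ind, n_snps,
              dimnames = list(sprintf("i%02d", seq_len(n_ind)),
                              sprintf("s%05d", seq_len(n_snps))))
  toy_gt(g, rep("X", n_ind), spacing_kb = spacing_kb)
}

test_that("ROH scanner finds injected runs and respects all thresholds", {
  gt <- het_background_gt()
  expect_equal(nrow(detect_roh(gt, "i01")), 0)  # all-heterozygous individual
  # 1,000 kb / 100-SNP homozygous run in a heterozygous background
  inj <- inject_roh(gt, "i01", "1", 5000, 6000)
  seg <- detect_roh(inj$gt, "i01")
  expect_equal(nrow(seg), 1)
  expect_lte(abs(seg$start_kb - 5000), 10)  # within one inter-SNP interval
  expect_lte(abs(seg$end_kb - 6000), 10)
  # run below the 500 kb length minimum is not reported
  inj2 <- inject_roh(gt, "i02", "1", 5000, 5400)  # 41 SNPs / 400 kb
  expect_equal(nrow(detect_roh(inj2$gt, "i02")), 0)
  # every reported segment satisfies the four thresholds
  gt3 <- het_background_gt(1, 4000, 10)
  reg <- metadiv:::empty_roh_registry()
  for (b in c(2000, 8000, 15000, 25000)) {
    r <- inject_roh(gt3, "i01", "1", b, b + 600 + (b %% 7) * 100, registry = reg)
    gt3 <- r$gt; reg <- r$registry
  }
  segs <- detect_roh(gt3, "i01")
  expect_gt(nrow(segs), 0)
  expect_true(all(segs$length_kb >= 500))
  expect_true(all(segs$n_snps >= 50))
  expect_true(all(segs$length_kb / segs$n_snps <= 1000))
  expect_true(all(abs(segs$end_kb - segs$start_kb - segs$length_kb) < 1e-9))
})

test_that("runs are split at large gaps and short chromosomes use a shrunken window", {
  # homozygous chromosome with a 1,500 kb void in the middle
  pos <- c(10 * (1:100), 10 * (1:100) + 2500)
  g <- matrix(0L, 1, 200, dimnames = list("i1", sprintf("s%03d", 1:200)))
  gt <- genotype_table(g, "X", data.frame(snp = colnames(g), chrom = "1",
                                          pos_kb = pos))
  segs <- detect_roh(gt, "i1")
  expect_equal(nrow(segs), 2)  # the gap (> 1,000 kb) splits the run
  expect_true(all(segs$n_snps == 100))
  # chromosome shorter than the window still yields a run when qualifying
  g2 <- matrix(0L, 1, 60, dimnames = list("i1", sprintf("t%03d", 1:60)))
  gt2 <- genotype_table(g2, "X", data.frame(snp = colnames(g2), chrom = "1",
                                            pos_kb = 20 * (1:60)))
  segs2 <- detect_roh(gt2, "i1", window_snps = 100)
  expect_equal(nrow(segs2), 1)
  expect_equal(segs2$n_snps, 60)
})

test_that("F_ROH evaluates the genome-fraction formula with the species constants", {
  segs <- data.frame(length_kb = c(26100))
  expect_equal(f_roh(segs, genome_length_kb("sheep")), 0.01)
  expect_equal(f_roh(data.frame(length_kb = 2510.611),
                     genome_length_kb("cattle")), 0.001)
  expect_equal(f_roh(data.frame(length_kb = numeric(0)), 2610000), 0)
  # sub-threshold segments are excluded from the sum
  expect_equal(f_roh(data.frame(length_kb = c(26100, 400)),
                     genome_length_kb("sheep")), 0.01)
  expect_error(f_roh(data.frame(length_kb = 3e6), 2510611), "exceeds")
})

test_that("breed-level ROH bins follow the printed category boundaries", {
  b <- bin_roh_stats(0.07, 150, 20)
  expect_equal(b$F_ROH_bin, "0.05 < F_ROH < 0.10")
  expect_equal(b$N_ROH_bin, "N_ROH <= 150")
  expect_equal(b$L_ROH_bin, "L_ROH >= 20")
  expect_equal(bin_roh_stats(0.10, 200, 15)$F_ROH_bin, "F_ROH >= 0.10")
  expect_equal(bin_roh_stats(0.05, 200, 15)$N_ROH_bin, "N_ROH >= 200")
  expect_equal(bin_roh_stats(0.05, 175, 17)$N_ROH_bin, "150 < N_ROH < 200")
  expect_equal(bin_roh_stats(0.05, 175, 15)$L_ROH_bin, "L_ROH <= 15")
})

test_that("roh_summary aggregates per-individual statistics by breed", {
  gt <- het_background_gt(4, 3000, 10)
  gt$fam$breed <- c("A", "A", "B", "B")
  r <- inject_roh(gt, "i01", "1", 2000, 4000)
  r <- inject_roh(r$gt, "i01", "1", 8000, 9000, registry = r$registry)
  r <- inject_roh(r$gt, "i02", "1", 12000, 13500, registry = r$registry)
  tab <- roh_summary(r$gt, genome_length_kb("sheep"))
  expect_equal(tab$breed, c("A", "B"))
  expect_equal(tab$N_ROH[1], 1.5)     # (2 + 1) segments / 2 individuals
  expect_equal(tab$N_ROH[2], 0)
  expect_gt(tab$F_ROH[1], 0)
  expect_equal(tab$F_ROH[2], 0)
  expect_equal(tab$L_ROH_mb[2], 0)
})
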