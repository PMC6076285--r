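breed_dosages <- function(gt, breed) {
  if (!breed %in% gt$fam$breed) stop("no individuals in breed ", breed)
  gt$geno[gt$fam$breed == breed, , drop = FALSE]
}

#' Observed heterozygosity of a breed
#'
#' Per-locus fraction of non-missing genotypes that are heterozygous,
#' averaged over loci with equal weight (loci with no calls are skipped).
#'
#' @param gt a [genotype_table()].
#' @param breed breed code.
#' @return H_O in \[0, 1\].
#' @export
observed_heterozygosity <- function(gt, breed) {
  g <- breed_dosages(gt, breed)
  ho <- colMeans(g == 1L, na.rm = TRUE)
  ho <- ho[!is.nan(ho)]
  if (length(ho) == 0) stop("no non-missing calls for breed ", breed)
  mean(ho)
}

per_locus_he <- function(g, unbiased = TRUE) {
  n <- colSums(!is.na(g))
  p <- colMeans(g, na.rm = TRUE) / 2
  he <- 2 * p * (1 - p)
  if (unbiased) he <- he * (2 * n) / (2 * n - 1)
  he[n == 0] <- NA_real_
  he
}

#' Expected heterozygosity of a breed
#'
#' Per locus `2*p*q`, multiplied by the small-sample factor `2n/(2n-1)` when
#' `unbiased` (n = non-missing genotypes at the locus), then averaged over
#' loci with equal weight.
#'
#' @inheritParams observed_heterozygosity
#' @param unbiased apply the `2n/(2n-1)` correction (default).
#' @return H_E in \[0, 1\].
#' @export
expected_heterozygosity <- function(gt, breed, unbiased = TRUE) {
  g <- breed_dosages(gt, breed)
  he <- per_locus_he(g, unbiased)
  he <- he[!is.na(he)]
  if (length(he) == 0) stop("no non-missing calls for breed ", breed)
  mean(he)
}

#' Multilocus inbreeding coefficient F_IS of a breed
#'
#' Ratio-of-sums estimator `1 - sum(Ho_l) / sum(He_l)` over loci, with
#' unbiased per-locus expected heterozygosity; monomorphic loci
#' (`He_l = 0`) are excluded from both sums. Measures the deficit of
#' observed relative to expected heterozygotes.
#'
#' @inheritParams observed_heterozygosity
#' @return F_IS in \[-1, 1\].
#' @export
fis <- function(gt, breed) {
  g <- breed_dosages(gt, breed)
  ho <- colMeans(g == 1L, na.rm = TRUE)
  he <- per_locus_he(g, unbiased = TRUE)
  use <- !is.na(he) & he > 0
  if (!any(use)) stop("all loci monomorphic for breed ", breed)
  1 - sum(ho[use]) / sum(he[use])
}

#' LD-method effective population size
#'
#' Estimates contemporary Ne from the mean squared genotype correlation (r2)
#' over all retained locus pairs, after excluding loci whose minor allele
#' frequency is below `pcrit` and subtracting the expected sampling
#' contribution to r2. Uses the random-mating bias corrections of the
#' standard LD method: for harmonic-mean sample size `S >= 30`,
#' `E[r2_sample] = 1/S + 3.19/S^2` and
#' `Ne = (1/3 + sqrt(1/9 - 2.76 r2')) / (2 r2')`; for `S < 30`,
#' `E[r2_sample] = 0.0018 + 0.907/S + 4.44/S^2` and
#' `Ne = (0.308 + sqrt(0.308^2 - 2.08 r2')) / (2 r2')`, where `r2'` is the
#' drift r2. A non-positive drift r2 gives `Ne = Inf` (no drift signal).
#'
#' @param gt a [genotype_table()].
#' @param breed breed code; `NULL` uses all individuals.
#' @param pcrit minimum minor allele frequency for a locus to enter.
#' @param prune optional `c(window_snps, step_snps, r2_threshold)` triple:
#'   LD-prune the table first so that locus pairs are near-independent
#'   (skip when the input is already pruned).
#' @return object of class `ne_estimate`: list with `r2_mean`,
#'   `r2_expected_sampling`, `r2_drift`, `S`, `Ne_hat`, `n_pairs`,
#'   `n_loci`.
#' @export
estimate_ne_ld <- function(gt, breed = NULL, pcrit = 0.05, prune = NULL) {
  sub <- if (is.null(breed)) gt else breed_genotypes(gt, breed)
  if (!is.null(prune)) {
    keep <- ld_prune(sub, prune[1], prune[2], prune[3])
    sub <- subset_genotypes(sub, snps = keep)
  }
  if (n_individuals(sub) < 10) {
    warning("fewer than 10 individuals; Ne estimate will be noisy")
  }
  maf <- minor_allele_freq(sub)
  maf[is.nan(maf)] <- 0
  g <- sub$geno[, maf >= pcrit, drop = FALSE]
  L <- ncol(g)
  if (L < 2) stop("fewer than 2 loci usable after the pcrit filter")
  r2 <- r2_matrix(g)
  ut <- upper.tri(r2)
  r2v <- r2[ut]
  ok <- !is.na(r2v)
  if (!any(ok)) stop("no locus pair with defined r2")
  if (anyNA(g)) {
    obs <- crossprod(!is.na(g))
    nv <- obs[ut]
  } else {
    nv <- rep(nrow(g), sum(ut))
  }
  use <- ok & nv >= 2
  r2_mean <- mean(r2v[use])
  S <- 1 / mean(1 / nv[use])  # harmonic mean pairwise sample size
  e_samp <- if (S >= 30) 1 / S + 3.19 / S^2 else
    0.0018 + 0.907 / S + 4.44 / S^2
  r2_drift <- r2_mean - e_samp
  Ne <- ne_from_r2_drift(r2_drift, S)
  structure(list(r2_mean = r2_mean, r2_expected_sampling = e_samp,
                 r2_drift = r2_drift, S = S, Ne_hat = Ne,
                 n_pairs = sum(use), n_loci = L),
            class = "ne_estimate")
}

ne_from_r2_drift <- function(r2_drift, S) {
  if (r2_drift <= 0) return(Inf)
  if (S >= 30) {
    a <- 1 / 3; b <- 2.76
  } else {
    a <- 0.308; b <- 2.08
  }
  (a + sqrt(max(0, a^2 - b * r2_drift))) / (2 * r2_drift)
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf(
    "LD Ne estimate: Ne_hat = %s (r2 = %.5f, sampling = %.5f, drift = %.5f, S = %.1f, %d pairs)\n",
    format(x$Ne_hat, digits = 5), x$r2_mean, x$r2_expected_sampling,
    x$r2_drift, x$S, x$n_pairs))
  invisible(x)
}

#' Bin an Ne estimate into the reporting categories
#'
#' Categories: `Ne <= 100`, `100 < Ne < 200`, `Ne >= 200` (infinite
#' estimates fall in the last).
#'
#' @param ne_hat positive Ne estimate (may be `Inf`).
#' @return character label.
#' @export
bin_ne <- function(ne_hat) {
  ifelse(ne_hat <= 100, "Ne <= 100",
         ifelse(ne_hat < 200, "100 < Ne < 200", "Ne >= 200"))
}

#' Per-breed diversity summary table
#'
#' One row per breed: observed/expected heterozygosity, F_IS, LD-method Ne
#' and its category, sample size.
#'
#' @param gt a [genotype_table()].
#' @param pcrit minimum MAF for the Ne computation.
#' @param prune optional pruning triple passed to [estimate_ne_ld()].
#' @return data frame.
#' @export
breed_diversity <- function(gt, pcrit = 0.05, prune = c(100, 25, 0.05)) {
  bs <- breeds(gt)
  rows <- lapply(bs, function(b) {
    ne <- tryCatch(suppressWarnings(
      estimate_ne_ld(gt, b, pcrit = pcrit, prune = prune))$Ne_hat,
      error = function(e) NA_real_)
    data.frame(
      breed = b,
      n_individuals = sum(gt$fam$breed == b),
      H_O = observed_heterozygosity(gt, b),
      H_E = expected_heterozygosity(gt, b),
      F_IS = fis(gt, b),
      Ne_hat = ne,
      Ne_bin = ifelse(is.na(ne), NA_character_, bin_ne(ne)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
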