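#' Quality-control filter for a genotype panel
#'
#' Applies the standard SNP-array QC used for multi-breed diversity panels:
#' individuals below a call-rate threshold are removed first; then SNPs are
#' removed if their call rate (over the retained individuals) is below
#' threshold, their pooled minor allele frequency is not above the MAF
#' threshold, or they lie outside the autosome set. MAF is computed on the
#' pooled sample across breeds.
#'
#' @param gt a [genotype_table()].
#' @param min_ind_call minimum individual call rate (kept if `>= threshold`).
#' @param min_snp_call minimum SNP call rate.
#' @param min_maf SNPs kept only if pooled MAF `> min_maf`.
#' @param autosomes character vector of autosomal chromosome labels, or
#'   `NULL` to skip the autosome filter.
#' @return list with elements `gt` (filtered table) and `report`
#'   (`qc_report`: counts in/out and removal reasons).
#' @export
qc_filter <- function(gt, min_ind_call = 0.95, min_snp_call = 0.95,
                      min_maf = 0.05, autosomes = NULL) {
  stopifnot(min_ind_call >= 0, min_ind_call <= 1,
            min_snp_call >= 0, min_snp_call <= 1,
            min_maf >= 0, min_maf <= 1)
  n_ind_in <- n_individuals(gt)
  n_snp_in <- n_snps(gt)

  icr <- individual_call_rate(gt)
  drop_ind <- gt$fam$id[icr < min_ind_call]
  if (length(drop_ind) == n_ind_in) stop("all individuals filtered by QC")
  gt1 <- subset_genotypes(gt, individuals = setdiff(gt$fam$id, drop_ind))

  scr <- snp_call_rate(gt1)
  maf <- minor_allele_freq(gt1)
  maf[is.nan(maf)] <- 0
  drop_call <- gt1$map$snp[scr < min_snp_call]
  drop_maf <- setdiff(gt1$map$snp[maf <= min_maf], drop_call)
  drop_auto <- character(0)
  if (!is.null(autosomes)) {
    drop_auto <- setdiff(gt1$map$snp[!(gt1$map$chrom %in% as.character(autosomes))],
                         c(drop_call, drop_maf))
  }
  keep <- setdiff(gt1$map$snp, c(drop_call, drop_maf, drop_auto))
  if (length(keep) == 0) stop("all SNPs filtered by QC")
  out <- subset_genotypes(gt1, snps = keep)

  report <- structure(list(
    n_individuals_in = n_ind_in,
    n_individuals_out = n_individuals(out),
    n_snps_in = n_snp_in,
    n_snps_out = n_snps(out),
    removed_individuals = list(call_rate = drop_ind),
    removed_snps = list(call_rate = drop_call, maf = drop_maf,
                        non_autosomal = drop_auto)
  ), class = "qc_report")
  stopifnot(n_ind_in - length(drop_ind) == report$n_individuals_out,
            n_snp_in - length(drop_call) - length(drop_maf) -
              length(drop_auto) == report$n_snps_out)
  list(gt = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:\n",
      " individuals:", x$n_individuals_in, "->", x$n_individuals_out, "\n",
      " SNPs:", x$n_snps_in, "->", x$n_snps_out,
      "(call rate", length(x$removed_snps$call_rate),
      "| MAF", length(x$removed_snps$maf),
      "| non-autosomal", length(x$removed_snps$non_autosomal), ")\n")
  invisible(x)
}

#' Pairwise SNP r-squared
#'
#' Squared Pearson correlation of per-individual allele-dosage vectors
#' (0/1/2), pairwise-complete over non-missing individuals. This is the
#' genotype-count ("composite") r2 convention used by SNP pruning tools when
#' phase is unknown.
#'
#' @param gt a [genotype_table()].
#' @param snp_a,snp_b SNP ids.
#' @return r-squared in \[0, 1\].
#' @export
snp_r2 <- function(gt, snp_a, snp_b) {
  x <- gt$geno[, snp_a]
  y <- gt$geno[, snp_b]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) stop("fewer than 2 individuals with both calls")
  if (stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) {
    stop("r2 undefined: zero genotype variance at ",
         if (stats::var(x[ok]) == 0) snp_a else snp_b)
  }
  stats::cor(x[ok], y[ok])^2
}

# r2 matrix for a dosage sub-matrix, pairwise complete; monomorphic columns
# yield NA rows/columns rather than an error.
r2_matrix <- function(g) {
  suppressWarnings(stats::cor(g, use = "pairwise.complete.obs")^2)
}

#' Windowed LD pruning
#'
#' Greedy sliding-window pruning in the style of `indep-pairwise <window>
#' <step> <r2>`: within each window of `window_snps` consecutive SNPs
#' (sliding by `step_snps`, per chromosome), while any retained pair has
#' r2 at or above the threshold, the member of the worst-offending pair
#' with the lower pooled MAF is dropped (tie: the SNP later on the map).
#' Deterministic for a given table.
#'
#' @param gt a [genotype_table()].
#' @param window_snps window size in SNPs.
#' @param step_snps step size in SNPs.
#' @param r2_threshold pruning threshold.
#' @return character vector of retained SNP ids (map order).
#' @export
ld_prune <- function(gt, window_snps = 100, step_snps = 25, r2_threshold) {
  stopifnot(window_snps >= 2, step_snps >= 1,
            r2_threshold > 0, r2_threshold <= 1)
  maf <- minor_allele_freq(gt)
  maf[is.nan(maf)] <- 0
  map <- gt$map
  keep <- rep(TRUE, nrow(map))
  names(keep) <- map$snp
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    L <- length(idx)
    start <- 1
    repeat {
      win <- idx[start:min(start + window_snps - 1, L)]
      win <- win[keep[win]]
      if (length(win) >= 2) {
        r2 <- r2_matrix(gt$geno[, win, drop = FALSE])
        diag(r2) <- NA
        repeat {
          if (all(is.na(r2)) || max(r2, na.rm = TRUE) < r2_threshold) break
          w <- which(r2 == max(r2, na.rm = TRUE), arr.ind = TRUE)[1, ]
          pair <- win[c(w[1], w[2])]
          drop <- if (maf[pair[1]] < maf[pair[2]]) pair[1]
          else if (maf[pair[2]] < maf[pair[1]]) pair[2]
          else max(pair)  # tie: later map position
          keep[drop] <- FALSE
          k <- which(win == drop)
          r2[k, ] <- NA
          r2[, k] <- NA
        }
      }
      if (start + window_snps - 1 >= L) break
      start <- start + step_snps
    }
  }
  map$snp[keep]
}
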