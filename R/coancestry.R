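#' Molecular coancestry between two individuals
#'
#' Probability that two alleles drawn at random, one from each individual,
#' are identical in state, averaged over the loci where both genotypes are
#' present. For dosages x, y of the same allele this is
#' `((2-x)(2-y) + xy) / 4` per locus. The self case (`y = x`) gives the
#' self-coancestry `s_x = (1 + homozygosity)/2`.
#'
#' @param x,y integer dosage vectors (0/1/2, `NA` missing) over the same
#'   loci.
#' @return coancestry in \[0, 1\].
#' @export
molecular_coancestry <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) stop("no locus where both genotypes are present")
  mean(((2 - x[ok]) * (2 - y[ok]) + x[ok] * y[ok]) / 4)
}

#' Self-coancestry of an individual
#' @param x integer dosage vector (0/1/2, `NA` missing).
#' @return `s_x` in \[0.5, 1\].
#' @export
self_coancestry <- function(x) molecular_coancestry(x, x)

#' Nei minimum distance between two individuals
#'
#' `d_xy = (s_x + s_y)/2 - f_xy`; zero for an individual with itself.
#'
#' @inheritParams molecular_coancestry
#' @return distance `>= 0` up to rounding.
#' @export
nei_min_distance <- function(x, y) {
  (self_coancestry(x) + self_coancestry(y)) / 2 - molecular_coancestry(x, y)
}

#' All-pairs molecular coancestry matrix
#'
#' Pairwise-complete coancestries for every ordered pair of individuals
#' (diagonal = self-coancestries). Warns when some pair shares fewer than
#' `min_overlap` loci.
#'
#' @param gt a [genotype_table()].
#' @param min_overlap minimum shared non-missing loci per pair before a
#'   warning is emitted.
#' @return symmetric numeric matrix with individual ids as dimnames.
#' @export
coancestry_matrix <- function(gt, min_overlap = 100) {
  X <- gt$geno
  M <- !is.na(X)
  X0 <- X; X0[!M] <- 0L
  storage.mode(X0) <- "double"
  storage.mode(M) <- "double"
  Lxy <- tcrossprod(M)
  if (any(Lxy == 0)) stop("some pair of individuals shares no genotyped locus")
  if (any(Lxy < min_overlap)) {
    warning("some individual pairs share fewer than ", min_overlap,
            " loci; coancestries will be noisy")
  }
  Sx <- tcrossprod(X0, M)   # sum of x over loci present in both
  C <- tcrossprod(X0)
  f <- (Lxy - (Sx + t(Sx)) / 2 + C / 2) / Lxy
  dimnames(f) <- list(gt$fam$id, gt$fam$id)
  f
}

# Population-level coancestry statistics: per-population mean
# self-coancestry s_i and the n x n matrix of mean pairwise coancestries
# f_ij (diagonal f_ii averaged over all ordered pairs including self, so
# that f_ii = s_i - D_ii with D_ii the mean within-population individual
# distance including the zero self-distances).
popstats <- function(gt, pops, min_overlap = 100) {
  pops <- as.character(pops)
  if (length(pops) != n_individuals(gt)) stop("one population label per individual required")
  f <- coancestry_matrix(gt, min_overlap)
  s <- diag(f)
  units <- sort(unique(pops))
  n <- length(units)
  idx <- lapply(units, function(u) which(pops == u))
  if (any(lengths(idx) == 0)) stop("population with zero individuals")
  s_i <- vapply(idx, function(ii) mean(s[ii]), 0)
  fmat <- matrix(NA_real_, n, n, dimnames = list(units, units))
  for (i in seq_len(n)) {
    for (j in i:n) {
      fij <- mean(f[idx[[i]], idx[[j]]])
      fmat[i, j] <- fij; fmat[j, i] <- fij
    }
  }
  list(units = units, n_i = lengths(idx), s_i = stats::setNames(s_i, units),
       fmat = fmat)
}

partition_from_popstats <- function(ps, keep = NULL) {
  units <- ps$units
  if (!is.null(keep)) units <- intersect(units, keep)
  n <- length(units)
  if (n < 2) stop("at least 2 populations required for a diversity partition")
  s_i <- ps$s_i[units]
  fmat <- ps$fmat[units, units, drop = FALSE]
  f_ii <- diag(fmat)
  s_tilde <- mean(s_i)
  f_tilde <- mean(f_ii)
  f_bar <- mean(fmat)                      # (1/n^2) sum_ij f_ij  (Eq. 2)
  D_ii <- s_i - f_ii
  D_ij <- (outer(f_ii, f_ii, "+")) / 2 - fmat  # Nei minimum distance
  diag(D_ij) <- D_ii
  list(
    stats = list(units = units, s_i = s_i, f_ii = f_ii, D_ii = D_ii,
                 D_ij = D_ij, fmat = fmat,
                 s_tilde = s_tilde, f_tilde = f_tilde, f_bar = f_bar,
                 D_tilde = s_tilde - f_tilde, D_bar = f_tilde - f_bar),
    partition = list(GD_T = 1 - f_bar,
                     GD_WS = 1 - f_tilde,
                     GD_BS = f_tilde - f_bar,
                     GD_WI = 1 - s_tilde,
                     GD_BI = s_tilde - f_tilde)
  )
}

#' Partition metapopulation genomic diversity by molecular coancestry
#'
#' Computes the average global coancestry with equal population weights and
#' splits the total gene diversity `GD_T = 1 - f_bar` into within-individual
#' (`GD_WI = 1 - s_tilde`), between-individual (`GD_BI = s_tilde -
#' f_tilde`), and between-population (`GD_BS = f_tilde - f_bar`)
#' components; `GD_WS = GD_WI + GD_BI` is the within-population share and
#' `GD_T = GD_WS + GD_BS` holds exactly.
#'
#' @param gt a [genotype_table()].
#' @param pops population label per individual (defaults to breed codes).
#' @param min_overlap see [coancestry_matrix()].
#' @return object of class `diversity_partition`: list with `stats`
#'   (population coancestry summaries) and `partition` (the GD components).
#' @export
partition_diversity <- function(gt, pops = gt$fam$breed, min_overlap = 100) {
  ps <- popstats(gt, pops, min_overlap)
  out <- partition_from_popstats(ps)
  class(out) <- "diversity_partition"
  out
}

#' @export
print.diversity_partition <- function(x, ...) {
  p <- x$partition
  cat(sprintf(
    "Coancestry diversity partition (%d populations):\n  GD_T = %.5f = GD_WS (%.5f) + GD_BS (%.5f)\n  GD_WS = GD_WI (%.5f) + GD_BI (%.5f)\n",
    length(x$stats$units), p$GD_T, p$GD_WS, p$GD_BS, p$GD_WI, p$GD_BI))
  invisible(x)
}

#' Leave-one-out contributions to coancestry-based diversity
#'
#' Removes each population (breed, or all breeds of a region) in turn,
#' recomputes the diversity partition on the remainder, and reports the
#' contribution of the removed unit as a percentage of the full total
#' diversity: `100 * (GD_X(full) - GD_X(without unit)) / GD_T(full)`.
#' Positive values mean the unit contributes diversity. The total uses
#' `GD_T(lambda) = GD_WS + lambda * GD_BS`, weighting the between-population
#' share by `lambda` (`lambda = 1`: equal weight).
#'
#' @param gt a [genotype_table()].
#' @param pops population label per individual (defaults to breed codes).
#' @param lambda weight on the between-population component.
#' @param min_overlap see [coancestry_matrix()].
#' @return data frame: `unit`, `dGD_WS`, `dGD_BS`, `dGD_T` (percent of full
#'   `GD_T`), the raw (unscaled) differences, and `method`.
#' @export
leave_one_out_contributions <- function(gt, pops = gt$fam$breed, lambda = 1,
                                        min_overlap = 100) {
  ps <- popstats(gt, pops, min_overlap)
  if (length(ps$units) < 3) stop("need at least 3 populations so each removal leaves 2")
  full <- partition_from_popstats(ps)$partition
  gdt_full <- full$GD_T
  rows <- lapply(ps$units, function(u) {
    red <- partition_from_popstats(ps, keep = setdiff(ps$units, u))$partition
    d_ws <- full$GD_WS - red$GD_WS
    d_bs <- full$GD_BS - red$GD_BS
    d_t <- (full$GD_WS + lambda * full$GD_BS) -
      (red$GD_WS + lambda * red$GD_BS)
    data.frame(unit = u,
               dGD_WS = 100 * d_ws / gdt_full,
               dGD_BS = 100 * d_bs / gdt_full,
               dGD_T = 100 * d_t / gdt_full,
               raw_dGD_WS = d_ws, raw_dGD_BS = d_bs, raw_dGD_T = d_t,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$method <- "coancestry"
  out
}
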