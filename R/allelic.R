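#' Hypergeometric allele-absence probability
#'
#' Probability that an allele with `N_ik` copies among the `N_i` sampled
#' genes of a population is absent from a random subsample of `g` genes:
#' `C(N_i - N_ik, g) / C(N_i, g)` (zero when `N_i - N_ik < g`). Computed in
#' log space for stability.
#'
#' @param N_i total genes sampled (vector or matrix).
#' @param N_ik copies of the allele (same shape).
#' @param g rarefaction sample size, `1 <= g <= N_i`.
#' @return probability in \[0, 1\].
#' @export
absence_probability <- function(N_i, N_ik, g) {
  if (any(g > N_i)) stop("rarefaction size g exceeds the sampled genes N_i")
  if (any(g < 1)) stop("g must be at least 1")
  if (any(N_ik < 0 | N_ik > N_i)) stop("allele counts must lie in [0, N_i]")
  p <- exp(lchoose(N_i - N_ik, g) - lchoose(N_i, g))
  p[N_i - N_ik < g] <- 0
  p
}

#' Rarefied allelic richness at one locus
#'
#' Expected number of distinct alleles in a random subsample of `g` genes:
#' `a_i = sum_k (1 - P_ik)` over the alleles observed at the locus.
#'
#' @param counts vector of allele copy counts at one locus (its sum is the
#'   sampled gene count `N_i`).
#' @param g rarefaction size in genes.
#' @return expected allele count, in \[1, length(counts)\] for a
#'   polymorphic locus.
#' @export
rarefied_richness <- function(counts, g) {
  N <- sum(counts)
  sum(1 - absence_probability(N, counts, g))
}

#' Within-population component of allelic diversity
#'
#' `A_S = mean_i(a_i) - 1`, per locus, then averaged over loci when a
#' matrix is supplied.
#'
#' @param a per-population rarefied richness: vector (one locus) or matrix
#'   (populations x loci).
#' @return `A_S` (scalar).
#' @export
within_component_As <- function(a) {
  if (is.matrix(a)) mean(colMeans(a) - 1) else mean(a) - 1
}

#' Rarefied allelic distance between two populations at one locus
#'
#' `d_A,ij = 1/2 sum_k [(1 - P_ik) P_jk + P_ik (1 - P_jk)]`: the chance
#' that an allele is seen in a rarefied sample from one population but
#' missed in the other, summed over alleles. Nonzero for a population with
#' itself at finite `g`.
#'
#' @param counts_i,counts_j named allele copy-count vectors at one locus
#'   (names are allele labels; missing alleles count 0).
#' @param g rarefaction size in genes.
#' @return `d_A,ij >= 0`.
#' @export
allelic_distance <- function(counts_i, counts_j, g) {
  alleles <- union(names(counts_i), names(counts_j))
  if (is.null(alleles)) {
    stopifnot(length(counts_i) == length(counts_j))
    ci <- counts_i; cj <- counts_j
  } else {
    ci <- stats::setNames(rep(0, length(alleles)), alleles)
    cj <- ci
    ci[names(counts_i)] <- counts_i
    cj[names(counts_j)] <- counts_j
  }
  Pi <- absence_probability(sum(ci), ci, g)
  Pj <- absence_probability(sum(cj), cj, g)
  sum((1 - Pi) * Pj + Pi * (1 - Pj)) / 2
}

#' Average between-population allelic distance
#'
#' `D_A = (1/n^2) sum_{i,j} d_A,ij`, the printed double sum over all
#' ordered population pairs including the diagonal terms.
#'
#' @param d_mat square matrix of pairwise `d_A,ij` (diagonal = `d_A,ii`).
#' @param include_diagonal keep the diagonal terms (default; required for
#'   the exact `A_T = A_S + D_A` identity). When `FALSE`, the mean is taken
#'   over off-diagonal pairs only.
#' @return `D_A`.
#' @export
average_DA <- function(d_mat, include_diagonal = TRUE) {
  if (include_diagonal) mean(d_mat)
  else mean(d_mat[row(d_mat) != col(d_mat)])
}

#' Total allelic diversity
#' @param A_S,D_A the two components.
#' @return `A_T = A_S + D_A`.
#' @export
total_AT <- function(A_S, D_A) A_S + D_A

# Per-population allele-absence probability matrices for a biallelic panel.
# Returns list(N, P1, P2, a) with populations as rows and loci as columns.
allelic_tables <- function(gt, pops, g = NULL) {
  pops <- as.character(pops)
  units <- sort(unique(pops))
  X <- gt$geno
  N <- do.call(rbind, lapply(units, function(u) {
    2 * colSums(!is.na(X[pops == u, , drop = FALSE]))
  }))
  C2 <- do.call(rbind, lapply(units, function(u) {
    colSums(X[pops == u, , drop = FALSE], na.rm = TRUE)
  }))
  C1 <- N - C2
  # default: twice the minimum per-locus genotype count over populations
  # and loci (N already counts genes = 2 x genotypes)
  if (is.null(g)) g <- min(N)
  if (g < 1) {
    stop("rarefaction size is below 1 gene (a population has a locus with no calls)")
  }
  short <- N < g
  if (any(short)) {
    stop("rarefaction size g = ", g, " infeasible for population ",
         units[which(rowSums(short) > 0)[1]])
  }
  P1 <- absence_probability(N, C1, g)
  P2 <- absence_probability(N, C2, g)
  list(units = units, N = N, P1 = P1, P2 = P2, a = 2 - P1 - P2, g = g)
}

# d_A,ij per locus for all ordered population pairs -> array [n, n, L]
allelic_distance_array <- function(tab) {
  n <- length(tab$units)
  L <- ncol(tab$P1)
  d <- array(NA_real_, c(n, n, L))
  for (i in seq_len(n)) {
    for (j in i:n) {
      dij <- ((1 - tab$P1[i, ]) * tab$P1[j, ] + tab$P1[i, ] * (1 - tab$P1[j, ]) +
                (1 - tab$P2[i, ]) * tab$P2[j, ] + tab$P2[i, ] * (1 - tab$P2[j, ])) / 2
      d[i, j, ] <- dij
      d[j, i, ] <- dij
    }
  }
  d
}

#' Partition allelic diversity by rarefaction
#'
#' Computes per-population rarefied allelic richness at a common gene count
#' `g` and partitions the metapopulation's allelic diversity into a
#' within-population component `A_S = mean(a_i) - 1`, a between-population
#' component `D_A` (mean pairwise rarefied allelic distance, diagonal
#' included), and the total `A_T = A_S + D_A`. All per-locus quantities are
#' averaged over loci with equal weight.
#'
#' @param gt a [genotype_table()].
#' @param pops population label per individual (defaults to breed codes).
#' @param g rarefaction size in genes; default `2 x` the minimum per-locus
#'   genotype count over populations and loci.
#' @param include_diagonal see [average_DA()].
#' @return object of class `allelic_partition`: list with `g`, `A_S`,
#'   `D_A`, `A_T`, per-locus vectors, the population-pair distance matrix
#'   `d_A` (multi-locus mean) and per-population mean richness `a_i`.
#' @export
allelic_partition <- function(gt, pops = gt$fam$breed, g = NULL,
                              include_diagonal = TRUE) {
  tab <- allelic_tables(gt, pops, g)
  d <- allelic_distance_array(tab)
  n <- length(tab$units)
  A_S_l <- colMeans(tab$a) - 1
  D_A_l <- apply(d, 3, function(m) average_DA(m, include_diagonal))
  out <- list(
    units = tab$units, g = tab$g,
    A_S = mean(A_S_l), D_A = mean(D_A_l),
    A_T = mean(A_S_l + D_A_l),
    A_S_locus = A_S_l, D_A_locus = D_A_l,
    a_i = stats::setNames(rowMeans(tab$a), tab$units),
    d_A = matrix(apply(d, c(1, 2), mean), n, n,
                 dimnames = list(tab$units, tab$units)))
  class(out) <- "allelic_partition"
  out
}

#' @export
print.allelic_partition <- function(x, ...) {
  cat(sprintf(
    "Rarefaction allelic diversity (g = %d genes, %d populations):\n  A_T = %.5f = A_S (%.5f) + D_A (%.5f)\n",
    x$g, length(x$units), x$A_T, x$A_S, x$D_A))
  invisible(x)
}

#' Leave-one-out contributions to allelic diversity
#'
#' Removes each population in turn and recomputes `A_S`, `D_A` and `A_T` on
#' the remainder, holding the rarefaction size fixed at the
#' full-metapopulation value so richness stays comparable across removals.
#' Contributions are reported as a percentage of the full `A_T`, aligned
#' with the coancestry contribution columns (`A_S -> dGD_WS`,
#' `D_A -> dGD_BS`, `A_T -> dGD_T`).
#'
#' @inheritParams allelic_partition
#' @return data frame in the same shape as
#'   [leave_one_out_contributions()], `method = "allelic_richness"`.
#' @export
leave_one_out_allelic <- function(gt, pops = gt$fam$breed, g = NULL,
                                  include_diagonal = TRUE) {
  pops <- as.character(pops)
  tab <- allelic_tables(gt, pops, g)
  if (length(tab$units) < 3) stop("need at least 3 populations so each removal leaves 2")
  d <- allelic_distance_array(tab)
  comp <- function(keep_idx) {
    A_S_l <- colMeans(tab$a[keep_idx, , drop = FALSE]) - 1
    D_A_l <- apply(d[keep_idx, keep_idx, , drop = FALSE], 3,
                   function(m) average_DA(m, include_diagonal))
    c(A_S = mean(A_S_l), D_A = mean(D_A_l), A_T = mean(A_S_l + D_A_l))
  }
  n <- length(tab$units)
  full <- comp(seq_len(n))
  rows <- lapply(seq_len(n), function(u) {
    red <- comp(setdiff(seq_len(n), u))
    data.frame(unit = tab$units[u],
               dGD_WS = 100 * (full["A_S"] - red["A_S"]) / full["A_T"],
               dGD_BS = 100 * (full["D_A"] - red["D_A"]) / full["A_T"],
               dGD_T = 100 * (full["A_T"] - red["A_T"]) / full["A_T"],
               raw_dGD_WS = unname(full["A_S"] - red["A_S"]),
               raw_dGD_BS = unname(full["D_A"] - red["D_A"]),
               raw_dGD_T = unname(full["A_T"] - red["A_T"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$method <- "allelic_richness"
  out
}
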