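#' Reynolds genetic distance between two populations
#'
#' Multi-locus ratio form of the coancestry-based drift distance:
#' `theta = sum_l sum_u (p_ilu - p_jlu)^2 / 2  /  sum_l (1 - sum_u p_ilu p_jlu)`
#' over shared loci, with no sample-size correction. For biallelic loci the
#' numerator per locus reduces to `(p_i - p_j)^2`.
#'
#' @param p_i,p_j per-locus frequencies of the same reference allele in the
#'   two populations (equal-length vectors; `NA`s dropped pairwise).
#' @return theta in \[0, 1\]; identically fixed populations give 0 with a
#'   warning.
#' @export
reynolds_distance <- function(p_i, p_j) {
  ok <- !is.na(p_i) & !is.na(p_j)
  p_i <- p_i[ok]; p_j <- p_j[ok]
  if (!length(p_i)) stop("no shared loci with defined frequencies")
  num <- sum((p_i - p_j)^2)
  den <- sum(1 - (p_i * p_j + (1 - p_i) * (1 - p_j)))
  if (den == 0) {
    warning("populations identically fixed at all loci; distance set to 0")
    return(0)
  }
  num / den
}

#' Pairwise Reynolds distance matrix over breeds
#'
#' @param gt a [genotype_table()].
#' @param pops population label per individual (defaults to breed codes).
#' @param prune optional `c(window, step, r2)` LD-pruning triple applied
#'   before computing frequencies (e.g. `c(100, 25, 0.25)`).
#' @return symmetric distance matrix with zero diagonal.
#' @export
reynolds_matrix <- function(gt, pops = gt$fam$breed, prune = NULL) {
  if (!is.null(prune)) {
    gt <- subset_genotypes(gt, snps = ld_prune(gt, prune[1], prune[2], prune[3]))
  }
  pops <- as.character(pops)
  units <- sort(unique(pops))
  freqs <- vapply(units, function(u) {
    colMeans(gt$geno[pops == u, , drop = FALSE], na.rm = TRUE) / 2
  }, numeric(n_snps(gt)))
  n <- length(units)
  d <- matrix(0, n, n, dimnames = list(units, units))
  for (i in seq_len(n)) {
    for (j in seq_len(n)[-seq_len(i)]) {
      d[i, j] <- d[j, i] <- reynolds_distance(freqs[, i], freqs[, j])
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration on a symmetric distance matrix
#' with labels sorted for deterministic tie-breaking. Negative branch
#' lengths are clamped to zero with the deficit transferred to the adjacent
#' branches through the same node, preserving path lengths between the
#' joined neighbors.
#'
#' @param d symmetric numeric matrix (zero diagonal, labels as dimnames) or
#'   a `dist` object; at least 3 labels.
#' @return an unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (any(is.na(d)) || any(!is.finite(d))) stop("distance matrix contains NA or non-finite entries")
  if (!isSymmetric(unname(d), tol = 1e-12)) stop("distance matrix must be symmetric")
  if (nrow(d) < 3) stop("at least 3 labels required")
  lab <- rownames(d)
  if (is.null(lab)) lab <- paste0("t", seq_len(nrow(d)))
  ord <- order(lab)
  d <- d[ord, ord, drop = FALSE]
  tree <- ape::nj(stats::as.dist(d))
  clamp_negative_branches(tree)
}

# Set negative edges to zero, moving the deficit onto the edges descending
# from the child node so pairwise path lengths through that node are kept.
clamp_negative_branches <- function(tree) {
  repeat {
    neg <- which(tree$edge.length < -1e-12)
    if (!length(neg)) break
    e <- neg[which.min(tree$edge.length[neg])]
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    child <- tree$edge[e, 2]
    down <- which(tree$edge[, 1] == child)
    if (length(down)) {
      tree$edge.length[down] <- tree$edge.length[down] + deficit
    } else break  # terminal edge: nothing below; leave clamped
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Write / read trees as newick text
#'
#' @param tree a `phylo` object.
#' @param path optional file path; when `NULL` the newick string is
#'   returned.
#' @return `write_newick`: the newick string (invisibly when written to a
#'   file); `read_newick`: a `phylo`.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Write a PHYLIP-style square distance matrix
#' @param d symmetric labelled matrix.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_phylip_dist <- function(d, path) {
  lines <- c(sprintf("%5d", nrow(d)),
             vapply(seq_len(nrow(d)), function(i) {
               paste0(formatC(rownames(d)[i], width = -10),
                      paste(sprintf("%.8f", d[i, ]), collapse = " "))
             }, ""))
  writeLines(lines, path)
  invisible(path)
}
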