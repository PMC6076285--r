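#' Genome length constants
#'
#' Total autosomal genome lengths used as the denominator of the ROH-based
#' inbreeding coefficient: 2,510,611 kb for cattle and 2,610,000 kb for
#' sheep.
#'
#' @param species `"sheep"` or `"cattle"`.
#' @return genome length in kb.
#' @export
genome_length_kb <- function(species) {
  switch(match.arg(species, c("sheep", "cattle")),
         sheep = 2610000, cattle = 2510611)
}

roh_scan_chrom <- function(x, pos, window_snps, het_allowed, missing_allowed,
                           hit_threshold, max_gap_kb, min_len_kb, min_snps,
                           min_density_kb_per_snp) {
  L <- length(x)
  if (L == 0) return(NULL)
  w <- min(window_snps, L)  # short chromosome: single shrunken window
  W <- L - w + 1
  het <- !is.na(x) & x == 1L
  mis <- is.na(x)
  ch <- c(0, cumsum(het))
  cm <- c(0, cumsum(mis))
  t <- seq_len(W)
  win_ok <- (ch[t + w] - ch[t]) <= het_allowed &
    (cm[t + w] - cm[t]) <= missing_allowed
  cwo <- c(0, cumsum(win_ok))
  s <- seq_len(L)
  lo <- pmax(1L, s - w + 1L)
  hi <- pmin(W, s)
  hits <- cwo[hi + 1] - cwo[lo]
  cover <- hi - lo + 1L
  eligible <- hits / cover >= hit_threshold
  if (!any(eligible)) return(NULL)
  # maximal eligible stretches, split at large inter-SNP gaps
  brk <- c(0, which(diff(pos) > max_gap_kb), L)
  segs <- list()
  r <- rle(eligible)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in which(r$values)) {
    a <- starts[k]; b <- ends[k]
    cut <- brk[brk >= a & brk < b]
    bounds <- sort(unique(c(a - 1, cut, b)))
    for (j in seq_len(length(bounds) - 1)) {
      i1 <- bounds[j] + 1; i2 <- bounds[j + 1]
      n <- i2 - i1 + 1
      len <- pos[i2] - pos[i1]
      if (len >= min_len_kb && n >= min_snps &&
          len / n <= min_density_kb_per_snp) {
        segs[[length(segs) + 1]] <- c(i1, i2, n, len)
      }
    }
  }
  if (!length(segs)) return(NULL)
  m <- do.call(rbind, segs)
  data.frame(start_kb = pos[m[, 1]], end_kb = pos[m[, 2]],
             n_snps = m[, 3], length_kb = m[, 4])
}

#' Detect runs of homozygosity for one individual
#'
#' Window-based scanner in the style of the standard SNP-array ROH callers:
#' sliding windows of `window_snps` SNPs (step 1) along each chromosome are
#' called homozygous when they contain at most `het_allowed` heterozygous
#' and `missing_allowed` missing calls; each SNP's hit rate is the fraction
#' of homozygous windows among the windows covering it; SNPs with hit rate
#' at or above `hit_threshold` form candidate runs, which are split at
#' inter-SNP gaps larger than `max_gap_kb` and kept only if they are at
#' least `min_len_kb` long, contain at least `min_snps` SNPs, and have at
#' least one SNP per `min_density_kb_per_snp` kb. Chromosomes with fewer
#' SNPs than the window size are scanned with a single shrunken window.
#'
#' @param gt a [genotype_table()].
#' @param individual individual id.
#' @param min_len_kb minimum segment length (kb).
#' @param min_snps minimum SNPs per segment.
#' @param window_snps scanning window size in SNPs.
#' @param het_allowed heterozygous calls allowed per window.
#' @param missing_allowed missing calls allowed per window.
#' @param min_density_kb_per_snp maximum kb per SNP within a segment.
#' @param max_gap_kb maximum inter-SNP gap within a segment (kb).
#' @param hit_threshold minimum homozygous-window hit rate for a SNP.
#' @return data frame of segments: `individual`, `chrom`, `start_kb`,
#'   `end_kb`, `n_snps`, `length_kb` (zero rows when none).
#' @export
detect_roh <- function(gt, individual, min_len_kb = 500, min_snps = 50,
                       window_snps = 50, het_allowed = 1,
                       missing_allowed = 5, min_density_kb_per_snp = 1000,
                       max_gap_kb = 1000, hit_threshold = 0.05) {
  i <- match(individual, gt$fam$id)
  if (is.na(i)) stop("unknown individual ", individual)
  x_all <- gt$geno[i, ]
  out <- list()
  for (ch in unique(gt$map$chrom)) {
    j <- gt$map$chrom == ch
    seg <- roh_scan_chrom(x_all[j], gt$map$pos_kb[j], window_snps,
                          het_allowed, missing_allowed, hit_threshold,
                          max_gap_kb, min_len_kb, min_snps,
                          min_density_kb_per_snp)
    if (!is.null(seg)) {
      seg <- cbind(individual = individual, chrom = ch, seg,
                   stringsAsFactors = FALSE)
      out[[length(out) + 1]] <- seg
    }
  }
  if (!length(out)) {
    return(data.frame(individual = character(0), chrom = character(0),
                      start_kb = numeric(0), end_kb = numeric(0),
                      n_snps = integer(0), length_kb = numeric(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detect ROH for every individual in a table
#'
#' @inheritParams detect_roh
#' @param ... parameters forwarded to [detect_roh()].
#' @return data frame of segments over all individuals.
#' @export
detect_roh_all <- function(gt, ...) {
  segs <- lapply(gt$fam$id, function(id) detect_roh(gt, id, ...))
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' ROH-based inbreeding coefficient
#'
#' `F_ROH` = summed length of an individual's qualifying ROH segments
#' divided by the total genome length.
#'
#' @param segments data frame of one individual's segments (needs a
#'   `length_kb` column).
#' @param genome_kb total genome length in kb (see [genome_length_kb()]).
#' @param min_len_kb only segments at least this long are summed.
#' @return F_ROH in \[0, 1\].
#' @export
f_roh <- function(segments, genome_kb, min_len_kb = 500) {
  stopifnot(genome_kb > 0)
  tot <- sum(segments$length_kb[segments$length_kb >= min_len_kb])
  if (tot > genome_kb) stop("summed ROH length exceeds genome length; corrupt input")
  tot / genome_kb
}

#' Per-breed ROH summary
#'
#' Per breed: mean per-individual ROH count (`N_ROH`), mean segment length
#' in Mb over individuals carrying at least one segment (`L_ROH`, 0 when
#' none), and mean per-individual `F_ROH`, each with its reporting bin.
#'
#' @param gt a [genotype_table()].
#' @param genome_kb total genome length in kb.
#' @param segments optional precomputed output of [detect_roh_all()];
#'   computed at defaults when missing.
#' @param ... parameters forwarded to [detect_roh_all()].
#' @return data frame, one row per breed.
#' @export
roh_summary <- function(gt, genome_kb, segments = NULL, ...) {
  if (is.null(segments)) segments <- detect_roh_all(gt, ...)
  rows <- lapply(breeds(gt), function(b) {
    ids <- gt$fam$id[gt$fam$breed == b]
    per <- lapply(ids, function(id) {
      s <- segments[segments$individual == id, , drop = FALSE]
      c(n = nrow(s),
        l_mb = if (nrow(s)) mean(s$length_kb) / 1000 else NA_real_,
        f = f_roh(s, genome_kb))
    })
    per <- do.call(rbind, per)
    n_roh <- mean(per[, "n"])
    l_roh <- if (all(is.na(per[, "l_mb"]))) 0 else mean(per[, "l_mb"], na.rm = TRUE)
    fr <- mean(per[, "f"])
    bins <- bin_roh_stats(fr, n_roh, l_roh)
    data.frame(breed = b, N_ROH = n_roh, L_ROH_mb = l_roh, F_ROH = fr,
               F_ROH_bin = bins$F_ROH_bin, N_ROH_bin = bins$N_ROH_bin,
               L_ROH_bin = bins$L_ROH_bin, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Reporting bins for breed-level ROH statistics
#'
#' `F_ROH`: `>= 0.10` / `0.05-0.10` / `<= 0.05`; `N_ROH`: `>= 200` /
#' `150-200` / `<= 150`; `L_ROH` (Mb): `>= 20` / `15-20` / `<= 15`.
#'
#' @param f_roh,n_roh,l_roh_mb breed-level values.
#' @return list with `F_ROH_bin`, `N_ROH_bin`, `L_ROH_bin`.
#' @export
bin_roh_stats <- function(f_roh, n_roh, l_roh_mb) {
  list(
    F_ROH_bin = if (f_roh >= 0.10) "F_ROH >= 0.10"
    else if (f_roh <= 0.05) "F_ROH <= 0.05" else "0.05 < F_ROH < 0.10",
    N_ROH_bin = if (n_roh >= 200) "N_ROH >= 200"
    else if (n_roh <= 150) "N_ROH <= 150" else "150 < N_ROH < 200",
    L_ROH_bin = if (l_roh_mb >= 20) "L_ROH >= 20"
    else if (l_roh_mb <= 15) "L_ROH <= 15" else "15 < L_ROH < 20"
  )
}
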