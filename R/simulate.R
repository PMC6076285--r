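#' Chromosome layout for simulated panels
#'
#' @param n_chrom number of chromosomes.
#' @param spacing_kb inter-SNP spacing in kb (SNPs are evenly spaced).
#' @return a list used by the simulators.
#' @export
chrom_layout <- function(n_chrom = 2, spacing_kb = 50) {
  stopifnot(n_chrom >= 1, spacing_kb > 0)
  list(n_chrom = as.integer(n_chrom), spacing_kb = spacing_kb)
}

even_map <- function(n_snps, layout) {
  per <- rep(n_snps %/% layout$n_chrom, layout$n_chrom)
  if (n_snps %% layout$n_chrom > 0) {
    per[seq_len(n_snps %% layout$n_chrom)] <- per[seq_len(n_snps %% layout$n_chrom)] + 1
  }
  data.frame(
    snp = sprintf("snp%06d", seq_len(n_snps)),
    chrom = rep(as.character(seq_len(layout$n_chrom)), per),
    pos_kb = unlist(lapply(per, function(k) layout$spacing_kb * seq_len(k))),
    stringsAsFactors = FALSE)
}

#' Simulate a multi-breed SNP panel (Balding-Nichols island model)
#'
#' Ancestral allele frequencies are drawn per SNP from Uniform(0.05, 0.95);
#' each breed's frequency is drawn from the Balding-Nichols Beta law
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` with breed-specific drift parameter `F`
#' (`F = 0` leaves the ancestral frequency unchanged). Genotypes are drawn
#' with within-breed inbreeding coefficient `f_ind`
#' (`P(hom) = p^2 + f p q`, `P(het) = 2pq(1-f)`).
#'
#' @param n_breeds number of breeds.
#' @param n_per_breed individuals per breed (recycled).
#' @param n_snps number of SNPs.
#' @param F_pop per-breed drift parameter in \[0, 1) (recycled).
#' @param f_ind per-breed inbreeding coefficient in \[0, 1\] (recycled).
#' @param layout a [chrom_layout()].
#' @param seed integer RNG seed; same seed gives identical output.
#' @return list with `gt` (a [genotype_table()]) and `truth` (ancestral and
#'   breed allele frequencies, parameters, empty ROH registry).
#' @export
simulate_metapopulation <- function(n_breeds, n_per_breed, n_snps,
                                    F_pop = 0.1, f_ind = 0,
                                    layout = chrom_layout(), seed = 1) {
  F_pop <- rep_len(F_pop, n_breeds)
  f_ind <- rep_len(f_ind, n_breeds)
  n_per_breed <- rep_len(n_per_breed, n_breeds)
  if (any(F_pop < 0 | F_pop >= 1)) stop("F_pop must be in [0, 1)")
  if (any(f_ind < 0 | f_ind > 1)) stop("f_ind must be in [0, 1]")
  set.seed(seed)
  p_anc <- stats::runif(n_snps, 0.05, 0.95)
  breed_codes <- sprintf("B%02d", seq_len(n_breeds))
  breed_freq <- matrix(NA_real_, n_breeds, n_snps,
                       dimnames = list(breed_codes, NULL))
  geno_list <- vector("list", n_breeds)
  for (b in seq_len(n_breeds)) {
    Fb <- F_pop[b]
    p <- if (Fb == 0) p_anc else
      stats::rbeta(n_snps, p_anc * (1 - Fb) / Fb, (1 - p_anc) * (1 - Fb) / Fb)
    breed_freq[b, ] <- p
    n <- n_per_breed[b]
    q <- 1 - p
    f <- f_ind[b]
    p_hom2 <- p^2 + f * p * q
    p_het <- 2 * p * q * (1 - f)
    u <- matrix(stats::runif(n * n_snps), n, n_snps)
    g <- matrix(0L, n, n_snps)
    g[u < rep(p_hom2, each = n)] <- 2L
    g[u >= rep(p_hom2, each = n) & u < rep(p_hom2 + p_het, each = n)] <- 1L
    rownames(g) <- sprintf("%s_I%04d", breed_codes[b], seq_len(n))
    geno_list[[b]] <- g
  }
  geno <- do.call(rbind, geno_list)
  map <- even_map(n_snps, layout)
  colnames(geno) <- map$snp
  colnames(breed_freq) <- map$snp
  gt <- genotype_table(geno, rep(breed_codes, n_per_breed), map)
  truth <- list(F_pop = stats::setNames(F_pop, breed_codes),
                f_ind = stats::setNames(f_ind, breed_codes),
                p_ancestral = stats::setNames(p_anc, map$snp),
                breed_freq = breed_freq,
                roh_registry = empty_roh_registry(),
                seed = seed)
  list(gt = gt, truth = truth)
}

empty_roh_registry <- function() {
  data.frame(individual = character(0), chrom = character(0),
             start_kb = numeric(0), end_kb = numeric(0),
             stringsAsFactors = FALSE)
}

#' Forward Wright-Fisher simulation of unlinked loci
#'
#' Discrete generations, constant population size `Ne_true`, random mating
#' with selfing allowed, free recombination (every locus segregates
#' independently). Initial frequencies are Uniform(0.05, 0.95); loci that fix
#' during the run are retained (downstream analyses drop them via their
#' allele-frequency criterion).
#'
#' @param Ne_true true effective (= census) size, `>= 2`.
#' @param n_generations number of generations of drift.
#' @param n_loci number of unlinked loci.
#' @param sample_n diploid individuals sampled at the end
#'   (`<= Ne_true`).
#' @param seed integer RNG seed.
#' @return a [genotype_table()] with a single breed `"WF"`.
#' @export
simulate_wright_fisher <- function(Ne_true, n_generations = 50, n_loci,
                                   sample_n, seed = 1) {
  if (Ne_true < 2) stop("Ne_true must be >= 2")
  if (sample_n > Ne_true) stop("sample_n cannot exceed Ne_true")
  set.seed(seed)
  p0 <- stats::runif(n_loci, 0.05, 0.95)
  G <- matrix(stats::rbinom(Ne_true * n_loci, 2, rep(p0, each = Ne_true)),
              Ne_true, n_loci)
  gamete <- function(P) {
    (P == 2L) + (P == 1L) * matrix(stats::rbinom(length(P), 1, 0.5),
                                   nrow(P), ncol(P))
  }
  for (g in seq_len(n_generations)) {
    mothers <- sample.int(Ne_true, Ne_true, replace = TRUE)
    fathers <- sample.int(Ne_true, Ne_true, replace = TRUE)
    G <- gamete(G[mothers, , drop = FALSE]) + gamete(G[fathers, , drop = FALSE])
  }
  keep <- sample.int(Ne_true, sample_n)
  G <- G[keep, , drop = FALSE]
  storage.mode(G) <- "integer"
  rownames(G) <- sprintf("WF_I%04d", seq_len(sample_n))
  map <- data.frame(snp = sprintf("wf%06d", seq_len(n_loci)),
                    chrom = "1", pos_kb = 1e5 * seq_len(n_loci),
                    stringsAsFactors = FALSE)
  colnames(G) <- map$snp
  genotype_table(G, rep("WF", sample_n), map)
}

#' Inject an autozygous segment into one individual
#'
#' All SNPs of `individual` within `[start_kb, end_kb]` on `chrom` are set
#' homozygous: homozygous calls are kept as they are, heterozygous or
#' missing calls are set homozygous for the individual's breed-major allele
#' at that SNP (ties resolved to the first allele). Used to plant
#' ground-truth runs of homozygosity.
#'
#' @param gt a [genotype_table()].
#' @param individual individual id.
#' @param chrom chromosome label.
#' @param start_kb,end_kb segment bounds in kb (inclusive).
#' @param registry optional existing registry (data frame as returned);
#'   overlapping a previous injection for the same individual and
#'   chromosome is an error.
#' @return list with `gt` (modified table) and `registry` (with the new row).
#' @export
inject_roh <- function(gt, individual, chrom, start_kb, end_kb,
                       registry = empty_roh_registry()) {
  i <- match(individual, gt$fam$id)
  if (is.na(i)) stop("unknown individual ", individual)
  if (end_kb <= start_kb) stop("end_kb must exceed start_kb")
  prev <- registry[registry$individual == individual &
                     registry$chrom == as.character(chrom), , drop = FALSE]
  if (any(prev$start_kb <= end_kb & prev$end_kb >= start_kb)) {
    stop("segment overlaps an existing injected segment for ", individual)
  }
  in_seg <- gt$map$chrom == as.character(chrom) &
    gt$map$pos_kb >= start_kb & gt$map$pos_kb <= end_kb
  if (!any(in_seg)) stop("no SNP in [", start_kb, ", ", end_kb, "] on chromosome ", chrom)
  p_breed <- allele_freq(gt, gt$fam$id[gt$fam$breed == gt$fam$breed[i]])
  x <- gt$geno[i, in_seg]
  major2 <- !is.na(p_breed[in_seg]) & p_breed[in_seg] > 0.5
  x[is.na(x) | x == 1L] <- ifelse(major2[is.na(x) | x == 1L], 2L, 0L)
  gt$geno[i, in_seg] <- as.integer(x)
  registry <- rbind(registry,
                    data.frame(individual = individual,
                               chrom = as.character(chrom),
                               start_kb = start_kb, end_kb = end_kb,
                               stringsAsFactors = FALSE))
  list(gt = gt, registry = registry)
}

#' Generate regional GDP-per-capita series with an optional planted signal
#'
#' Produces one annual GDP-per-capita series per region for 1993-2013 (21
#' values). Each region's series rises linearly from its base value by a
#' total increase `delta = growth + planted_beta * contribution + eps`,
#' `eps ~ N(0, noise_sd)`, so the 2013-1993 increase carries a plantable
#' linear association with the supplied diversity contributions.
#'
#' @param regions character vector of region names.
#' @param base base-year (1993) GDP per capita, recycled over regions.
#' @param growth baseline total increase over the period (the intercept of
#'   the planted relation).
#' @param noise_sd standard deviation of the noise on the total increase.
#' @param planted_beta slope of the planted relation between the GDPPC
#'   increase and `contributions`.
#' @param contributions per-region diversity contributions (e.g. averaged
#'   total-diversity contributions); required when `planted_beta != 0`.
#' @param seed integer RNG seed.
#' @return data frame with columns `region`, `year`, `gdppc`.
#' @export
generate_region_economy <- function(regions, base = 8000, growth = 5000,
                                    noise_sd = 0, planted_beta = 0,
                                    contributions = NULL, seed = 1) {
  n <- length(regions)
  base <- rep_len(base, n)
  if (is.null(contributions)) contributions <- rep(0, n)
  if (length(contributions) != n) stop("one contribution per region required")
  set.seed(seed)
  delta <- growth + planted_beta * contributions +
    stats::rnorm(n, 0, noise_sd)
  years <- 1993:2013
  out <- do.call(rbind, lapply(seq_len(n), function(r) {
    series <- base[r] + delta[r] * (years - 1993) / 20
    data.frame(region = regions[r], year = years, gdppc = series,
               stringsAsFactors = FALSE)
  }))
  if (any(out$gdppc < 0)) stop("negative GDP per capita generated; raise base or lower noise_sd")
  out
}
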