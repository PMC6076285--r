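#' Build a genotype table
#'
#' The central container of the package: diploid, biallelic SNP genotypes for
#' a set of individuals, each assigned to exactly one breed, together with a
#' SNP map (chromosome and physical position in kb). Genotypes are stored as
#' allele-2 dosages (0, 1, 2) with `NA` for missing calls; the original
#' allele labels are kept per SNP so files can be round-tripped.
#'
#' SNPs are sorted by chromosome and then by physical position at
#' construction; positions must be strictly increasing within a chromosome.
#'
#' @param geno integer matrix, individuals x SNPs, entries 0/1/2 (dosage of
#'   allele 2) or `NA`. Row names are individual ids, column names SNP ids.
#' @param breed character vector, one breed code per individual.
#' @param map data frame with columns `snp`, `chrom`, `pos_kb` and optionally
#'   `a1`, `a2` (allele labels; default `"A"`, `"B"`).
#' @return An object of class `genotype_table` with elements `geno`, `fam`
#'   (data frame `id`, `breed`) and `map`.
#' @export
genotype_table <- function(geno, breed, map) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.null(rownames(geno))) stop("geno must have individual ids as row names")
  if (is.null(colnames(geno))) stop("geno must have SNP ids as column names")
  if (anyDuplicated(rownames(geno))) stop("duplicate individual ids")
  if (anyDuplicated(colnames(geno))) stop("duplicate SNP ids")
  if (length(breed) != nrow(geno)) stop("one breed code per individual required")
  bad <- geno[!is.na(geno) & !(geno %in% 0:2)]
  if (length(bad)) stop("genotype dosages must be 0, 1, 2 or NA")
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  need <- c("snp", "chrom", "pos_kb")
  if (!all(need %in% names(map))) stop("map needs columns snp, chrom, pos_kb")
  if (is.null(map$a1)) map$a1 <- "A"
  if (is.null(map$a2)) map$a2 <- "B"
  map$chrom <- as.character(map$chrom)
  map$pos_kb <- as.numeric(map$pos_kb)
  if (any(map$pos_kb < 0)) stop("SNP positions must be non-negative")
  if (!setequal(map$snp, colnames(geno))) stop("map SNPs do not match geno columns")
  ord <- order(chrom_order(map$chrom), map$pos_kb)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  geno <- geno[, map$snp, drop = FALSE]
  for (ch in unique(map$chrom)) {
    p <- map$pos_kb[map$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("SNP positions not strictly increasing on chromosome ", ch)
    }
  }
  structure(
    list(
      geno = geno,
      fam = data.frame(id = rownames(geno), breed = as.character(breed),
                       stringsAsFactors = FALSE),
      map = map
    ),
    class = "genotype_table"
  )
}

# Numeric-aware chromosome ordering ("1" < "2" < "10" < "X")
chrom_order <- function(chrom) {
  n <- suppressWarnings(as.numeric(chrom))
  key <- ifelse(is.na(n), Inf, n)
  o <- order(key, chrom)
  match(seq_along(chrom), seq_along(chrom)[o])
  r <- numeric(length(chrom))
  r[o] <- seq_along(chrom)
  r
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$geno), "individuals x", ncol(x$geno), "SNPs\n")
  cat("  breeds:", paste(sort(unique(x$fam$breed)), collapse = ", "), "\n")
  cat("  chromosomes:", length(unique(x$map$chrom)),
      " missing rate:", format(mean(is.na(x$geno)), digits = 3), "\n")
  invisible(x)
}

#' Number of individuals / SNPs in a genotype table
#' @param gt a `genotype_table`.
#' @return integer count.
#' @export
n_individuals <- function(gt) nrow(gt$geno)

#' @rdname n_individuals
#' @export
n_snps <- function(gt) ncol(gt$geno)

#' Subset a genotype table
#'
#' @param gt a `genotype_table`.
#' @param individuals character ids (or logical/integer index) to keep.
#' @param snps character SNP ids (or logical/integer index) to keep.
#' @return a `genotype_table`.
#' @export
subset_genotypes <- function(gt, individuals = NULL, snps = NULL) {
  g <- gt$geno
  fam <- gt$fam
  map <- gt$map
  if (!is.null(individuals)) {
    idx <- if (is.character(individuals)) match(individuals, fam$id) else
      seq_len(nrow(g))[individuals]
    if (anyNA(idx)) stop("unknown individual id(s)")
    g <- g[idx, , drop = FALSE]
    fam <- fam[idx, , drop = FALSE]
  }
  if (!is.null(snps)) {
    jdx <- if (is.character(snps)) match(snps, map$snp) else
      seq_len(ncol(g))[snps]
    if (anyNA(jdx)) stop("unknown SNP id(s)")
    g <- g[, jdx, drop = FALSE]
    map <- map[jdx, , drop = FALSE]
  }
  genotype_table(g, fam$breed, map)
}

#' Individuals belonging to one breed
#' @param gt a `genotype_table`.
#' @param breed breed code.
#' @return a `genotype_table` restricted to that breed.
#' @export
breed_genotypes <- function(gt, breed) {
  keep <- gt$fam$breed == breed
  if (!any(keep)) stop("no individuals in breed ", breed)
  subset_genotypes(gt, individuals = which(keep))
}

#' Breed codes present in a table
#' @param gt a `genotype_table`.
#' @return character vector of breed codes (sorted).
#' @export
breeds <- function(gt) sort(unique(gt$fam$breed))

#' Per-SNP allele frequencies
#'
#' Frequency of allele 2 at every SNP, over the non-missing genotypes of the
#' given individuals (all by default).
#'
#' @param gt a `genotype_table`.
#' @param individuals optional subset of individual ids.
#' @return named numeric vector (NaN where no calls).
#' @export
allele_freq <- function(gt, individuals = NULL) {
  g <- gt$geno
  if (!is.null(individuals)) g <- g[gt$fam$id %in% individuals, , drop = FALSE]
  colMeans(g, na.rm = TRUE) / 2
}

#' Per-SNP minor allele frequency
#' @inheritParams allele_freq
#' @return named numeric vector in \[0, 0.5\].
#' @export
minor_allele_freq <- function(gt, individuals = NULL) {
  p <- allele_freq(gt, individuals)
  pmin(p, 1 - p)
}

#' Call rates
#'
#' @param gt a `genotype_table`.
#' @return `individual_call_rate(gt)`: named fraction of non-missing SNP
#'   calls per individual; `snp_call_rate(gt)`: same per SNP.
#' @export
individual_call_rate <- function(gt) rowMeans(!is.na(gt$geno))

#' @rdname individual_call_rate
#' @export
snp_call_rate <- function(gt) colMeans(!is.na(gt$geno))
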