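#' Read a PED/MAP genotype panel
#'
#' Reads PLINK-style whitespace-delimited text PED/MAP files. The PED family
#' ID column is interpreted as the breed code; genotype `"0 0"` is missing.
#' MAP physical positions are in base pairs and are converted to kb.
#'
#' Allele labels at each SNP are ordered lexicographically; the dosage stored
#' in the returned table counts copies of the second (lexicographically
#' larger) allele. More than two distinct alleles at a SNP is an error.
#'
#' @param ped_path path to the PED file.
#' @param map_path path to the MAP file.
#' @return a [genotype_table()].
#' @export
read_genotypes <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
  map_raw <- utils::read.table(map_path, header = FALSE,
                               colClasses = "character")
  if (ncol(map_raw) != 4) stop("MAP file must have 4 columns, found ",
                               ncol(map_raw))
  names(map_raw) <- c("chrom", "snp", "cm", "bp")
  if (anyDuplicated(map_raw$snp)) {
    stop("duplicate SNP id in MAP: ",
         map_raw$snp[duplicated(map_raw$snp)][1])
  }
  L <- nrow(map_raw)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  len <- lengths(toks)
  if (any(len != 6 + 2 * L)) {
    stop("ragged PED row ", which(len != 6 + 2 * L)[1],
         ": expected ", 6 + 2 * L, " fields, found ",
         len[which(len != 6 + 2 * L)[1]])
  }
  tok <- do.call(rbind, toks)
  breed <- tok[, 1]
  ids <- tok[, 2]
  if (anyDuplicated(ids)) {
    stop("duplicate individual id in PED: ", ids[duplicated(ids)][1])
  }
  al <- tok[, -(1:6), drop = FALSE]
  A1 <- al[, seq(1, 2 * L, by = 2), drop = FALSE]
  A2 <- al[, seq(2, 2 * L, by = 2), drop = FALSE]
  half <- xor(A1 == "0", A2 == "0")
  if (any(half)) {
    w <- which(half, arr.ind = TRUE)[1, ]
    stop("half-missing genotype for individual ", ids[w[1]],
         " at SNP ", map_raw$snp[w[2]])
  }
  miss <- A1 == "0"
  geno <- matrix(NA_integer_, nrow(tok), L,
                 dimnames = list(ids, map_raw$snp))
  a1 <- a2 <- character(L)
  for (j in seq_len(L)) {
    obs <- c(A1[!miss[, j], j], A2[!miss[, j], j])
    alleles <- sort(unique(obs))
    if (length(alleles) > 2) {
      stop("more than 2 alleles at SNP ", map_raw$snp[j], ": ",
           paste(alleles, collapse = ","))
    }
    if (length(alleles) == 0) alleles <- c("A", "B")
    if (length(alleles) == 1) alleles <- c(alleles, alleles)
    a1[j] <- alleles[1]; a2[j] <- alleles[2]
    d <- (A1[, j] == alleles[2]) + (A2[, j] == alleles[2])
    if (alleles[1] == alleles[2]) d <- rep(0L, nrow(tok))
    d[miss[, j]] <- NA_integer_
    geno[, j] <- d
  }
  map <- data.frame(snp = map_raw$snp, chrom = map_raw$chrom,
                    pos_kb = as.numeric(map_raw$bp) / 1000,
                    a1 = a1, a2 = a2, stringsAsFactors = FALSE)
  genotype_table(geno, breed, map)
}

#' Write a genotype table as PED/MAP
#'
#' Inverse of [read_genotypes()]: writes the same whitespace-delimited
#' dialect (MAP positions in bp, `"0 0"` for missing calls).
#'
#' @param gt a [genotype_table()].
#' @param ped_path,map_path output paths.
#' @return invisibly, the two paths.
#' @export
write_genotypes <- function(gt, ped_path, map_path) {
  map <- gt$map
  utils::write.table(
    data.frame(map$chrom, map$snp, 0, format(map$pos_kb * 1000,
                                             scientific = FALSE,
                                             trim = TRUE)),
    map_path, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  g <- gt$geno
  n <- nrow(g); L <- ncol(g)
  A1 <- matrix(rep(map$a1, each = n), n, L)
  A2 <- matrix(rep(map$a1, each = n), n, L)
  a2rep <- rep(map$a2, each = n)
  i1 <- which(!is.na(g) & g >= 1)
  i2 <- which(!is.na(g) & g == 2)
  A1[i1] <- a2rep[i1]
  A2[i2] <- a2rep[i2]
  A1[is.na(g)] <- "0"; A2[is.na(g)] <- "0"
  body <- matrix("", n, 2 * L)
  body[, seq(1, 2 * L, 2)] <- A1
  body[, seq(2, 2 * L, 2)] <- A2
  rows <- cbind(gt$fam$breed, gt$fam$id, "0", "0", "0", "-9", body)
  writeLines(apply(rows, 1, paste, collapse = " "), ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read a breed metadata table
#'
#' Tab-separated text with columns `breed_code`, `species`, `region`.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_breed_metadata <- function(path) {
  md <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("breed_code", "species", "region")
  if (!all(need %in% names(md))) {
    stop("breed metadata needs columns: ", paste(need, collapse = ", "))
  }
  md
}

#' Write a QC report as TSV
#' @param report a `qc_report` from [qc_filter()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_qc_report <- function(report, path) {
  lines <- c(
    sprintf("n_individuals_in\t%d", report$n_individuals_in),
    sprintf("n_individuals_out\t%d", report$n_individuals_out),
    sprintf("n_snps_in\t%d", report$n_snps_in),
    sprintf("n_snps_out\t%d", report$n_snps_out))
  for (reason in names(report$removed_individuals)) {
    items <- report$removed_individuals[[reason]]
    lines <- c(lines, sprintf("removed_individual\t%s\t%s", reason,
                              paste(items, collapse = ",")))
  }
  for (reason in names(report$removed_snps)) {
    items <- report$removed_snps[[reason]]
    lines <- c(lines, sprintf("removed_snp\t%s\t%s", reason,
                              paste(items, collapse = ",")))
  }
  writeLines(lines, path)
  invisible(path)
}
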