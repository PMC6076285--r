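pipeline_defaults <- function() {
  list(
    species = "sheep",            # sheep | cattle | custom
    genome_kb = NULL,             # required for species = "custom"
    seed = 1,
    out_dir = "metadiv-run",
    input = "synthetic",          # "synthetic" or list(ped =, map =)
    synthetic = list(n_breeds = 5, n_per_breed = 30, n_snps = 2000,
                     F_pop = 0.1, f_ind = 0, n_chrom = 2, spacing_kb = 50),
    regions = NULL,               # named vector breed -> region
    qc = list(min_ind_call = 0.95, min_snp_call = 0.95, min_maf = 0.05,
              autosomes = NULL),
    roh = list(min_len_kb = 500, min_snps = 50, window_snps = 50,
               het_allowed = 1, missing_allowed = 5,
               min_density_kb_per_snp = 1000, max_gap_kb = 1000,
               hit_threshold = 0.05),
    ne = list(pcrit = 0.05, prune = c(100, 25, 0.05)),
    tree_prune = c(100, 25, 0.25),
    lambda = 1,
    g = NULL,                     # rarefaction size; NULL = data-driven
    economy = NULL                # path to CSV, or list for the generator
  )
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills in defaults, and validates
#' ranges. Defaults follow the standard analysis parameters: MAF 0.05,
#' call rates 0.95, Pcrit 0.05, ROH 500 kb / 50 SNPs / 1 het / density
#' 1000, pruning triples 100-25-0.05 (Ne) and 100-25-0.25 (tree),
#' `lambda = 1`. The species sets the ROH genome length (sheep 2,610,000
#' kb; cattle 2,510,611 kb; `custom` requires `genome_kb`).
#'
#' @param config path to a YAML file, or a (possibly partial) named list.
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  def <- pipeline_defaults()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(def, config)
  for (sub in c("synthetic", "qc", "roh", "ne")) {
    bad <- setdiff(names(config[[sub]]), names(def[[sub]]))
    if (length(bad)) stop("unknown config key(s) in ", sub, ": ",
                          paste(bad, collapse = ", "))
  }
  if (!cfg$species %in% c("sheep", "cattle", "custom")) {
    stop("species must be sheep, cattle or custom")
  }
  cfg$genome_kb <- if (cfg$species == "custom") {
    if (is.null(cfg$genome_kb) || cfg$genome_kb <= 0) {
      stop("species = custom requires a positive genome_kb")
    }
    cfg$genome_kb
  } else genome_length_kb(cfg$species)
  if (cfg$lambda < 0) stop("lambda must be non-negative")
  with(cfg$qc, stopifnot(min_ind_call >= 0, min_ind_call <= 1,
                         min_snp_call >= 0, min_snp_call <= 1,
                         min_maf >= 0, min_maf < 1))
  if (cfg$ne$pcrit < 0 || cfg$ne$pcrit >= 0.5) stop("pcrit must be in [0, 0.5)")
  if (!is.list(cfg$input) && !identical(cfg$input, "synthetic")) {
    stop("input must be \"synthetic\" or list(ped = ..., map = ...)")
  }
  if (is.list(cfg$input)) {
    for (p in unlist(cfg$input)) if (!file.exists(p)) stop("input file not found: ", p)
  }
  if (is.character(cfg$economy) && !file.exists(cfg$economy)) {
    stop("economy file not found: ", cfg$economy)
  }
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full conservation-prioritization pipeline
#'
#' Stage order: input (read or simulate) -> QC -> per-breed diversity and
#' LD-Ne -> ROH -> diversity partitions and leave-one-out contributions
#' (coancestry and allelic richness, breed level and region level) ->
#' method averaging and paired t-tests -> Reynolds/NJ tree -> economics
#' comparisons and regressions. Every stage's table is written to
#' `out_dir` as TSV/newick/JSON; a rerun with the same config and seed is
#' byte-identical.
#'
#' @param config a [pipeline_config()] (or anything it accepts).
#' @return invisibly, a list with the main in-memory results and the paths
#'   of the written artifacts.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run_log.txt")
  log_lines <- c(sprintf("metadiv pipeline, seed %d, species %s (L = %d kb)",
                         cfg$seed, cfg$species, as.integer(cfg$genome_kb)))
  paths <- character(0)

  # -- input stage
  set.seed(cfg$seed)
  if (identical(cfg$input, "synthetic")) {
    sy <- cfg$synthetic
    sim <- simulate_metapopulation(sy$n_breeds, sy$n_per_breed, sy$n_snps,
                                   F_pop = sy$F_pop, f_ind = sy$f_ind,
                                   layout = chrom_layout(sy$n_chrom, sy$spacing_kb),
                                   seed = cfg$seed)
    gt0 <- sim$gt
    log_lines <- c(log_lines, sprintf("simulated %d breeds x %s individuals, %d SNPs",
                                      sy$n_breeds, paste(sy$n_per_breed, collapse = "/"),
                                      sy$n_snps))
  } else {
    gt0 <- read_genotypes(cfg$input$ped, cfg$input$map)
    log_lines <- c(log_lines, sprintf("read %d individuals x %d SNPs from %s",
                                      n_individuals(gt0), n_snps(gt0), cfg$input$ped))
  }
  region_of <- cfg$regions
  if (is.null(region_of)) {
    region_of <- stats::setNames(paste0("region_", breeds(gt0)), breeds(gt0))
  }
  region_of <- unlist(region_of)

  # -- QC
  qc <- qc_filter(gt0, cfg$qc$min_ind_call, cfg$qc$min_snp_call,
                  cfg$qc$min_maf, cfg$qc$autosomes)
  gt <- qc$gt
  paths <- c(paths, write_qc_report(qc$report, file.path(cfg$out_dir, "qc_report.tsv")))
  log_lines <- c(log_lines, sprintf("QC: %d/%d individuals, %d/%d SNPs retained",
                                    qc$report$n_individuals_out, qc$report$n_individuals_in,
                                    qc$report$n_snps_out, qc$report$n_snps_in))

  # -- per-breed statistics
  stats_tab <- breed_diversity(gt, pcrit = cfg$ne$pcrit, prune = cfg$ne$prune)
  paths <- c(paths, write_tsv(stats_tab, file.path(cfg$out_dir, "breed_diversity.tsv")))

  # -- ROH
  segs <- do.call(detect_roh_all, c(list(gt), cfg$roh))
  roh_tab <- roh_summary(gt, cfg$genome_kb, segments = segs)
  paths <- c(paths, write_tsv(segs, file.path(cfg$out_dir, "roh_segments.tsv")),
             write_tsv(roh_tab, file.path(cfg$out_dir, "roh_summary.tsv")))

  # -- diversity partitions and contributions (breed level)
  part_co <- partition_diversity(gt)
  part_al <- allelic_partition(gt, g = cfg$g)
  co_tab <- leave_one_out_contributions(gt, lambda = cfg$lambda)
  al_tab <- leave_one_out_allelic(gt, g = cfg$g)
  avg_tab <- average_methods(co_tab, al_tab)
  paths <- c(paths,
             write_tsv(co_tab, file.path(cfg$out_dir, "contributions_coancestry.tsv")),
             write_tsv(al_tab, file.path(cfg$out_dir, "contributions_allelic.tsv")),
             write_tsv(avg_tab, file.path(cfg$out_dir, "contributions_averaged.tsv")))
  method_tests <- lapply(c(dGD_WS = "dGD_WS", dGD_BS = "dGD_BS", dGD_T = "dGD_T"),
                         function(cl) {
                           m <- merge(co_tab[, c("unit", cl)], al_tab[, c("unit", cl)], by = "unit")
                           suppressWarnings(paired_method_test(m[[2]], m[[3]]))
                         })

  # -- region level
  pop_region <- region_of[gt$fam$breed]
  region_avg <- NULL
  if (length(unique(pop_region)) >= 3) {
    co_reg <- leave_one_out_contributions(gt, pops = pop_region, lambda = cfg$lambda)
    al_reg <- leave_one_out_allelic(gt, pops = pop_region, g = cfg$g)
    region_avg <- average_methods(co_reg, al_reg)
    paths <- c(paths, write_tsv(region_avg,
                                file.path(cfg$out_dir, "contributions_region_averaged.tsv")))
  } else {
    log_lines <- c(log_lines, "fewer than 3 regions: region-level contributions skipped")
  }

  # -- structure tree
  tree <- NULL
  if (length(breeds(gt)) >= 3) {
    dmat <- reynolds_matrix(gt, prune = cfg$tree_prune)
    tree <- nj_tree(dmat)
    paths <- c(paths, write_phylip_dist(dmat, file.path(cfg$out_dir, "reynolds_dist.txt")))
    write_newick(tree, file.path(cfg$out_dir, "nj_tree.nwk"))
    paths <- c(paths, file.path(cfg$out_dir, "nj_tree.nwk"))
  } else {
    log_lines <- c(log_lines, "fewer than 3 breeds: tree stage skipped")
  }

  # -- priority report
  priority <- build_priority_report(avg_tab, stats_tab, roh_tab)
  paths <- c(paths, write_tsv(priority, file.path(cfg$out_dir, "priority_report.tsv")))

  # -- economics
  economics <- NULL
  if (!is.null(cfg$economy) && !is.null(region_avg)) {
    eco <- if (is.character(cfg$economy)) read_region_economy(cfg$economy) else {
      e <- cfg$economy
      contributions <- region_avg$dGD_T[match(unique(unname(region_of)), region_avg$unit)]
      generate_region_economy(unique(unname(region_of)),
                              base = e$base %||% 8000,
                              growth = e$growth %||% 5000,
                              noise_sd = e$noise_sd %||% 0,
                              planted_beta = e$planted_beta %||% 0,
                              contributions = contributions,
                              seed = cfg$seed + 1L)
    }
    eco_sum <- region_economy_summary(eco)
    merged <- merge(region_avg, eco_sum, by.x = "unit", by.y = "region")
    regressions <- lapply(c(dGD_WS = "dGD_WS", dGD_BS = "dGD_BS", dGD_T = "dGD_T"),
                          function(cl) regress_diversity_on_economy(merged[[cl]],
                                                                    merged$delta_GDPPC))
    ks <- NULL
    by_cat <- split(merged$dGD_T, merged$category)
    by_cat <- by_cat[lengths(by_cat) >= 2]
    if (length(by_cat) >= 2) ks <- compare_groups_ks(by_cat)
    economics <- list(summary = eco_sum, merged = merged,
                      regressions = regressions, ks = ks)
    paths <- c(paths, write_tsv(eco_sum, file.path(cfg$out_dir, "economy_summary.tsv")))
    report <- list(method_paired_t = method_tests,
                   regressions = regressions, ks = ks)
    jsonlite::write_json(report, file.path(cfg$out_dir, "economics_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, file.path(cfg$out_dir, "economics_report.json"))
  }

  writeLines(c(log_lines, paste("wrote:", paths)), log_path)
  invisible(list(gt = gt, qc = qc$report, breed_stats = stats_tab,
                 roh = roh_tab, roh_segments = segs,
                 partition_coancestry = part_co, partition_allelic = part_al,
                 contributions = list(coancestry = co_tab, allelic = al_tab,
                                      averaged = avg_tab, region = region_avg),
                 method_tests = method_tests, tree = tree,
                 priority = priority, economics = economics,
                 paths = c(paths, log_path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
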