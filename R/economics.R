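#' Read a long-format region economy table
#'
#' CSV with columns `region`, `year`, `gdppc` (annual GDP per capita, USD).
#'
#' @param path file path.
#' @return data frame.
#' @export
read_region_economy <- function(path) {
  eco <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("region", "year", "gdppc")
  if (!all(need %in% names(eco))) {
    stop("economy table needs columns: ", paste(need, collapse = ", "))
  }
  eco
}

#' Summarise regional GDP-per-capita series
#'
#' Per region: the 1993-2013 mean (`A_GDPPC`), the 2013 minus 1993 increase
#' (`delta_GDPPC`) and the economic category from
#' [categorize_economy()]. Each region must have the full 21 annual values.
#'
#' @param eco long data frame (`region`, `year`, `gdppc`).
#' @return data frame, one row per region.
#' @export
region_economy_summary <- function(eco) {
  rows <- lapply(split(eco, eco$region), function(e) {
    e <- e[order(e$year), ]
    if (nrow(e) != 21 || e$year[1] != 1993 || e$year[21] != 2013) {
      stop("region ", e$region[1], " must have 21 annual values for 1993-2013")
    }
    if (any(e$gdppc < 0)) stop("negative GDP per capita for region ", e$region[1])
    a <- mean(e$gdppc)
    data.frame(region = e$region[1], A_GDPPC = a,
               delta_GDPPC = e$gdppc[21] - e$gdppc[1],
               category = categorize_economy(a), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Economic category of a region
#'
#' `underdeveloped` when A-GDPPC is at most $1,500; `developed` when at
#' least $15,000; `developing` in between (the overlapping printed
#' boundaries are resolved to the poorer category at $1,500 and to
#' developed at $15,000).
#'
#' @param a_gdppc mean annual GDP per capita (positive).
#' @param lower,upper category thresholds in USD.
#' @return character label (vectorized).
#' @export
categorize_economy <- function(a_gdppc, lower = 1500, upper = 15000) {
  stopifnot(all(a_gdppc > 0))
  ifelse(a_gdppc <= lower, "underdeveloped",
         ifelse(a_gdppc >= upper, "developed", "developing"))
}

#' Average the two contribution methods
#'
#' Merges a coancestry and an allelic-richness contribution table (same
#' units) and takes the per-unit arithmetic mean of each contribution
#' column.
#'
#' @param coancestry_table,allelic_table outputs of
#'   [leave_one_out_contributions()] and [leave_one_out_allelic()].
#' @return data frame: `unit`, per-method and averaged `dGD_WS`, `dGD_BS`,
#'   `dGD_T`, the averaged contribution fraction bin, and the rank by
#'   averaged `dGD_T` (ties broken by unit code).
#' @export
average_methods <- function(coancestry_table, allelic_table) {
  if (!setequal(coancestry_table$unit, allelic_table$unit)) {
    stop("unit sets differ between the two methods: ",
         paste(symdiff_chr(coancestry_table$unit, allelic_table$unit),
               collapse = ", "))
  }
  co <- coancestry_table[order(coancestry_table$unit), ]
  al <- allelic_table[match(co$unit, allelic_table$unit), ]
  out <- data.frame(
    unit = co$unit,
    dGD_WS_coancestry = co$dGD_WS, dGD_BS_coancestry = co$dGD_BS,
    dGD_T_coancestry = co$dGD_T,
    dGD_WS_allelic = al$dGD_WS, dGD_BS_allelic = al$dGD_BS,
    dGD_T_allelic = al$dGD_T,
    dGD_WS = (co$dGD_WS + al$dGD_WS) / 2,
    dGD_BS = (co$dGD_BS + al$dGD_BS) / 2,
    dGD_T = (co$dGD_T + al$dGD_T) / 2,
    stringsAsFactors = FALSE)
  out$dGD_T_bin <- vapply(out$dGD_T, bin_contribution, "")
  out <- out[order(-out$dGD_T, out$unit), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

symdiff_chr <- function(a, b) union(setdiff(a, b), setdiff(b, a))

#' Paired t-test between the two contribution methods
#'
#' Two-sided paired t-test of a contribution column across units. Constant
#' (zero-variance) differences give `t = 0`, `p = 1` with a warning.
#'
#' @param coancestry_values,allelic_values per-unit contribution values in
#'   matching unit order.
#' @return list with `t`, `df`, `p`.
#' @export
paired_method_test <- function(coancestry_values, allelic_values) {
  if (length(coancestry_values) != length(allelic_values)) {
    stop("the two methods must cover the same units")
  }
  d <- coancestry_values - allelic_values
  if (stats::sd(d) == 0) {
    warning("zero-variance differences; returning t = 0, p = 1")
    return(list(t = 0, df = length(d) - 1, p = 1))
  }
  ht <- stats::t.test(coancestry_values, allelic_values, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Bin a contribution into the four reporting fractions
#'
#' Fractions `< -0.1`, `-0.1-0`, `0-0.1`, `> 0.1`; boundaries go to the
#' lower-magnitude interval (0 and -0.1 to `-0.1-0`; 0.1 to `0-0.1`).
#'
#' @param delta finite contribution value.
#' @return one of `"<-0.1"`, `"-0.1-0"`, `"0-0.1"`, `">0.1"`.
#' @export
bin_contribution <- function(delta) {
  stopifnot(is.finite(delta))
  if (delta < -0.1) "<-0.1"
  else if (delta <= 0) "-0.1-0"
  else if (delta <= 0.1) "0-0.1"
  else ">0.1"
}

#' Pairwise Kolmogorov-Smirnov comparisons between groups
#'
#' Two-sample KS test for every pair of categories; the exact p-value is
#' used when the group sizes allow at most `max_exact` label splits,
#' otherwise the asymptotic approximation.
#'
#' @param values_by_category named list of numeric vectors.
#' @param max_exact exact-enumeration budget on `n1 * n2`.
#' @return data frame: `group1`, `group2`, `D`, `p`, `exact`.
#' @export
compare_groups_ks <- function(values_by_category, max_exact = 10000) {
  if (any(lengths(values_by_category) < 2)) {
    stop("every compared group needs at least 2 values")
  }
  gs <- names(values_by_category)
  pairs <- utils::combn(gs, 2)
  rows <- apply(pairs, 2, function(pr) {
    x <- values_by_category[[pr[1]]]
    y <- values_by_category[[pr[2]]]
    exact <- length(x) * length(y) <= max_exact
    ht <- suppressWarnings(stats::ks.test(x, y, exact = exact))
    data.frame(group1 = pr[1], group2 = pr[2],
               D = unname(ht$statistic), p = ht$p.value, exact = exact,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ordinary least squares with slope inference
#'
#' Simple OLS of `y` on `x` with the textbook slope t-test
#' (`df = n - 2`).
#'
#' @param x predictor, `y` response; at least 3 paired observations.
#' @param y response.
#' @return list with `slope`, `intercept`, `r_squared`, `p`, `se_slope`,
#'   `df`, `ci95` (95 percent slope confidence interval).
#' @export
ols_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("at least 3 paired observations required")
  if (stats::var(x) == 0) stop("zero predictor variance")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  ci <- stats::confint(fit, "x", level = 0.95)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p = sm$coefficients["x", "Pr(>|t|)"],
       se_slope = sm$coefficients["x", "Std. Error"],
       df = fit$df.residual,
       ci95 = c(ci[1], ci[2]))
}

#' Dual regression between diversity contributions and economic growth
#'
#' Fits OLS in both directions for one contribution component: the
#' contribution on the GDPPC increase (the reported association) and the
#' GDPPC increase on the contribution (the reverse fit, e.g. for recovering
#' a planted economy-on-diversity slope). R-squared is shared between the
#' two directions.
#'
#' @param delta_gd per-unit diversity contributions.
#' @param delta_gdppc matching GDPPC increases.
#' @return list with `diversity_on_economy` and `economy_on_diversity`
#'   [ols_fit()] results and `r_squared`.
#' @export
regress_diversity_on_economy <- function(delta_gd, delta_gdppc) {
  f1 <- ols_fit(delta_gdppc, delta_gd)
  f2 <- ols_fit(delta_gd, delta_gdppc)
  list(diversity_on_economy = f1, economy_on_diversity = f2,
       r_squared = f1$r_squared)
}

#' Assemble the per-breed conservation priority report
#'
#' Merges averaged contributions with per-breed diversity and ROH
#' statistics, ranks breeds by averaged total contribution, marks the core
#' conservation set (`dGD_T > 0`) and flags at-risk breeds (`Ne <= 100` or
#' `F_ROH >= 0.10`).
#'
#' @param records output of [average_methods()] at breed level.
#' @param breed_stats output of [breed_diversity()].
#' @param roh output of [roh_summary()].
#' @return data frame sorted by rank.
#' @export
build_priority_report <- function(records, breed_stats, roh) {
  orphans <- symdiff_chr(records$unit, breed_stats$breed)
  orphans <- union(orphans, symdiff_chr(records$unit, roh$breed))
  if (length(orphans)) {
    stop("breed keys do not match across inputs: ",
         paste(sort(orphans), collapse = ", "))
  }
  out <- records
  out <- merge(out, breed_stats, by.x = "unit", by.y = "breed")
  out <- merge(out, roh[, c("breed", "N_ROH", "L_ROH_mb", "F_ROH")],
               by.x = "unit", by.y = "breed")
  out$core_set <- out$dGD_T > 0
  out$at_risk <- (!is.na(out$Ne_hat) & out$Ne_hat <= 100) | out$F_ROH >= 0.10
  out <- out[order(-out$dGD_T, out$unit), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
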