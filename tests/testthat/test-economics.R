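test_that("economic categories partition the positive reals at the stated thresholds", {
  expect_equal(categorize_economy(1200), "underdeveloped")
  expect_equal(categorize_economy(1500), "underdeveloped")  # boundary to poorer
  expect_equal(categorize_economy(1501), "developing")
  expect_equal(categorize_economy(15000), "developed")      # boundary to developed
  expect_equal(categorize_economy(16000), "developed")
  # total function: every positive value gets exactly one category
  grid <- c(10^seq(0, 6, by = 0.1), 1500, 15000)
  cats <- categorize_economy(grid)
  expect_true(all(cats %in% c("underdeveloped", "developing", "developed")))
  expect_equal(length(cats), length(grid))
})

test_that("contribution fractions use the printed four bins with boundaries to the lower magnitude", {
  expect_equal(bin_contribution(0.15), ">0.1")
  expect_equal(bin_contribution(0.1), "0-0.1")
  expect_equal(bin_contribution(0.0), "-0.1-0")
  expect_equal(bin_contribution(-0.05), "-0.1-0")
  expect_equal(bin_contribution(-0.1), "-0.1-0")
  expect_equal(bin_contribution(-0.2), "<-0.1")
})

test_that("method averaging merges tables and paired t-tests follow the closed form", {
  co <- data.frame(unit = c("a", "b", "c", "d"),
                   dGD_WS = c(1, 2, 3, 4), dGD_BS = c(0, 1, 0, 1),
                   dGD_T = c(1, 3, 3, 5))
  al <- co
  al$dGD_WS <- co$dGD_WS - c(1, -1, 0, 2)   # differences {1, -1, 0, 2}
  avg <- average_methods(co, al)
  expect_equal(avg$dGD_WS[match(c("a", "b", "c", "d"), avg$unit)],
               (co$dGD_WS + al$dGD_WS) / 2)
  tt <- paired_method_test(co$dGD_WS, al$dGD_WS)
  expect_equal(tt$t, 0.5 / (sd(c(1, -1, 0, 2)) / 2), tolerance = 1e-6)
  expect_equal(tt$df, 3)
  expect_equal(tt$p, 2 * pt(-abs(tt$t), 3), tolerance = 1e-12)
  # identical tables: zero-variance convention
  expect_warning(t0 <- paired_method_test(co$dGD_T, co$dGD_T), "zero-variance")
  expect_equal(t0$t, 0); expect_equal(t0$p, 1)
  # constant offset shifts the average by half the offset
  al2 <- co; al2$dGD_T <- co$dGD_T + 2
  avg2 <- average_methods(co, al2)
  expect_equal(avg2$dGD_T[match(co$unit, avg2$unit)], co$dGD_T + 1)
  # mismatched unit sets are an error naming the orphans
  expect_error(average_methods(co, al[-1, ]), "a")
  # rank: descending averaged dGD_T, ties by unit code
  expect_equal(avg2$unit[1], "d")
})

test_that("two-sample KS comparisons agree with exact enumeration", {
  res <- suppressWarnings(compare_groups_ks(list(g1 = c(1, 2), g2 = c(3, 4))))
  expect_equal(res$D, 1)
  expect_equal(res$p, 1 / 3)   # 2 of the 6 label splits reach D = 1
  expect_true(res$exact)
  # identical samples: no distributional difference
  res2 <- suppressWarnings(compare_groups_ks(list(a = c(1, 2, 3), b = c(1, 2, 3))))
  expect_equal(res2$D, 0)
  expect_error(compare_groups_ks(list(a = 1, b = c(1, 2))), "at least 2")
  set.seed(81)
  for (k in 1:6) {
    x <- rnorm(sample(3:8, 1))
    y <- rnorm(sample(3:8, 1)) + runif(1, -1, 1)
    got <- suppressWarnings(compare_groups_ks(list(x = x, y = y)))
    ref <- enum_ks(x, y)
    expect_equal(got$D, ref$D, tolerance = 1e-12)
    expect_equal(got$p, ref$p, tolerance = 1e-9)
  }
})

test_that("OLS matches the textbook closed forms on a 3-point dataset", {
  x <- c(1, 2, 4); y <- c(2, 3, 9)
  fit <- ols_fit(x, y)
  sxx <- sum((x - mean(x))^2); sxy <- sum((x - mean(x)) * (y - mean(y)))
  b <- sxy / sxx; a <- mean(y) - b * mean(x)
  expect_equal(fit$slope, b, tolerance = 1e-12)
  expect_equal(fit$intercept, a, tolerance = 1e-12)
  r2 <- 1 - sum((y - a - b * x)^2) / sum((y - mean(y))^2)
  expect_equal(fit$r_squared, r2, tolerance = 1e-12)
  expect_equal(fit$df, 1)
  # noiseless line
  fit2 <- suppressWarnings(ols_fit(1:5, 2 * (1:5)))
  expect_equal(fit2$slope, 2, tolerance = 1e-12)
  expect_equal(fit2$r_squared, 1, tolerance = 1e-12)
  expect_error(ols_fit(c(1, 1, 1), c(1, 2, 3)), "zero predictor variance")
  expect_error(ols_fit(c(1, 2), c(1, 2)), "at least 3")
  dual <- regress_diversity_on_economy(c(1, 2, 3, 5), c(2, 4, 7, 9))
  expect_equal(dual$r_squared, cor(c(1, 2, 3, 5), c(2, 4, 7, 9))^2,
               tolerance = 1e-12)
  expect_equal(dual$diversity_on_economy$r_squared,
               dual$economy_on_diversity$r_squared, tolerance = 1e-12)
})

test_that("region economy summary validates the 21-year window", {
  eco <- generate_region_economy(c("x", "y"), base = c(1000, 20000),
                                 growth = 500, seed = 82)
  s <- region_economy_summary(eco)
  expect_equal(s$category, c("underdeveloped", "developed"))
  expect_error(region_economy_summary(eco[eco$year > 1994, ]), "21 annual")
})

test_that("priority report ranks, marks the core set and flags at-risk breeds", {
  rec <- data.frame(unit = c("b1", "b2", "b3"),
                    dGD_WS = c(0.1, -0.2, 0.1), dGD_BS = c(0.1, 0.1, -0.3),
                    dGD_T = c(0.2, -0.1, -0.2))
  bs <- data.frame(breed = c("b1", "b2", "b3"), n_individuals = 10,
                   H_O = 0.3, H_E = 0.3, F_IS = 0,
                   Ne_hat = c(50, 500, 150), Ne_bin = bin_ne(c(50, 500, 150)))
  roh <- data.frame(breed = c("b1", "b2", "b3"), N_ROH = 1, L_ROH_mb = 1,
                    F_ROH = c(0.01, 0.12, 0.02))
  rep <- build_priority_report(rec, bs, roh)
  expect_equal(rep$unit, c("b1", "b2", "b3"))  # descending dGD_T
  expect_equal(rep$core_set, c(TRUE, FALSE, FALSE))
  expect_equal(rep$at_risk, c(TRUE, TRUE, FALSE))  # Ne <= 100; F_ROH >= 0.10
  expect_error(build_priority_report(rec, bs[-1, ], roh), "b1")
  # equal contributions: rank tie broken by breed code
  rec2 <- rec; rec2$dGD_T <- c(0.2, 0.2, 0.2)
  rep2 <- build_priority_report(rec2, bs, roh)
  expect_equal(rep2$unit, c("b1", "b2", "b3"))
})
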