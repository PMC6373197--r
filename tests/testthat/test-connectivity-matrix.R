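test_that("Pearson r matches direct covariance-formula evaluation", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, x), 1, tolerance = 1e-12)
  r <- pearson_r(x, c(2, 4, 5, 4))
  expect_equal(r, oracle_pearson(x, c(2, 4, 5, 4)), tolerance = 1e-12)
  expect_equal(r, 0.7182, tolerance = 1e-4)

  # constant vector: undefined with an explicit reason
  rr <- pearson_r(c(1, 2, 3), c(5, 5, 5))
  expect_true(is.na(rr))
  expect_equal(attr(rr, "reason"), "zero variance")
  expect_error(pearson_r(1, 1), "equal length|complete pairs")
  expect_error(pearson_r(c(1, NA), c(2, 3)), "complete pairs")
})

test_that("correlation p-values follow the t transform", {
  expect_equal(correlation_pvalue(0, 10), 1)
  p <- correlation_pvalue(0.5, 8)
  expect_equal(p, 0.207, tolerance = 1e-3)
  expect_equal(p, oracle_cor_pvalue(0.5, 8), tolerance = 1e-10)
  expect_lt(correlation_pvalue(0.99, 8), 0.001)
  expect_equal(p_stars(correlation_pvalue(0.99, 8)), "***")

  collinear <- correlation_pvalue(1, 5)
  expect_equal(as.numeric(collinear), 0)
  expect_true(attr(collinear, "collinear"))
  expect_error(correlation_pvalue(0.5, 2), "n_pairs")
})

test_that("group matrices cover 120 pairs with the minimum-pair rule", {
  # 3 animals, all regions present: every pair rests on 3 pairs -> excluded
  set.seed(1)
  mat <- matrix(rnorm(3 * 16, 100, 10), 3, 16)
  tab <- make_matrix_table(mat, rep("recall", 3))
  cm <- group_correlation_matrix(tab, "recall")
  expect_equal(nrow(cm), 120)
  expect_true(all(cm$excluded))
  expect_true(all(cm$n_pairs == 3))
  expect_true(all(grepl("fewer than 4 pairs", cm$reason)))

  # regions measured in disjoint animal subsets: n_pairs = 0, excluded
  mat <- matrix(rnorm(6 * 16, 100, 10), 6, 16)
  mat[1:3, 1] <- NA  # ACC only in animals 4-6
  mat[4:6, 2] <- NA  # PL only in animals 1-3
  cm <- group_correlation_matrix(make_matrix_table(mat, rep("recall", 6)),
                                 "recall")
  row <- cm[cm$region_a == "ACC" & cm$region_b == "PL", ]
  expect_equal(row$n_pairs, 0)
  expect_true(row$excluded)

  # zero-variance region: explicit reason, no NaN propagation
  mat <- matrix(rnorm(6 * 16, 100, 10), 6, 16)
  mat[, 3] <- 42
  cm <- group_correlation_matrix(make_matrix_table(mat, rep("recall", 6)),
                                 "recall")
  il <- cm[cm$region_a == "IL" | cm$region_b == "IL", ]
  expect_true(all(il$excluded))
  expect_true(all(il$reason == "zero variance"))
  expect_false(any(is.nan(cm$r)))

  expect_error(group_correlation_matrix(tab, "extinction"), "not present")
})

test_that("square-matrix view is symmetric with implicit unit diagonal", {
  cohort <- simulate_cohort(simulation_config(n_per_group = 8, seed = 13))
  cm <- group_correlation_matrix(aggregate_densities(cohort), "extinction")
  M <- as_square_matrix(cm, "r")
  expect_identical(M, t(M))
  expect_equal(unname(diag(M)), rep(1, 16))
  N <- as_square_matrix(cm, "n_pairs")
  expect_identical(N, t(N))
})

test_that("pairwise-complete deletion only uses each pair's animals", {
  set.seed(23)
  mat <- matrix(rnorm(8 * 16, 100, 10), 8, 16)
  mat[1, 1] <- NA # animal A01 misses ACC
  tab_full <- make_matrix_table(mat, rep("recall", 8))
  tab_drop <- make_matrix_table(mat[-1, ], rep("recall", 7))
  cm_full <- group_correlation_matrix(tab_full, "recall")
  cm_drop <- group_correlation_matrix(tab_drop, "recall")
  acc_full <- cm_full[cm_full$region_a == "ACC", ]
  acc_drop <- cm_drop[cm_drop$region_a == "ACC", ]
  # ACC correlations never saw A01, so dropping it changes nothing
  expect_equal(acc_full$r, acc_drop$r, tolerance = 1e-12)
  expect_equal(acc_full$n_pairs, acc_drop$n_pairs)
  # non-ACC pairs lose exactly A01's contribution
  other <- cm_full$region_a != "ACC" & cm_full$region_b != "ACC"
  expect_true(all(cm_full$n_pairs[other] - cm_drop$n_pairs[other] == 1))
})

test_that("planted correlation is recovered through the matrix stage", {
  # low measurement noise so the planted log-scale correlation is only
  # mildly attenuated on the observed density scale
  cfg <- simulation_config(
    n_per_group = c(2, 2, 50, 2), missing_rate = 0, noise_cv = 0.1,
    correlation = list(home_cage = factor_correlation(),
                       context_only = factor_correlation(),
                       recall = factor_correlation(c(vCA1 = 1, vCA3 = 0.9)),
                       extinction = factor_correlation()),
    seed = 55
  )
  tab <- aggregate_densities(simulate_cohort(cfg))
  cm <- group_correlation_matrix(tab, "recall")
  row <- cm[cm$region_a == "vCA3" & cm$region_b == "vCA1", ]
  expect_equal(row$n_pairs, 50)
  expect_lt(abs(row$r - 0.9), 0.1)
  expect_lt(row$p, 0.001)
})

test_that("matrix implementation agrees with brute force on random vectors", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(4:10, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    r <- pearson_r(x, y)
    expect_equal(r, oracle_pearson(x, y), tolerance = 1e-10)
    expect_equal(correlation_pvalue(r, n), oracle_cor_pvalue(r, n),
                 tolerance = 1e-10)
  }
})

test_that("p-values are uniform under planted independence", {
  # 2000 independent pairs at n = 8: KS-style check must not reject at 1%
  set.seed(4242)
  p <- replicate(2000, {
    x <- rnorm(8)
    y <- rnorm(8)
    correlation_pvalue(pearson_r(x, y), 8)
  })
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("exports round-trip and flag exclusions", {
  cohort <- simulate_cohort(simulation_config(n_per_group = 6, seed = 71))
  cm <- group_correlation_matrix(aggregate_densities(cohort), "recall")
  path <- tempfile(fileext = ".tsv")
  sq <- tempfile(fileext = ".csv")
  write_correlation_matrix(cm, path, sq)
  back <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(back), 120)
  M <- as.matrix(utils::read.csv(sq, row.names = 1))
  expect_equal(unname(M["vCA1", "vCA3"]),
               cm$r[cm$region_a == "vCA3" & cm$region_b == "vCA1"],
               tolerance = 1e-6)
})
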