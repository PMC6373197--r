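test_that("region panel and groups are fixed", {
  reg <- brain_regions()
  expect_equal(nrow(reg), 16)
  expect_false(any(duplicated(reg$region)))
  expect_setequal(unique(reg$division),
                  c("cortex", "thalamus", "amygdala", "hippocampus"))
  expect_equal(length(fos_groups()), 4)
  expect_equal(baseline_group(), "home_cage")
  expect_error(region_division("acc"), "unknown region")
})

test_that("identical seed gives bit-identical cohorts", {
  cfg <- simulation_config(n_per_group = 4, seed = 123)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  attr(a, "ground_truth") <- NULL
  attr(b, "ground_truth") <- NULL
  expect_identical(a, b)
})

test_that("per-animal substreams are stable when other groups grow", {
  small <- simulate_cohort(simulation_config(n_per_group = c(3, 3, 3, 3),
                                             seed = 7))
  big <- simulate_cohort(simulation_config(n_per_group = c(3, 8, 3, 3),
                                           seed = 7))
  pick <- function(df, id) {
    s <- df[df$animal_id == id, ]
    rownames(s) <- NULL
    attr(s, "ground_truth") <- NULL
    s
  }
  for (id in unique(small$animal_id)) {
    expect_identical(pick(small, id), pick(big, id), label = id)
  }
})

test_that("emitted records respect the observation model", {
  cfg <- simulation_config(n_per_group = 5, seed = 11,
                           sections_range = c(2, 6))
  cohort <- simulate_cohort(cfg)
  expect_true(all(cohort$cfos_count >= 0))
  expect_true(all(cohort$cfos_count == round(cohort$cfos_count)))
  expect_true(all(cohort$area_mm2 > 0.5 & cohort$area_mm2 < 2.5))
  nsec <- tapply(cohort$section_index,
                 paste(cohort$animal_id, cohort$region), max)
  expect_true(all(nsec >= 2 & nsec <= 6))
  # every animal carries one group label and groups have the planted sizes
  expect_equal(unname(table(unique(cohort[c("animal_id", "group")])$group)),
               rep(5L, 4), ignore_attr = TRUE)
})

test_that("invalid configurations are rejected with diagnostics", {
  bad <- fosconnect:::default_correlations()
  # hub with mutually independent spokes at r = 0.9 is not PSD
  R <- diag(16)
  dimnames(R) <- list(region_codes(), region_codes())
  R["NRe", c("ACC", "PL", "BLA")] <- 0.9
  R[c("ACC", "PL", "BLA"), "NRe"] <- 0.9
  bad$recall <- R
  expect_error(simulation_config(correlation = bad),
               "recall.*not positive semidefinite")
  expect_error(simulation_config(missing_rate = 1), "missing_rate")
  expect_error(simulation_config(sections_range = c(0, 6)), "sections_range")
  expect_error(simulation_config(sections_range = c(6, 2)), "sections_range")
  expect_error(simulation_config(mean_density = -1), "mean_density")
})

test_that("planted means are recovered at Monte-Carlo scale", {
  fc <- matrix(1, 4, 16, dimnames = list(fos_groups(), region_codes()))
  cfg <- simulation_config(
    n_per_group = 250, missing_rate = 0, fold_change = fc,
    correlation = list(home_cage = factor_correlation(),
                       context_only = factor_correlation(),
                       recall = factor_correlation(),
                       extinction = factor_correlation()),
    seed = 202
  )
  tab <- aggregate_densities(simulate_cohort(cfg))
  target <- cfg$mean_density
  for (g in fos_groups()) {
    rows <- tab$design$animal_id[tab$design$group == g]
    m <- colMeans(tab$entries[rows, ])
    se <- apply(tab$entries[rows, ], 2, stats::sd) / sqrt(length(rows))
    z <- abs(m - target) / se
    # 16 regions x 4 groups of 3-sigma checks: allow the expected rare
    # fluctuation past 3 SE, but nothing past 4 SE
    expect_lte(sum(z > 3), 1, label = paste("group", g, "mean recovery"))
    expect_true(all(z < 4), label = paste("group", g, "mean recovery 4se"))
  }
})

test_that("planted correlations are recovered from simulated densities", {
  R <- factor_correlation(c(vCA1 = 1, vCA3 = 0.95))
  cfg <- simulation_config(
    n_per_group = c(2, 2, 50, 2), missing_rate = 0,
    correlation = list(home_cage = factor_correlation(),
                       context_only = factor_correlation(),
                       recall = R, extinction = factor_correlation()),
    seed = 31
  )
  cohort <- simulate_cohort(cfg)
  latent <- attr(cohort, "ground_truth")$latent_density
  rc <- grep("^RC_", rownames(latent))
  expect_gt(stats::cor(log(latent[rc, "vCA1"]), log(latent[rc, "vCA3"])), 0.8)
  expect_gt(stats::cor(latent[rc, "vCA1"], latent[rc, "vCA3"]), 0.8)

  # observed (noisy, aggregated) densities at n = 200: planted r within 0.1
  cfg2 <- simulation_config(
    n_per_group = c(2, 2, 200, 2), missing_rate = 0, noise_cv = 0.1,
    correlation = list(home_cage = factor_correlation(),
                       context_only = factor_correlation(),
                       recall = factor_correlation(c(vCA1 = 1, vCA3 = 0.9)),
                       extinction = factor_correlation()),
    seed = 32
  )
  tab <- aggregate_densities(simulate_cohort(cfg2))
  rc <- tab$design$animal_id[tab$design$group == "recall"]
  r_obs <- stats::cor(tab$entries[rc, "vCA1"], tab$entries[rc, "vCA3"])
  expect_lt(abs(r_obs - 0.9), 0.1)
})

test_that("missingness is close to the configured rate", {
  cfg <- simulation_config(n_per_group = 100, missing_rate = 0.2, seed = 44)
  tab <- aggregate_densities(simulate_cohort(cfg))
  frac <- mean(is.na(tab$entries))
  expect_lt(abs(frac - 0.2), 0.02)
})

test_that("ground truth round-trips through the JSON sidecar", {
  cohort <- simulate_cohort(simulation_config(n_per_group = 3, seed = 8))
  path <- tempfile(fileext = ".json")
  write_ground_truth(cohort, path)
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(gt$seed, 8)
  expect_equal(unlist(gt$mean_density),
               attr(cohort, "ground_truth")$mean_density)
  expect_equal(dim(gt$correlation$recall), c(16, 16))
  expect_error(write_ground_truth(data.frame(x = 1), tempfile()),
               "ground-truth")
})
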