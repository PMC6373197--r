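#' Single-factor inter-regional correlation structure
#'
#' Builds a valid (positive semidefinite) 16 x 16 correlation matrix from a
#' vector of factor loadings: regions with non-zero loadings co-vary through
#' one shared latent factor, `cor(a, b) = loading_a * loading_b`, all other
#' pairs are independent. This is the standard way to plant a correlated
#' module without leaving the space of valid correlation matrices.
#'
#' @param loadings Named numeric vector in `[-1, 1]`; names must be region
#'   codes. Regions not named get loading 0.
#' @return A 16 x 16 correlation matrix with region-code dimnames.
#' @examples
#' R <- factor_correlation(c(NRe = 1, PVT = 0.9, BLA = 0.9))
#' R["NRe", "PVT"]
#' @export
factor_correlation <- function(loadings = numeric()) {
  regions <- region_codes()
  lam <- stats::setNames(numeric(length(regions)), regions)
  if (length(loadings)) {
    if (is.null(names(loadings))) {
      stop("`loadings` must be a named vector of region codes", call. = FALSE)
    }
    region_division(names(loadings)) # validates the codes
    if (any(abs(loadings) > 1)) {
      stop("factor loadings must lie in [-1, 1]", call. = FALSE)
    }
    lam[names(loadings)] <- loadings
  }
  R <- tcrossprod(lam)
  diag(R) <- 1
  dimnames(R) <- list(regions, regions)
  R
}

#' Hub correlation structure
#'
#' Plants one hub region correlated `r` with each of a set of spoke regions
#' through a single latent factor (hub loading 1, spoke loadings `r`).
#' Positive semidefiniteness then forces the spokes to co-vary with each
#' other at `r^2`; a hub-and-spoke structure with mutually independent
#' spokes and hub-spoke correlation 0.9 is not a valid correlation matrix.
#'
#' @param hub Region code of the hub.
#' @param spokes Character vector of spoke region codes.
#' @param r Hub-spoke correlation in `[0, 1]`.
#' @return A 16 x 16 correlation matrix.
#' @export
hub_correlation <- function(hub, spokes, r = 0.9) {
  if (hub %in% spokes) stop("`hub` must not be among `spokes`", call. = FALSE)
  factor_correlation(stats::setNames(c(1, rep(r, length(spokes))),
                                     c(hub, spokes)))
}

default_mean_density <- function() {
  # Baseline (home-cage) cFos+ densities in cells/mm^2; order-of-magnitude
  # values typical of mouse forebrain IHC, higher in cortex than amygdala.
  d <- brain_regions()
  stats::setNames(
    c(cortex = 150, thalamus = 100, amygdala = 60, hippocampus = 120)[d$division],
    d$region
  )
}

default_fold_changes <- function() {
  regions <- region_codes()
  groups <- fos_groups()
  fc <- matrix(1, nrow = length(groups), ncol = length(regions),
               dimnames = list(groups, regions))
  # Emulates the observed activation pattern: familiar-context recruitment of
  # PL/IL/PVT; broad cortical/thalamic/amygdalar/ventral-hippocampal
  # recruitment at remote recall; similar but CEA- and ACC-sparing pattern
  # after extinction; dorsal CA fields silent throughout.
  fc["context_only", c("PL", "IL", "PVT")] <- 1.8
  fc["recall", c("ACC", "PL", "IL", "RSP", "PVT", "NRe", "CEA", "BLA",
                 "dDG", "vCA3", "vCA1")] <-
    c(1.8, 3.0, 2.0, 1.8, 2.0, 2.5, 1.8, 2.2, 1.5, 2.0, 2.0)
  fc["extinction", c("PL", "IL", "RSP", "PVT", "NRe", "BLA",
                     "dDG", "vCA3", "vCA1")] <-
    c(2.5, 2.0, 1.8, 2.0, 2.5, 2.0, 1.5, 2.0, 2.0)
  fc
}

default_correlations <- function() {
  # Control groups: independent regions. Recall: a midline-thalamus-centred
  # module spanning cortex, amygdala and both hippocampal poles. Extinction:
  # a similar module that additionally couples the ventral hippocampus with
  # the medial prefrontal cortex.
  list(
    home_cage = factor_correlation(),
    context_only = factor_correlation(),
    recall = factor_correlation(c(
      NRe = 0.9, PVT = 0.8, BLA = 0.8, ACC = 0.7, dCA1 = 0.7,
      dDG = 0.7, vCA3 = 0.7
    )),
    extinction = factor_correlation(c(
      NRe = 0.9, PVT = 0.8, BLA = 0.8, PL = 0.7, IL = 0.7,
      vCA1 = 0.7, vCA3 = 0.7
    ))
  )
}

check_correlation_matrix <- function(R, label) {
  regions <- region_codes()
  if (!is.matrix(R) || !all(dim(R) == 16L)) {
    stop(sprintf("correlation matrix `%s` must be 16 x 16", label),
         call. = FALSE)
  }
  if (is.null(dimnames(R))) dimnames(R) <- list(regions, regions)
  if (!identical(rownames(R), regions) || !identical(colnames(R), regions)) {
    stop(sprintf("correlation matrix `%s` must have region-code dimnames in canonical order", label),
         call. = FALSE)
  }
  if (max(abs(R - t(R))) > 1e-8) {
    stop(sprintf("correlation matrix `%s` is not symmetric", label),
         call. = FALSE)
  }
  if (max(abs(diag(R) - 1)) > 1e-8) {
    stop(sprintf("correlation matrix `%s` must have unit diagonal", label),
         call. = FALSE)
  }
  if (any(R < -1 - 1e-12) || any(R > 1 + 1e-12)) {
    stop(sprintf("correlation matrix `%s` has entries outside [-1, 1]", label),
         call. = FALSE)
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop(sprintf(
      "correlation matrix `%s` is not positive semidefinite (min eigenvalue %.3g)",
      label, min(ev)), call. = FALSE)
  }
  R
}

#' Simulation configuration for a synthetic cFos cohort
#'
#' Assembles and validates the parameters of the synthetic cohort generator.
#' The generator emulates the data structure of a four-group contextual fear
#' study: per-animal latent regional densities drawn from a log-scale
#' multivariate normal (Gaussian copula) with planted group means and
#' inter-regional correlations, observed through 2-6 histological sections
#' per animal and region with multiplicative measurement noise, and with
#' completely-at-random missing animal x region entries.
#'
#' @param n_per_group Animals per group: a single integer or a vector of
#'   four (named by group or in `fos_groups()` order). Default 7, within
#'   the study's 5-8 range.
#' @param mean_density Baseline (home-cage) mean density per region,
#'   cells/mm^2, strictly positive; a scalar or named 16-vector.
#' @param fold_change True group x region multipliers over baseline
#'   (`>= 0`); a 4 x 16 matrix with group/region dimnames.
#' @param correlation Named list of four 16 x 16 group-specific correlation
#'   matrices (symmetric, unit diagonal, positive semidefinite) for the
#'   latent log-densities.
#' @param animal_cv Between-animal coefficient of variation of the latent
#'   regional density (`>= 0`), default 0.3.
#' @param noise_cv Coefficient of variation of per-section multiplicative
#'   measurement noise (`>= 0`), default 0.2.
#' @param sections_range Inclusive integer interval for the number of
#'   sections per animal x region, within `[1, 10]`; default `c(2, 6)`.
#' @param missing_rate Probability that an animal x region entry is absent
#'   entirely, in `[0, 1)`; default 0.1.
#' @param seed Master integer seed; per-animal substreams are derived from
#'   it so that adding animals never perturbs earlier ones.
#' @return A validated list of class `"simulation_config"`.
#' @seealso [simulate_cohort()]
#' @export
simulation_config <- function(n_per_group = 7L,
                              mean_density = default_mean_density(),
                              fold_change = default_fold_changes(),
                              correlation = default_correlations(),
                              animal_cv = 0.3,
                              noise_cv = 0.2,
                              sections_range = c(2L, 6L),
                              missing_rate = 0.1,
                              seed = 1L) {
  groups <- fos_groups()
  regions <- region_codes()

  if (length(n_per_group) == 1L) {
    n_per_group <- stats::setNames(rep(as.integer(n_per_group), 4L), groups)
  } else if (length(n_per_group) == 4L) {
    n_per_group <- as.integer(n_per_group)
    names(n_per_group) <- names(n_per_group) %||% groups
    n_per_group <- n_per_group[groups]
  } else {
    stop("`n_per_group` must have length 1 or 4", call. = FALSE)
  }
  if (anyNA(n_per_group) || any(n_per_group < 1L)) {
    stop("`n_per_group` must be positive integers for all four groups",
         call. = FALSE)
  }

  if (length(mean_density) == 1L) {
    mean_density <- stats::setNames(rep(mean_density, 16L), regions)
  }
  if (length(mean_density) != 16L || is.null(names(mean_density))) {
    stop("`mean_density` must be a scalar or a named 16-vector", call. = FALSE)
  }
  mean_density <- mean_density[regions]
  if (anyNA(mean_density) || any(mean_density <= 0)) {
    stop("`mean_density` must be > 0 for all 16 regions", call. = FALSE)
  }

  if (!is.matrix(fold_change) || !all(dim(fold_change) == c(4L, 16L))) {
    stop("`fold_change` must be a 4 x 16 group-by-region matrix",
         call. = FALSE)
  }
  fold_change <- fold_change[groups, regions, drop = FALSE]
  if (anyNA(fold_change) || any(fold_change < 0)) {
    stop("`fold_change` entries must be >= 0", call. = FALSE)
  }

  if (!is.list(correlation) || !setequal(names(correlation), groups)) {
    stop("`correlation` must be a list of four matrices named by group",
         call. = FALSE)
  }
  correlation <- correlation[groups]
  for (g in groups) check_correlation_matrix(correlation[[g]], g)

  stopifnot_scalar_number(animal_cv, "animal_cv", lower = 0)
  stopifnot_scalar_number(noise_cv, "noise_cv", lower = 0)

  sections_range <- as.integer(sections_range)
  if (length(sections_range) != 2L || anyNA(sections_range) ||
      sections_range[1] > sections_range[2] ||
      sections_range[1] < 1L || sections_range[2] > 10L) {
    stop("`sections_range` must be an integer interval [low, high] within [1, 10]",
         call. = FALSE)
  }

  stopifnot_scalar_number(missing_rate, "missing_rate", lower = 0)
  if (missing_rate >= 1) {
    stop("`missing_rate` must be < 1: a rate of 1 would drop every entry",
         call. = FALSE)
  }
  stopifnot_scalar_number(seed, "seed")

  structure(
    list(
      n_per_group = n_per_group,
      mean_density = mean_density,
      fold_change = fold_change,
      correlation = correlation,
      animal_cv = animal_cv,
      noise_cv = noise_cv,
      sections_range = sections_range,
      missing_rate = missing_rate,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

group_prefix <- c(home_cage = "HC", context_only = "CO",
                  recall = "RC", extinction = "EX")

#' Simulate a synthetic cFos cohort
#'
#' Generates per-section cFos quantification records for a four-group cohort
#' with known ground truth. For each animal, latent regional densities are
#' drawn from a multivariate log-normal: `log(density)` is multivariate
#' normal with the group's planted correlation matrix, and marginal means
#' equal to `mean_density * fold_change` (the log-normal mean correction is
#' applied, so planted means are recovered exactly in expectation). Each
#' retained animal x region entry is observed through a uniform number of
#' sections in `sections_range`; each section has an area drawn uniformly
#' from 0.5-2.5 mm^2 and a count `round(latent density * area * noise)`
#' with log-normal multiplicative noise of CV `noise_cv`. Entries are
#' dropped completely at random with probability `missing_rate`.
#'
#' Planted correlations act on the log scale and attenuate slightly on the
#' raw density scale and under measurement noise.
#'
#' Each animal consumes an independent substream seeded from the master
#' seed, so the same animal's records are bit-identical regardless of how
#' many other animals are simulated.
#'
#' @param config A [simulation_config()] object (or arguments to build one,
#'   passed as a list).
#' @return A data frame of section records with columns `animal_id`,
#'   `group`, `region`, `section_index`, `cfos_count`, `area_mm2`, carrying
#'   the ground truth (config, planted means, fold changes, correlations,
#'   per-animal latent densities) in attribute `"ground_truth"`.
#' @examples
#' cfg <- simulation_config(n_per_group = 3, seed = 42)
#' head(simulate_cohort(cfg))
#' @export
simulate_cohort <- function(config = simulation_config()) {
  if (is.list(config) && !inherits(config, "simulation_config")) {
    config <- do.call(simulation_config, config)
  }
  stopifnot(inherits(config, "simulation_config"))
  groups <- fos_groups()
  regions <- region_codes()
  n_regions <- length(regions)

  sigma_a <- sqrt(log(1 + config$animal_cv^2))
  sigma_e <- sqrt(log(1 + config$noise_cv^2))

  # Upper-triangular Cholesky factors; PSD-but-singular matrices get a tiny
  # diagonal ridge for factorisation only (planted structure is unchanged
  # beyond numerical precision).
  chol_by_group <- lapply(config$correlation, function(R) {
    ch <- tryCatch(chol(R), error = function(e) NULL)
    if (is.null(ch)) ch <- chol(R + diag(1e-10, n_regions))
    ch
  })

  records <- vector("list", sum(config$n_per_group))
  latents <- vector("list", sum(config$n_per_group))
  k <- 0L
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    mu <- config$mean_density * config$fold_change[g, ]
    for (ai in seq_len(config$n_per_group[[g]])) {
      k <- k + 1L
      animal_id <- sprintf("%s_%02d", group_prefix[[g]], ai)
      rec <- with_local_seed(
        substream_seed(config$seed, gi, ai),
        simulate_animal(animal_id, g, mu, chol_by_group[[g]],
                        sigma_a, sigma_e, config)
      )
      records[[k]] <- rec$sections
      latents[[k]] <- rec$latent
    }
  }
  out <- data.frame(
    animal_id = unlist(lapply(records, `[[`, "animal_id"),
                       use.names = FALSE),
    group = unlist(lapply(records, `[[`, "group"), use.names = FALSE),
    region = unlist(lapply(records, `[[`, "region"), use.names = FALSE),
    section_index = unlist(lapply(records, `[[`, "section_index"),
                           use.names = FALSE),
    cfos_count = unlist(lapply(records, `[[`, "cfos_count"),
                        use.names = FALSE),
    area_mm2 = unlist(lapply(records, `[[`, "area_mm2"), use.names = FALSE),
    stringsAsFactors = FALSE
  )
  latent_mat <- do.call(rbind, latents)

  attr(out, "ground_truth") <- list(
    config = config,
    mean_density = config$mean_density,
    fold_change = config$fold_change,
    correlation = config$correlation,
    latent_density = latent_mat
  )
  out
}

# One animal under an already-seeded RNG stream. Draw order is fixed:
# latent MVN, missingness mask, then per-region section counts/areas/noise.
simulate_animal <- function(animal_id, group, mu, chol_R,
                            sigma_a, sigma_e, config) {
  regions <- region_codes()
  n_regions <- length(regions)

  z <- drop(rnorm(n_regions) %*% chol_R)
  # E[exp(sigma*z - sigma^2/2)] = 1, so E[latent] = mu exactly.
  latent <- mu * exp(sigma_a * z - sigma_a^2 / 2)
  latent[mu == 0] <- 0

  keep <- runif(n_regions) >= config$missing_rate
  lo <- config$sections_range[1]
  hi <- config$sections_range[2]

  region_v <- character(0)
  section_v <- integer(0)
  count_v <- integer(0)
  area_v <- numeric(0)
  for (ri in seq_len(n_regions)) {
    n_sec <- if (lo == hi) lo else sample(lo:hi, 1L)
    area <- runif(n_sec, 0.5, 2.5)
    noise <- if (sigma_e > 0) {
      exp(sigma_e * rnorm(n_sec) - sigma_e^2 / 2)
    } else {
      rep(1, n_sec)
    }
    if (!keep[ri]) next # draws above keep substreams aligned across masks
    region_v <- c(region_v, rep(regions[ri], n_sec))
    section_v <- c(section_v, seq_len(n_sec))
    count_v <- c(count_v, as.integer(round(latent[ri] * area * noise)))
    area_v <- c(area_v, area)
  }
  latent_row <- matrix(latent, nrow = 1,
                       dimnames = list(animal_id, regions))
  list(
    sections = list(
      animal_id = rep(animal_id, length(region_v)),
      group = rep(group, length(region_v)),
      region = region_v,
      section_index = section_v,
      cfos_count = count_v,
      area_mm2 = area_v
    ),
    latent = latent_row
  )
}

#' Write simulation ground truth as JSON
#'
#' Serialises the planted parameters of a simulated cohort (means, fold
#' changes, correlation matrices, seed and the per-animal latent densities)
#' so recovery analyses can run from files alone.
#'
#' @param cohort A data frame returned by [simulate_cohort()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(cohort, path) {
  gt <- attr(cohort, "ground_truth")
  if (is.null(gt)) {
    stop("`cohort` carries no ground-truth attribute; was it produced by simulate_cohort()?",
         call. = FALSE)
  }
  payload <- list(
    seed = gt$config$seed,
    n_per_group = as.list(gt$config$n_per_group),
    animal_cv = gt$config$animal_cv,
    noise_cv = gt$config$noise_cv,
    sections_range = gt$config$sections_range,
    missing_rate = gt$config$missing_rate,
    mean_density = as.list(gt$mean_density),
    fold_change = gt$fold_change,
    correlation = gt$correlation,
    latent_density = gt$latent_density
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}
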