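#' One-way ANOVA of regional cFos density across groups
#'
#' Classical fixed-effects one-way ANOVA of the non-missing per-animal
#' densities of one region across the experimental groups:
#' `F = (SSB / df_between) / (SSW / df_within)`, with the p-value from the
#' upper tail of the F distribution. Groups contribute whatever animals
#' have the region measured (complete-case within region); `df_between` is
#' the number of contributing groups minus one.
#'
#' A table whose observations are all identical (zero total variance) is a
#' degenerate test: it is flagged and reported with `F = 0`, `p = 1`.
#'
#' @param table A `density_table`.
#' @param region Region code.
#' @return A list of class `"anova_result"`: `region`, `F`, `df_between`,
#'   `df_within`, `p`, `group_means` (named), `group_n` (named),
#'   `degenerate` (logical).
#' @examples
#' cohort <- simulate_cohort(simulation_config(n_per_group = 6, seed = 3))
#' one_way_anova(aggregate_densities(cohort), "PL")
#' @export
one_way_anova <- function(table, region) {
  dat <- region_densities(table, region)
  counts <- table(dat$group)
  if (sum(counts >= 2) < 2) {
    stop(sprintf(
      "region %s: need at least 2 groups with >= 2 observations (have %s)",
      region, paste(sprintf("%s:%d", names(counts), counts), collapse = ", ")),
      call. = FALSE)
  }
  g <- factor(dat$group)
  group_means <- tapply(dat$density, g, mean)
  group_n <- as.integer(table(g))
  names(group_n) <- levels(g)

  df_between <- nlevels(g) - 1L
  df_within <- nrow(dat) - nlevels(g)

  if (stats::var(dat$density) == 0) {
    return(structure(
      list(region = region, F = 0, df_between = df_between,
           df_within = df_within, p = 1,
           group_means = group_means, group_n = group_n, degenerate = TRUE),
      class = "anova_result"))
  }

  fit <- stats::anova(stats::lm(density ~ g, data = dat))
  structure(
    list(
      region = region,
      F = fit[["F value"]][1],
      df_between = fit[["Df"]][1],
      df_within = fit[["Df"]][2],
      p = fit[["Pr(>F)"]][1],
      group_means = group_means,
      group_n = group_n,
      degenerate = FALSE
    ),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("%s: F(%d, %d) = %.3g, p = %.4g%s\n", x$region,
              x$df_between, x$df_within, x$F, x$p,
              if (x$degenerate) " [degenerate: zero variance]" else ""))
  invisible(x)
}

#' ANOVA table over all regions
#'
#' Runs [one_way_anova()] for every region with enough data; regions
#' failing the precondition are reported as `NA` rows with a message.
#'
#' @param table A `density_table`.
#' @return Data frame, one row per region: `region`, `F`, `df_between`,
#'   `df_within`, `p`, `degenerate`, plus per-group mean and n columns.
#' @export
anova_all_regions <- function(table) {
  groups <- fos_groups()
  rows <- lapply(region_codes(), function(reg) {
    res <- tryCatch(one_way_anova(table, reg), error = function(e) {
      message("skipping ANOVA for ", reg, ": ", conditionMessage(e))
      NULL
    })
    base <- data.frame(region = reg, F = NA_real_, df_between = NA_integer_,
                       df_within = NA_integer_, p = NA_real_,
                       degenerate = NA, stringsAsFactors = FALSE)
    means <- stats::setNames(rep(NA_real_, length(groups)),
                             paste0("mean_", groups))
    ns <- stats::setNames(rep(NA_integer_, length(groups)),
                          paste0("n_", groups))
    if (!is.null(res)) {
      base$F <- res$F
      base$df_between <- res$df_between
      base$df_within <- res$df_within
      base$p <- res$p
      base$degenerate <- res$degenerate
      means[paste0("mean_", names(res$group_means))] <- res$group_means
      ns[paste0("n_", names(res$group_n))] <- res$group_n
    }
    cbind(base, as.data.frame(as.list(means)), as.data.frame(as.list(ns)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sidak multiplicity adjustment
#'
#' Single-step Sidak correction for a family of `m` comparisons:
#' `p' = min(1, 1 - (1 - p)^m)`. Controls the family-wise error rate
#' exactly under independence and conservatively under positive dependence.
#'
#' @param p_raw Numeric vector of raw p-values in `[0, 1]`.
#' @param m Family size, integer `>= 1`.
#' @return Adjusted p-values, same length as `p_raw`.
#' @examples
#' sidak_adjust(0.01, 3) # 1 - 0.99^3 = 0.029701
#' @export
sidak_adjust <- function(p_raw, m) {
  stopifnot_scalar_number(m, "m", lower = 1)
  if (m != round(m)) stop("`m` must be an integer >= 1", call. = FALSE)
  if (any(is.na(p_raw)) || any(p_raw < 0 | p_raw > 1)) {
    stop("`p_raw` must lie in [0, 1]", call. = FALSE)
  }
  pmin(1, 1 - (1 - p_raw)^m)
}

#' Holm-Sidak step-down multiplicity adjustment
#'
#' Step-down variant of the Sidak correction: raw p-values are sorted
#' ascending, the i-th smallest is adjusted with the shrinking family size
#' `m - i + 1` as `1 - (1 - p_(i))^(m - i + 1)`, monotonicity is enforced
#' by a running maximum, values are capped at 1, and results are returned
#' in the original input order. Uniformly at least as powerful as
#' single-step Sidak.
#'
#' @param p_raw Numeric vector of raw p-values in `[0, 1]` (non-empty).
#' @return Adjusted p-values in input order.
#' @examples
#' holm_sidak_adjust(c(0.01, 0.04, 0.03))
#' @export
holm_sidak_adjust <- function(p_raw) {
  if (length(p_raw) == 0L) {
    stop("`p_raw` must contain at least one p-value", call. = FALSE)
  }
  if (any(is.na(p_raw)) || any(p_raw < 0 | p_raw > 1)) {
    stop("`p_raw` must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p_raw)
  ord <- order(p_raw)
  sorted <- p_raw[ord]
  adj <- 1 - (1 - sorted)^(m - seq_len(m) + 1)
  adj <- pmin(1, cummax(adj))
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Pairwise post-hoc comparisons for one region
#'
#' All pairwise group contrasts of one region's densities via two-sample
#' Welch t-tests, with the chosen multiplicity correction applied over the
#' family of comparisons (per region). The default follows the cFos
#' analyses' convention (single-step Sidak); the step-down Holm-Sidak
#' variant is also available.
#'
#' @param table A `density_table`.
#' @param region Region code.
#' @param method `"sidak"` (default) or `"holm_sidak"`.
#' @return Data frame of class `"posthoc_result"`: one row per comparison
#'   with `region`, `group_a`, `group_b`, `mean_diff` (a minus b), `p_raw`,
#'   `p_adjusted`, `method`, `family_size`.
#' @export
posthoc_comparisons <- function(table, region,
                                method = c("sidak", "holm_sidak")) {
  method <- match.arg(method)
  dat <- region_densities(table, region)
  counts <- table(dat$group)
  usable <- names(counts)[counts >= 2]
  if (length(usable) < 2) {
    stop(sprintf("region %s: need >= 2 groups with >= 2 observations", region),
         call. = FALSE)
  }
  usable <- intersect(fos_groups(), usable)
  pairs <- utils::combn(usable, 2)
  m <- ncol(pairs)

  rows <- lapply(seq_len(m), function(i) {
    a <- pairs[1, i]
    b <- pairs[2, i]
    xa <- dat$density[dat$group == a]
    xb <- dat$density[dat$group == b]
    p <- if (stats::var(xa) == 0 && stats::var(xb) == 0 &&
             mean(xa) == mean(xb)) {
      1 # identical constant samples: no evidence of a difference
    } else {
      stats::t.test(xa, xb)$p.value
    }
    data.frame(region = region, group_a = a, group_b = b,
               mean_diff = mean(xa) - mean(xb), p_raw = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- switch(method,
    sidak = sidak_adjust(out$p_raw, m),
    holm_sidak = holm_sidak_adjust(out$p_raw)
  )
  out$method <- method
  out$family_size <- m
  class(out) <- c("posthoc_result", "data.frame")
  out
}

#' Fold changes over the home-cage baseline
#'
#' Ratio of each group's mean regional density to the home-cage mean,
#' computed per region. `home_cage` itself is always exactly 1. A zero or
#' missing home-cage mean makes the ratio undefined; such entries are
#' flagged (`undefined = TRUE`, fold change `NA`) rather than reported as
#' infinite, and a message notes the exclusion. All 16 regions always
#' appear, so the table can size network nodes directly.
#'
#' These values are the node weights of the connectivity networks.
#'
#' @param table A `density_table`.
#' @return Data frame: `region`, `group`, `fold_change`, `undefined`,
#'   `n_group`, `n_baseline`.
#' @export
fold_changes <- function(table) {
  stopifnot(inherits(table, "density_table"))
  groups <- fos_groups()
  base <- baseline_group()
  rows <- lapply(region_codes(), function(reg) {
    dat <- region_densities(table, reg)
    base_x <- dat$density[dat$group == base]
    base_mean <- if (length(base_x)) mean(base_x) else NA_real_
    do.call(rbind, lapply(groups, function(g) {
      gx <- dat$density[dat$group == g]
      undefined <- FALSE
      fc <- if (g == base && length(base_x)) {
        1 # baseline self-ratio, exact even when the mean is 0
      } else if (length(base_x) == 0L || base_mean == 0 ||
                 length(gx) == 0L) {
        undefined <- TRUE
        NA_real_
      } else {
        mean(gx) / base_mean
      }
      data.frame(region = reg, group = g, fold_change = fc,
                 undefined = undefined, n_group = length(gx),
                 n_baseline = length(base_x), stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(out$undefined)) {
    bad <- out[out$undefined, ]
    message("fold change undefined for ",
            paste(sprintf("%s/%s", bad$region, bad$group), collapse = ", "),
            " (zero or missing baseline); excluded from node sizing")
  }
  out
}
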