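#' Pearson product-moment correlation
#'
#' Standard Pearson correlation of two density vectors after pairwise
#' deletion of entries missing in either vector. At least two complete
#' pairs are required; a zero-variance (constant) vector has no defined
#' correlation and yields `NA` with a `"reason"` attribute, never a silent
#' `NaN`.
#'
#' @param x,y Numeric vectors of equal length (NA allowed).
#' @return The correlation coefficient, or `NA` with attribute
#'   `reason = "zero variance"` when either vector is constant.
#' @examples
#' pearson_r(c(1, 2, 3, 4), c(2, 4, 5, 4))
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 2L) {
    stop("need at least 2 complete pairs, have ", length(x), call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(structure(NA_real_, reason = "zero variance"))
  }
  stats::cor(x, y)
}

#' Two-sided p-value of a Pearson correlation
#'
#' Exact test under bivariate normality: `t = r * sqrt((n - 2)/(1 - r^2))`
#' referred to the t distribution on `n - 2` degrees of freedom, two-sided.
#' Perfect correlation (`|r| = 1`) is collinear; its p is reported as 0
#' with a `"collinear"` attribute.
#'
#' @param r Correlation coefficient in `[-1, 1]` (NA propagates).
#' @param n_pairs Number of complete pairs, `>= 3`.
#' @return Two-sided p-value.
#' @examples
#' correlation_pvalue(0.5, 8)
#' @export
correlation_pvalue <- function(r, n_pairs) {
  if (is.na(r)) return(NA_real_)
  stopifnot_scalar_number(r, "r", lower = -1, upper = 1)
  stopifnot_scalar_number(n_pairs, "n_pairs", lower = 3)
  if (abs(r) == 1) {
    return(structure(0, collinear = TRUE))
  }
  df <- n_pairs - 2
  t_stat <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(abs(t_stat), df = df, lower.tail = FALSE)
}

#' Inter-regional correlation matrix of one group
#'
#' For every unordered pair of the 16 regions, computes the Pearson
#' correlation of per-animal cFos densities across the animals of one
#' group, using pairwise-complete observations (the effective `n_pairs`
#' varies per pair when entries are missing). Pairs resting on fewer than
#' four complete pairs are excluded from all downstream weight, as are
#' zero-variance pairs; exclusions carry an explicit reason. Significance
#' stars are assigned from the raw two-sided p at 0.05 / 0.01 / 0.001. A
#' Benjamini-Hochberg column over the non-excluded pairs is provided for
#' reference only; it never feeds the network edge filter.
#'
#' @param table A `density_table`.
#' @param group Group label present in the table.
#' @param min_pairs Minimum complete pairs for a pair to count (default 4).
#' @return A data frame of class `"correlation_matrix"` with 120 rows:
#'   `group`, `region_a`, `region_b` (canonical atlas order), `r`, `p`,
#'   `n_pairs`, `excluded`, `reason`, `stars`, `p_bh`.
#' @examples
#' cohort <- simulate_cohort(simulation_config(n_per_group = 8, seed = 9))
#' cm <- group_correlation_matrix(aggregate_densities(cohort), "recall")
#' head(cm)
#' @export
group_correlation_matrix <- function(table, group, min_pairs = 4L) {
  stopifnot(inherits(table, "density_table"))
  animals <- table$design$animal_id[table$design$group == group]
  if (length(animals) == 0L) {
    stop("group not present in density table: ", group, call. = FALSE)
  }
  mat <- table$entries[animals, , drop = FALSE]
  regions <- region_codes()
  pairs <- utils::combn(regions, 2)

  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]
    b <- pairs[2, i]
    x <- mat[, a]
    y <- mat[, b]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    r <- NA_real_
    p <- NA_real_
    excluded <- FALSE
    reason <- NA_character_
    if (n < min_pairs) {
      excluded <- TRUE
      reason <- sprintf("fewer than %d pairs", min_pairs)
      if (n >= 2L) {
        rr <- pearson_r(x, y)
        r <- as.numeric(rr)
      }
    } else {
      rr <- pearson_r(x, y)
      if (is.na(rr)) {
        excluded <- TRUE
        reason <- attr(rr, "reason")
      } else {
        r <- as.numeric(rr)
        p <- as.numeric(correlation_pvalue(r, n))
      }
    }
    data.frame(group = group, region_a = a, region_b = b, r = r, p = p,
               n_pairs = n, excluded = excluded, reason = reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$stars <- ifelse(out$excluded, NA_character_, p_stars(out$p))
  out$p_bh <- NA_real_
  keep <- !out$excluded & !is.na(out$p)
  out$p_bh[keep] <- stats::p.adjust(out$p[keep], method = "BH")
  class(out) <- c("correlation_matrix", "data.frame")
  attr(out, "group") <- group
  attr(out, "min_pairs") <- min_pairs
  out
}

#' Correlation matrices for every group
#'
#' @param table A `density_table`.
#' @param min_pairs Minimum complete pairs (default 4).
#' @return Named list of `correlation_matrix` objects, one per group in
#'   the table (canonical group order).
#' @export
all_correlation_matrices <- function(table, min_pairs = 4L) {
  groups <- intersect(fos_groups(), unique(table$design$group))
  stats::setNames(
    lapply(groups, function(g) group_correlation_matrix(table, g, min_pairs)),
    groups
  )
}

#' Square-matrix view of a correlation matrix
#'
#' Expands the 120-pair long form into the symmetric 16 x 16 matrix (unit
#' diagonal implicit; excluded pairs `NA`). Querying `(a, b)` and `(b, a)`
#' returns identical values by construction.
#'
#' @param cm A `correlation_matrix`.
#' @param value Which quantity to tabulate: `"r"`, `"p"` or `"n_pairs"`.
#' @return A 16 x 16 matrix with region dimnames.
#' @export
as_square_matrix <- function(cm, value = c("r", "p", "n_pairs")) {
  value <- match.arg(value)
  regions <- region_codes()
  M <- matrix(NA_real_, 16, 16, dimnames = list(regions, regions))
  v <- cm[[value]]
  if (value != "n_pairs") v[cm$excluded] <- NA_real_
  ia <- match(cm$region_a, regions)
  ib <- match(cm$region_b, regions)
  M[cbind(ia, ib)] <- v
  M[cbind(ib, ia)] <- v
  diag(M) <- switch(value, r = 1, p = NA_real_, n_pairs = NA_real_)
  M
}

#' Write a correlation matrix
#'
#' Writes the long-format pair table (TSV/CSV by extension) and, when
#' `square_path` is given, a square 16 x 16 r-matrix CSV with excluded
#' pairs empty.
#'
#' @param cm A `correlation_matrix`.
#' @param path Long-format output path.
#' @param square_path Optional square-matrix CSV path.
#' @param sep Optional delimiter for `path`.
#' @return `path`, invisibly.
#' @export
write_correlation_matrix <- function(cm, path, square_path = NULL,
                                     sep = NULL) {
  sep <- infer_sep(path, sep)
  utils::write.table(as.data.frame(cm), path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "")
  if (!is.null(square_path)) {
    utils::write.csv(as_square_matrix(cm, "r"), square_path, na = "")
  }
  invisible(path)
}

#' Render a correlation matrix heat map
#'
#' Color-coded display of the group's inter-regional correlations: a
#' blue-white-red scale over `[-1, 1]`, gray cells for excluded pairs and
#' significance stars overlaid. Writes a PNG when `file` is given,
#' otherwise draws on the active device.
#'
#' @param cm A `correlation_matrix`.
#' @param file Optional PNG path.
#' @return `file` (or `NULL`), invisibly.
#' @export
plot_correlation_matrix <- function(cm, file = NULL) {
  regions <- region_codes()
  M <- as_square_matrix(cm, "r")
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 900, res = 120)
    on.exit(grDevices::dev.off())
  }
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
  op <- graphics::par(mar = c(6, 6, 3, 1))
  on.exit(graphics::par(op), add = TRUE, after = FALSE)
  n <- length(regions)
  graphics::plot(NA, xlim = c(0.5, n + 0.5), ylim = c(0.5, n + 0.5),
                 xlab = "", ylab = "", axes = FALSE, asp = 1,
                 main = paste("Inter-regional correlations:",
                              attr(cm, "group")))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      col <- if (is.na(M[i, j])) "gray80" else pal[round((M[i, j] + 1) * 50) + 1]
      graphics::rect(j - 0.5, n - i + 0.5, j + 0.5, n - i + 1.5,
                     col = col, border = "white")
    }
  }
  ia <- match(cm$region_a, regions)
  ib <- match(cm$region_b, regions)
  lab <- ifelse(is.na(cm$stars), "", cm$stars)
  graphics::text(ib, n - ia + 1, lab, cex = 0.7)
  graphics::text(ia, n - ib + 1, lab, cex = 0.7)
  graphics::axis(1, at = seq_len(n), labels = regions, las = 2, tick = FALSE)
  graphics::axis(2, at = n:1, labels = regions, las = 1, tick = FALSE)
  invisible(file)
}
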