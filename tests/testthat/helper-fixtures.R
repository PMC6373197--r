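# In-code fixtures: density tables and correlation-pair tables built
# directly, bypassing the simulator, for unit-level checks.

# Density table with given values in one region (others missing).
make_region_table <- function(values, groups, region = "PL") {
  n <- length(values)
  animals <- sprintf("A%02d", seq_len(n))
  entries <- matrix(NA_real_, n, 16,
                    dimnames = list(animals, fosconnect::region_codes()))
  entries[, region] <- values
  n_sections <- matrix(0L, n, 16, dimnames = dimnames(entries))
  n_sections[, region] <- 3L
  structure(
    list(entries = entries, n_sections = n_sections,
         design = data.frame(animal_id = animals, group = as.character(groups),
                             stringsAsFactors = FALSE)),
    class = "density_table"
  )
}

# Density table from a full animals x 16 matrix.
make_matrix_table <- function(mat, groups) {
  stopifnot(ncol(mat) == 16)
  colnames(mat) <- fosconnect::region_codes()
  animals <- rownames(mat) %||% sprintf("A%02d", seq_len(nrow(mat)))
  rownames(mat) <- animals
  n_sections <- matrix(3L, nrow(mat), 16, dimnames = dimnames(mat))
  n_sections[is.na(mat)] <- 0L
  structure(
    list(entries = mat, n_sections = n_sections,
         design = data.frame(animal_id = animals, group = as.character(groups),
                             stringsAsFactors = FALSE)),
    class = "density_table"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# All 120 region pairs as a correlation-pair data frame with uniform
# defaults, ready for targeted overrides.
make_pair_table <- function(r = 0, p = 1, n_pairs = 6L) {
  pairs <- t(utils::combn(fosconnect::region_codes(), 2))
  data.frame(group = "recall", region_a = pairs[, 1], region_b = pairs[, 2],
             r = r, p = p, n_pairs = n_pairs, excluded = FALSE,
             stringsAsFactors = FALSE)
}

set_pair <- function(tab, a, b, ...) {
  i <- which((tab$region_a == a & tab$region_b == b) |
               (tab$region_a == b & tab$region_b == a))
  stopifnot(length(i) == 1)
  for (nm in names(list(...))) tab[i, nm] <- list(...)[[nm]]
  tab
}

# Hand-written 120-pair table spanning every edge-filter boundary case.
boundary_fixture <- function() {
  tab <- make_pair_table(r = 0, p = 1, n_pairs = 6L)
  # survivors
  tab <- set_pair(tab, "ACC", "PL", r = 0.5, p = 0.1, n_pairs = 4L)   # all boundaries inclusive
  tab <- set_pair(tab, "ACC", "IL", r = 0.6, p = 0.05, n_pairs = 6L)
  tab <- set_pair(tab, "NRe", "vCA1", r = 0.95, p = 0.001, n_pairs = 5L)
  tab <- set_pair(tab, "BLA", "NRe", r = 0.51, p = 0.09, n_pairs = 8L)
  # non-survivors, one per failing conjunct
  tab <- set_pair(tab, "ACC", "RSP", r = -0.8, p = 0.01, n_pairs = 8L) # negative
  tab <- set_pair(tab, "PL", "IL", r = 0.499999, p = 0.05, n_pairs = 6L) # r below
  tab <- set_pair(tab, "PL", "RSP", r = 0.7, p = 0.100001, n_pairs = 6L) # p above
  tab <- set_pair(tab, "CM", "NRe", r = 0.9, p = 0.001, n_pairs = 3L,
                  excluded = TRUE) # fewer than 4 pairs
  tab <- set_pair(tab, "CM", "PVT", r = 0.9, p = 0.001, n_pairs = 3L) # n below even unflagged
  tab <- set_pair(tab, "dDG", "dCA3", r = 0.9, p = 0.001, n_pairs = 5L,
                  excluded = TRUE) # upstream exclusion wins
  tab
}

# Fold-change table covering all 16 regions for one group.
make_fold_table <- function(group, fold = 1, undefined = FALSE) {
  data.frame(region = fosconnect::region_codes(), group = group,
             fold_change = fold, undefined = undefined,
             stringsAsFactors = FALSE)
}
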