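SECTION_COLUMNS <- c("animal_id", "group", "region", "section_index",
                     "cfos_count", "area_mm2")

#' Read a per-section cFos quantification table
#'
#' Reads and validates a delimited-text table of per-section cFos counts
#' (one row per histological section of one animal and region). The
#' delimiter is inferred from the file extension (`.csv` comma, otherwise
#' tab) unless given. Validation failures report 1-based row numbers into
#' the data body.
#'
#' @param path Path to a TSV/CSV file with header columns `animal_id`,
#'   `group`, `region`, `section_index`, `cfos_count`, `area_mm2`.
#' @param sep Field delimiter; `NULL` (default) infers it from the
#'   extension.
#' @return A validated data frame of section records.
#' @seealso [write_sections()], [aggregate_densities()]
#' @export
read_sections <- function(path, sep = NULL) {
  if (!file.exists(path)) {
    stop("section table not found: ", path, call. = FALSE)
  }
  sep <- infer_sep(path, sep)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "")
  validate_sections(raw)
}

#' Validate section records
#'
#' Checks the section-record contract: required columns present, known
#' region codes, non-negative integer counts, strictly positive areas,
#' positive section indices, unique `(animal_id, region, section_index)`
#' keys and a single group label per animal. Errors carry 1-based data-row
#' numbers.
#'
#' @param records Data frame of candidate section records.
#' @return The validated data frame (types normalised), invisibly usable
#'   downstream.
#' @export
validate_sections <- function(records) {
  missing_cols <- setdiff(SECTION_COLUMNS, names(records))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  records <- records[SECTION_COLUMNS]
  if (nrow(records) == 0L) {
    stop("section table is empty", call. = FALSE)
  }
  records$animal_id <- as.character(records$animal_id)
  records$group <- as.character(records$group)
  records$region <- as.character(records$region)

  problems <- character()
  row_err <- function(rows, what) {
    sprintf("row %s: %s", paste(rows, collapse = ", "), what)
  }

  bad <- which(!(records$region %in% region_codes()))
  if (length(bad)) {
    problems <- c(problems, row_err(bad, paste0(
      "unknown region code (", paste(unique(records$region[bad]), collapse = ", "), ")")))
  }
  count <- suppressWarnings(as.numeric(records$cfos_count))
  bad <- which(is.na(count) | count < 0 | count != round(count))
  if (length(bad)) {
    problems <- c(problems, row_err(bad, "cfos_count must be a non-negative integer"))
  }
  area <- suppressWarnings(as.numeric(records$area_mm2))
  bad <- which(is.na(area) | area <= 0)
  if (length(bad)) {
    problems <- c(problems, row_err(bad, "area_mm2 must be > 0"))
  }
  sec <- suppressWarnings(as.numeric(records$section_index))
  bad <- which(is.na(sec) | sec < 1 | sec != round(sec))
  if (length(bad)) {
    problems <- c(problems, row_err(bad, "section_index must be a positive integer"))
  }

  key <- paste(records$animal_id, records$region, records$section_index,
               sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    problems <- c(problems, row_err(dup,
      "duplicate (animal_id, region, section_index)"))
  }

  grp_per_animal <- tapply(records$group, records$animal_id,
                           function(g) length(unique(g)))
  multi <- names(grp_per_animal)[grp_per_animal > 1]
  if (length(multi)) {
    problems <- c(problems, sprintf(
      "animal(s) with conflicting group labels: %s",
      paste(multi, collapse = ", ")))
  }

  if (length(problems)) {
    stop("invalid section records:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }

  records$section_index <- as.integer(sec)
  records$cfos_count <- as.integer(count)
  records$area_mm2 <- area
  records
}

#' Write section records to delimited text
#'
#' @param records Data frame of section records.
#' @param path Output path; `.csv` writes comma-separated, anything else
#'   tab-separated.
#' @param sep Optional explicit delimiter.
#' @return `path`, invisibly.
#' @export
write_sections <- function(records, path, sep = NULL) {
  sep <- infer_sep(path, sep)
  utils::write.table(records[SECTION_COLUMNS], path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Aggregate section records into per-animal regional densities
#'
#' Computes, for every animal x region entry, the cFos density in
#' cells/mm^2. By default each section's density (`cfos_count / area_mm2`)
#' is computed first and the per-section densities are averaged
#' (`pooled = FALSE`); the pooled alternative, total count over total area,
#' is available as `pooled = TRUE`. The number of contributing sections is
#' recorded per entry.
#'
#' Entries whose section count falls outside 2-6 (the usual sampling depth
#' of one animal's region) are kept but reported under
#' `section_policy = "warn"` (default), or dropped and reported under
#' `"strict"`.
#'
#' @param records Validated section records (see [validate_sections()]).
#' @param section_policy `"warn"` (keep out-of-range entries) or
#'   `"strict"` (drop them).
#' @param pooled Logical; use pooled total-count / total-area instead of
#'   the mean of per-section densities.
#' @return A `density_table` object: a list with `entries` (animal x 16
#'   region density matrix, `NA` where missing), `n_sections` (matching
#'   section counts, 0 where missing) and `design` (data frame mapping
#'   `animal_id` to `group`).
#' @examples
#' cohort <- simulate_cohort(simulation_config(n_per_group = 3, seed = 1))
#' tab <- aggregate_densities(cohort)
#' tab
#' @export
aggregate_densities <- function(records,
                                section_policy = c("warn", "strict"),
                                pooled = FALSE) {
  section_policy <- match.arg(section_policy)
  records <- validate_sections(records)

  regions <- region_codes()
  animals <- unique(records$animal_id)
  design <- unique(records[c("animal_id", "group")])
  design <- design[match(animals, design$animal_id), ]
  rownames(design) <- NULL

  fa <- factor(records$animal_id, levels = animals)
  fr <- factor(records$region, levels = regions)
  entries <- if (pooled) {
    tapply(records$cfos_count, list(fa, fr), sum) /
      tapply(records$area_mm2, list(fa, fr), sum)
  } else {
    tapply(records$cfos_count / records$area_mm2, list(fa, fr), mean)
  }
  n_sections <- tapply(records$area_mm2, list(fa, fr), length)
  n_sections[is.na(n_sections)] <- 0L
  storage.mode(n_sections) <- "integer"
  dimnames(entries) <- dimnames(n_sections) <- list(animals, regions)

  out_of_range <- which(n_sections > 0L & (n_sections < 2L | n_sections > 6L),
                        arr.ind = TRUE)
  if (nrow(out_of_range)) {
    desc <- sprintf("%s/%s (%d sections)",
                    rownames(n_sections)[out_of_range[, 1]],
                    colnames(n_sections)[out_of_range[, 2]],
                    n_sections[out_of_range])
    if (section_policy == "strict") {
      message("dropping ", nrow(out_of_range),
              " entr", if (nrow(out_of_range) == 1) "y" else "ies",
              " with section counts outside [2, 6]: ",
              paste(desc, collapse = "; "))
      entries[out_of_range] <- NA_real_
      n_sections[out_of_range] <- 0L
    } else {
      message("keeping ", nrow(out_of_range),
              " entr", if (nrow(out_of_range) == 1) "y" else "ies",
              " with section counts outside [2, 6]: ",
              paste(desc, collapse = "; "))
    }
  }

  structure(
    list(entries = entries, n_sections = n_sections, design = design),
    class = "density_table"
  )
}

#' @export
print.density_table <- function(x, ...) {
  n_missing <- sum(is.na(x$entries))
  cat(sprintf(
    "density_table: %d animals x %d regions (%d missing entries)\n",
    nrow(x$entries), ncol(x$entries), n_missing))
  tab <- table(x$design$group)
  cat("groups:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Densities and groups of one region
#'
#' Convenience accessor: non-missing per-animal densities of `region`,
#' with the matching group labels.
#'
#' @param table A `density_table`.
#' @param region Region code.
#' @return A data frame with columns `animal_id`, `group`, `density`.
#' @export
region_densities <- function(table, region) {
  stopifnot(inherits(table, "density_table"))
  if (!region %in% colnames(table$entries)) {
    stop("unknown region: ", region, call. = FALSE)
  }
  d <- table$entries[, region]
  ok <- !is.na(d)
  data.frame(
    animal_id = rownames(table$entries)[ok],
    group = table$design$group[match(rownames(table$entries)[ok],
                                     table$design$animal_id)],
    density = unname(d[ok]),
    stringsAsFactors = FALSE
  )
}

#' Long-format view of a density table
#'
#' @param x A `density_table`.
#' @param row.names,optional Ignored (S3 signature).
#' @param ... Ignored.
#' @return Data frame with columns `animal_id`, `group`, `region`,
#'   `density_cfos_per_mm2`, `n_sections`, one row per non-missing entry.
#' @export
as.data.frame.density_table <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  idx <- which(!is.na(x$entries), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  animals <- rownames(x$entries)[idx[, 1]]
  data.frame(
    animal_id = animals,
    group = x$design$group[match(animals, x$design$animal_id)],
    region = colnames(x$entries)[idx[, 2]],
    density_cfos_per_mm2 = x$entries[idx],
    n_sections = x$n_sections[idx],
    stringsAsFactors = FALSE
  )
}

#' Write / read a density table
#'
#' Long-format delimited-text export of a `density_table`, and its inverse.
#' The round trip preserves densities at full printed precision and the
#' animal-to-group design.
#'
#' @param table A `density_table`.
#' @param path TSV/CSV path.
#' @param sep Optional delimiter (inferred from extension by default).
#' @return `write_density_table` returns `path` invisibly;
#'   `read_density_table` returns a `density_table`.
#' @export
write_density_table <- function(table, path, sep = NULL) {
  sep <- infer_sep(path, sep)
  long <- as.data.frame(table)
  utils::write.table(long, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_density_table
#' @export
read_density_table <- function(path, sep = NULL) {
  sep <- infer_sep(path, sep)
  long <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
  need <- c("animal_id", "group", "region", "density_cfos_per_mm2",
            "n_sections")
  missing_cols <- setdiff(need, names(long))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  regions <- region_codes()
  animals <- unique(long$animal_id)
  entries <- matrix(NA_real_, length(animals), length(regions),
                    dimnames = list(animals, regions))
  n_sections <- matrix(0L, length(animals), length(regions),
                       dimnames = list(animals, regions))
  entries[cbind(match(long$animal_id, animals),
                match(long$region, regions))] <- long$density_cfos_per_mm2
  n_sections[cbind(match(long$animal_id, animals),
                   match(long$region, regions))] <- as.integer(long$n_sections)
  design <- unique(long[c("animal_id", "group")])
  design <- design[match(animals, design$animal_id), ]
  rownames(design) <- NULL
  structure(list(entries = entries, n_sections = n_sections, design = design),
            class = "density_table")
}
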