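#' Brain region panel
#'
#' The 16 forebrain regions quantified by the pipeline, grouped into four
#' major subdivisions: medial prefrontal / retrosplenial cortex (ACC, PL,
#' IL, RSP), midline thalamus (CM, aNRe, NRe, PVT), amygdala (CEA, BLA) and
#' dorsal/ventral hippocampal subfields (dDG, dCA3, dCA1, vDG, vCA3, vCA1).
#' Region codes are case-sensitive identifiers; each maps to exactly one
#' division.
#'
#' @return A data frame with columns `region` (character code) and
#'   `division` (one of `"cortex"`, `"thalamus"`, `"amygdala"`,
#'   `"hippocampus"`), one row per region, in canonical atlas order.
#' @examples
#' brain_regions()
#' @export
brain_regions <- function() {
  data.frame(
    region = c(
      "ACC", "PL", "IL", "RSP",
      "CM", "aNRe", "NRe", "PVT",
      "CEA", "BLA",
      "dDG", "dCA3", "dCA1", "vDG", "vCA3", "vCA1"
    ),
    division = rep(
      c("cortex", "thalamus", "amygdala", "hippocampus"),
      times = c(4L, 4L, 2L, 6L)
    ),
    stringsAsFactors = FALSE
  )
}

#' Region codes in canonical order
#'
#' @return Character vector of the 16 region codes.
#' @export
region_codes <- function() brain_regions()$region

#' Division of one or more region codes
#'
#' @param region Character vector of region codes.
#' @return Character vector of division labels.
#' @export
region_division <- function(region) {
  tab <- brain_regions()
  idx <- match(region, tab$region)
  if (anyNA(idx)) {
    stop("unknown region code(s): ",
         paste(unique(region[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  tab$division[idx]
}

#' Experimental group labels
#'
#' The four-group contextual fear design: `home_cage` (baseline cFos
#' activity, sacrificed 24 h after the last session), `context_only`
#' (context exposure without foot shock), `recall` (single conditioned
#' context re-exposure 30 days after conditioning) and `extinction`
#' (full spaced extinction paradigm). `home_cage` is the designated
#' baseline for fold-change computations.
#'
#' @return Character vector of the four group labels, baseline first.
#' @export
fos_groups <- function() c("home_cage", "context_only", "recall", "extinction")

#' Baseline group label
#'
#' @return `"home_cage"`.
#' @export
baseline_group <- function() "home_cage"

#' Significance star coding
#'
#' Standard three-level star labels used in correlation-matrix displays:
#' `*` for p < 0.05, `**` for p < 0.01, `***` for p < 0.001, empty
#' otherwise.
#'
#' @param p Numeric vector of p-values (NA allowed).
#' @return Character vector of star labels.
#' @export
p_stars <- function(p) {
  out <- character(length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}
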