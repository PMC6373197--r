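`%||%` <- function(a, b) if (is.null(a)) b else a

# Run an expression under a local RNG seed, restoring the caller's RNG
# state afterwards so package functions never disturb the global stream.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic per-animal substream seed: independent of the number of
# animals in other groups, so enlarging one group never perturbs another.
# Kept strictly below 2^31 - 1.
substream_seed <- function(master_seed, group_index, animal_index) {
  (as.numeric(master_seed) * 10007 + group_index * 131071 +
     animal_index * 127) %% 2147483647
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single non-missing number", name),
         call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("`%s` must be in [%s, %s], got %s", name,
                 format(lower), format(upper), format(x)), call. = FALSE)
  }
  invisible(x)
}

# Delimiter inferred from file extension: ".csv" -> comma, anything else tab.
infer_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}
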