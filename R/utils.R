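# Shared internal helpers: classed error conditions, name normalization,
# deterministic text table writers.

#' @keywords internal
ox_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "redoxscreen_error"),
                      call = call))
}

#' @keywords internal
assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) ||
      x < min) {
    ox_stop(sprintf("`%s` must be a single integer >= %d", name, min),
            "invalid_parameter")
  }
  as.integer(x)
}

# lowercase, trim, collapse internal whitespace — identity used to match
# drug names across databases
#' @keywords internal
normalize_name <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

# percent rounded to one decimal, as the network/mining summaries report it
#' @keywords internal
pct1 <- function(count, total) {
  if (total == 0) return(0)
  round(100 * count / total, 1)
}

# Deterministic TSV/CSV writers: fixed column order, no quotes, no rownames,
# so identical data frames serialize byte-identically.
#' @keywords internal
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' @keywords internal
write_csv <- function(df, path) {
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' @keywords internal
read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, ...)
}

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state.
#' @keywords internal
with_seed <- function(seed, expr) {
  seed <- assert_count(seed, "seed", min = 0L)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
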