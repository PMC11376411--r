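# Internal helpers shared across modules.

#' Package verbosity
#'
#' Messages go to standard error via [message()]. Set
#' `options(catforge.verbose = FALSE)` to silence progress output.
#' @noRd
cf_msg <- function(...) {
  if (isTRUE(getOption("catforge.verbose", TRUE))) message(...)
  invisible(NULL)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so generators are deterministic without
# clobbering the session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Read a tab-separated table with a header row
#'
#' Thin wrapper used for all of the package's TSV interfaces (quality,
#' taxonomy, profiles, annotations).
#'
#' @param path File path.
#' @param required Character vector of column names that must be present.
#' @return A data.frame.
#' @export
read_tsv_table <- function(path, required = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stopf("%s is missing required column(s): %s", path,
          paste(missing, collapse = ", "))
  df
}

#' Write a tab-separated table
#'
#' @param df A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Seven-rank lineage order used throughout.
TAXONOMY_RANKS <- c("domain", "phylum", "class", "order", "family",
                    "genus", "species")
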