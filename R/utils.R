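#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so package functions that take a `seed`
#' argument do not disturb the caller's RNG stream.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Derive a stage-specific seed from a global seed
#'
#' Fans a global seed out to per-stage streams with fixed offsets, keeping
#' the result inside R's 32-bit integer range, so one user-facing seed
#' reproducibly controls every stochastic stage.
#'
#' @param seed global integer seed
#' @param offset integer stage offset
#' @return derived integer seed in `[0, 2^31)`
#' @export
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% .Machine$integer.max)
}

#' Write a data frame as a plain tab-separated table
#'
#' Thin wrapper over [utils::write.table()] with the conventions used by all
#' package writers: tab-separated, unquoted, no row names.
#'
#' @param df data frame
#' @param path output path
#' @param col.names write a header row (default `TRUE`)
#' @return `path`, invisibly
#' @export
write_tsv <- function(df, path, col.names = TRUE) {
  utils::write.table(df, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = col.names)
  invisible(path)
}
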