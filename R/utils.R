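# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package functions do not
#' disturb the caller's RNG stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG stream alone.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Mix a user seed with a stream index into a 31-bit substream seed.
# Keeps derived seeds strictly below 2^31 so they remain valid R integers.
mixSeed <- function(seed, stream) {
  s <- (as.double(seed) * 2654435761 + as.double(stream) * 40503) %% 2147483647
  as.integer(s)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Deterministic TSV writer used by all result writers.
writeTsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  out <- df
  for (j in which(num)) {
    out[[j]] <- ifelse(is.na(df[[j]]), "NA", formatC(df[[j]], digits = 17, format = "g"))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, quote = "", comment.char = "", ...)
}
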