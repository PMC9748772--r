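`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a global seed
#'
#' Stage-scoped sub-streams let pipeline stages be rerun independently while
#' remaining reproducible from one global seed. Kept below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stage integer or character stage identifier.
#' @return an integer seed.
#' @export
deriveSeed <- function(seed, stage) {
  if (is.character(stage)) {
    stage <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  }
  as.integer((as.numeric(seed) * 48271 + 10007 * as.numeric(stage) + 12345) %%
               2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

isCount <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x >= 0 && x == floor(x)
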