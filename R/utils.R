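# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so generators are pure functions
#' of their arguments.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# stop() without the call, with sprintf-style formatting
qstop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Numbers printed so that read-back reproduces the double exactly.
fmt_num <- function(x) sprintf("%.17g", x)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
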