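# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ..., class = NULL) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(class, "burdengwas_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global random-number stream set from `seed`, then
#' restores the previous stream so callers' RNG state is untouched. With
#' `seed = NULL` the expression just uses the current stream.
#'
#' @param seed Integer scalar or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stopf("seed must be a single finite number, got %s", deparse(seed))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible child seed from a master seed and a stream label,
# keeping the result inside the 32-bit integer range.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(as.character(stream)) * (31L^(seq_len(nchar(as.character(stream))) %% 7L)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_boundary = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("%s must be a single finite number", name)
  }
  ok <- if (allow_boundary) x >= lower && x <= upper else x > lower && x < upper
  if (!ok) {
    stopf("%s = %g outside %s%g, %g%s", name, x,
          if (allow_boundary) "[" else "(", lower, upper,
          if (allow_boundary) "]" else ")")
  }
  invisible(x)
}

# Two-sided p-value from a squared z-score (1-df chi-square upper tail),
# floored at the smallest normalized double so extreme statistics never
# underflow to an (invalid) exact zero.
zsq_to_p <- function(z_sq) {
  pmax(stats::pchisq(z_sq, df = 1, lower.tail = FALSE),
       .Machine$double.xmin)
}
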