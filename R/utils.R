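# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_axonloc <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_axonloc(sprintf("'%s' must be a single finite number", name))
  if (x < min || (strict_min && x == min) || x > max)
    stop_axonloc(sprintf("'%s' = %g is out of range [%g, %g]%s", name, x,
                         min, max, if (strict_min) " (exclusive lower bound)" else ""))
  invisible(x)
}

# Run `expr` under a deterministic RNG sub-stream derived from an integer
# seed and a component label, restoring the caller's RNG state afterwards.
# All generator functions route their randomness through this helper so a
# single seed reproduces every component byte-for-byte.
with_substream <- function(seed, component, expr) {
  sub <- (as.integer(seed) + utf8ToInt(substr(component, 1L, 1L)) * 1009L +
            nchar(component) * 101L) %% .Machine$integer.max
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(sub)
  expr
}
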