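#' @keywords internal
"_PACKAGE"

# Run expr with a temporarily fixed RNG state, restoring the caller's stream.
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
    set.seed(as.integer(seed))
  }
  force(expr)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p / (1 - p))

# 1-based indices of the n central PE lines for an even-length axis whose DC
# sample sits at index Y/2 + 1.
central_band <- function(Y, n) {
  dc <- Y %/% 2L + 1L
  start <- dc - (n %/% 2L)
  seq.int(start, start + n - 1L)
}

stopifnot_finite <- function(x, what = "input") {
  if (!all(is.finite(Re(x))) || (is.complex(x) && !all(is.finite(Im(x)))))
    stop(sprintf("non-finite values in %s", what))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
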