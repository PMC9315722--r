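# internal helpers shared across the package

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# round-half-up; base round() rounds half to even, which would make the
# retained-edge count depend on the parity of the tie
round_half_up <- function(x) floor(x + 0.5)

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# add a length-ncol vector to every row of a matrix without sweep() overhead
add_rows <- function(m, v) m + rep(v, each = nrow(m))

is_binary_label <- function(x) {
  !anyNA(x) && all(x %in% c(0L, 1L))
}
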