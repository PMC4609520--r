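#' @keywords internal
"_PACKAGE"

#' @importFrom stats optimize rbinom rnorm runif setNames sd predict
#' @importFrom utils read.csv write.csv modifyList
NULL

# Run `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards.  All package randomness flows through this.
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
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

# Derive a per-unit child seed from a base seed, kept inside 32-bit range.
child_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 16807) %% 2147483647)
}

# Half-away-from-zero rounding to one decimal, used for report formatting.
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

fmt1 <- function(x) sprintf("%.1f", round_half_up(x, 1L))

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

is_binary <- function(x) all(x %in% c(0, 1))

`%||%` <- function(a, b) if (is.null(a)) b else a
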