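#' @keywords internal
"_PACKAGE"

# Stop with a classed condition so callers/tests can distinguish error kinds.
stop_dpifuse <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "dpifuse_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Deterministic fan-out of one global seed into named sub-streams, so that
# e.g. changing the lapse draw does not reshuffle the noise stream.
sub_seed <- function(seed, stream) {
  stopifnot(is_count(seed + 1))  # allow 0
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

# Evaluate with a local RNG state (does not disturb the caller's RNG).
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
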