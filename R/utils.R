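# internal validation helpers

stop_restfc <- function(msg, class = "restfc_error") {
  rlang::abort(msg, class = c(class, "restfc_error"))
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_restfc(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    stop_restfc(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 0L) {
  check_number(x, name, lower = lower)
  if (x != round(x)) stop_restfc(sprintf("`%s` must be an integer count.", name))
  invisible(as.integer(x))
}

check_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_restfc(sprintf("`%s` must be a numeric matrix.", name))
  }
  if (!all(is.finite(x))) {
    stop_restfc(sprintf("`%s` contains non-finite values.", name))
  }
  invisible(x)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All stochastic package code funnels through this.
with_rng_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# counter-based substream: independent reproducible per-unit seeds
substream_seed <- function(base_seed, counter) {
  (as.double(base_seed) * 7919 + 104729 * as.double(counter)) %% 2147483647
}
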