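# Internal helpers shared across modules.

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
# A NULL seed leaves the global stream untouched (and advances it).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Draw n child seeds (< 2^31) from a master seed; used so that embarrassingly
# parallel sub-computations (null networks, participants) are individually
# reproducible from the recorded master seed.
spawn_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max, n, replace = FALSE))
}

# round half away from zero (BCT-style edge-count rounding); base round()
# rounds half to even.
round_half_up <- function(x) floor(x + 0.5)

stop_arg <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "plinet_argument_error")
}

check_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    stop_arg("`%s` must be a single finite number in [%s, %s]", name,
             format(lo), format(hi))
  }
  invisible(x)
}
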