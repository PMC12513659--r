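# Internal helpers shared across modules.

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

#' Convert between degrees and radians
#'
#' All internal computation in vergedist is in radians; degrees appear only
#' at user-facing boundaries (noise levels are conventionally reported in
#' degrees of vergence angle).
#'
#' @param x numeric vector of angles.
#' @return numeric vector of converted angles.
#' @export
deg2rad <- function(x) x * DEG2RAD

#' @rdname deg2rad
#' @export
rad2deg <- function(x) x * RAD2DEG

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic entry points route through this so that no
# function has hidden global side effects.
with_local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic child seed for cell `i` of a grid driven by `seed`.
# Kept strictly below 2^31 so it is always a valid R integer seed.
child_seed <- function(seed, i) {
  as.integer((as.double(seed) + 7919 * as.double(i)) %% 2147483629)
}

stop_domain <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop_domain("`%s` must be finite and strictly positive", name)
  }
  invisible(x)
}
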