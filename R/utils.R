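# Internal helpers shared across modules.

# Classed conditions so callers can distinguish failure modes programmatically.
itil_error <- function(class, msg, ..., call. = sys.call(-1)) {
  cond <- structure(
    class = c(class, "itil_error", "error", "condition"),
    list(message = msg, call = call., ...)
  )
  stop(cond)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    itil_error("itil_invalid_argument", sprintf("`%s` must be a finite number", name))
  }
  if (positive && x <= 0) {
    itil_error("itil_invalid_argument", sprintf("`%s` must be positive", name))
  }
  invisible(x)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` with the global random-number state set from `seed`, then
#' restores the previous state, so seeded generators are pure functions of
#' their specification and never disturb the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Deterministic integer hash of pixel coordinates, used for seeded per-pixel
# colour jitter that is independent of tiling (same global pixel -> same
# jitter, whichever tile renders it). Arithmetic kept within double precision.
pixel_hash <- function(ix, iy, seed, channel = 0L) {
  h <- (ix * 73856.093 + iy * 19349.663 + seed * 83492.791 + channel * 7919)
  h <- h - floor(h / 1048576) * 1048576    # mod 2^20, exact in doubles
  (h * 2654435.761) %% 7
}
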