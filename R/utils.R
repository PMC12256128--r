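#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (`0.125 -> 0.13` at two
#' digits), the convention used throughout the reporting functions. Base R's
#' [round()] rounds half to even, which disagrees with hand-computed
#' percentages on exact ties.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_up(2.885, 2)  # 2.89
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # nudge by an ulp-scale epsilon so values that are decimal ties but sit
  # just below .5 in binary still round up
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state so that
#' seeded internals never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive a child seed from a base seed and integer offsets; stays in
# [0, 2^31 - 2] so it is always a valid R seed.
derive_seed <- function(base_seed, ...) {
  parts <- c(base_seed, ...)
  h <- 0
  for (p in parts) h <- (h * 48271 + as.numeric(p)) %% 2147483647
  as.integer(h)
}

# Classed error helpers so callers can distinguish failure modes.
stop_rpvaudit <- function(class, message, ...) {
  stop(structure(
    class = c(class, "rpvaudit_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

stop_invalid_argument <- function(message, ...) {
  stop_rpvaudit("invalid_argument", message, ...)
}
stop_schema_error <- function(message, ...) {
  stop_rpvaudit("schema_error", message, ...)
}
stop_integrity_error <- function(message, ...) {
  stop_rpvaudit("integrity_error", message, ...)
}
stop_invalid_state <- function(message, ...) {
  stop_rpvaudit("invalid_state", message, ...)
}
stop_empty_result <- function(message, ...) {
  stop_rpvaudit("empty_result_error", message, ...)
}
stop_training_failure <- function(message, ...) {
  stop_rpvaudit("training_failure", message, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# FNV-1a hash of a character scalar, reported as hex; used for config
# fingerprints in run manifests (stable across sessions, no dependency).
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30), b) + 2^30  # keep in int range
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

# Fixed-precision formatting for floats written to CSV so outputs are
# byte-stable across runs and platforms.
format_confidence <- function(x) sprintf("%.6f", x)
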