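# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Printed summary tables in this field round 2.5 -> 3 (half away from zero),
#' whereas base [round()] uses banker's rounding. All user-facing percentages
#' and averages in this package go through this helper.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return `x` rounded to `digits` places, ties away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # small epsilon absorbs double-precision error in x * p (e.g. 2.675 * 100)
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Deterministic per-stream sub-seed derived from one user-visible seed, so
# adding a generator stream never shifts the draws of another.
stream_seed <- function(seed, stream) {
  offsets <- c(
    lengths = 1, signs = 2, counts = 3,
    read_bases = 4, read_quality = 5, ct = 6
  )
  if (!stream %in% names(offsets)) {
    stop("unknown random stream: ", stream)
  }
  as.integer((abs(as.numeric(seed)) * 7919 + offsets[[stream]]) %% 2147483629)
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("'", name, "' must be a single finite number", call. = FALSE)
  }
  invisible(x)
}
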