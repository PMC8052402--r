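# Internal helpers shared across modules.

abort_invalid <- function(msg) {
  rlang::abort(msg, class = "chromaqtl_invalid_argument")
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) || x < min || x != floor(x)) {
    abort_invalid(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

check_prob <- function(x, name, lo = 0, hi = 1, open_lo = FALSE, open_hi = FALSE) {
  ok <- length(x) == 1L && is.numeric(x) && !is.na(x) &&
    (if (open_lo) x > lo else x >= lo) && (if (open_hi) x < hi else x <= hi)
  if (!ok) abort_invalid(sprintf("`%s` must lie in %s%g, %g%s.", name,
                                 if (open_lo) "(" else "[", lo, hi,
                                 if (open_hi) ")" else "]"))
  x
}

#' Derive a reproducible sub-seed from a master seed and a label
#'
#' All stochastic generators in the package draw their randomness from one
#' explicit master seed; per-stage sub-seeds are derived deterministically so
#' that stages can be re-run in isolation without perturbing each other.
#'
#' @param seed Master integer seed.
#' @param label Character tag naming the consumer of the sub-seed.
#' @return A single integer seed in `[0, 2^31 - 19)`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.character(label), length(label) == 1L)
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes)) %% 2147483629
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919) %% 2147483629)
}

# log(sum(exp(x))) guarded against -Inf and overflow
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

# 0-based signed distance from a 1-based variant position to the nearest
# edge of a 0-based half-open interval; 0 when the variant lies inside.
interval_distance <- function(pos, start, end) {
  v <- pos - 1
  out <- numeric(length(v))
  left <- v < start
  right <- v >= end
  out[left] <- v[left] - start[left]
  out[right] <- v[right] - end[right] + 1
  out
}
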