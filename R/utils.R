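#' Nearest-rank percentile
#'
#' The q-th percentile of `x` as the ceiling(q * n)-th order statistic of the
#' ascending sort. Deterministic and interpolation-free; this is the percentile
#' convention used everywhere in the package (Treg subgroup thresholds, the
#' permutation-test critical value).
#'
#' @param x numeric vector, length >= 1.
#' @param q quantile level in (0, 1].
#' @return the nearest-rank order statistic.
#' @examples
#' nearest_rank(1:100, 0.75) # 75
#' @export
nearest_rank <- function(x, q) {
  stopifnot(length(x) >= 1, is.numeric(x), q > 0, q <= 1)
  xs <- sort(x)
  xs[ceiling(q * length(xs))]
}

#' Derive reproducible per-sample sub-seeds from one master seed
#'
#' One master seed per run; each sample gets its own integer sub-seed so
#' per-sample results are reproducible and independent of processing order.
#'
#' @param master_seed integer master seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`.
#' @export
stream_seeds <- function(master_seed, n) {
  stopifnot(n >= 0)
  if (n == 0L) return(integer(0))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# Even-odd point-in-polygon over a list of rings (each list(x, y)); holes are
# just additional rings. Returns logical vector.
point_in_rings <- function(px, py, rings) {
  inside <- rep(FALSE, length(px))
  for (r in rings) {
    hit <- sp::point.in.polygon(px, py, r$x, r$y) > 0
    inside <- xor(inside, hit)
  }
  inside
}

# Signed area of one ring (shoelace); positive = counter-clockwise.
ring_signed_area <- function(ring) {
  x <- ring$x; y <- ring$y
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' Package-level logging
#'
#' Messages are emitted through [message()] with a stage tag so pipeline runs
#' can be audited; suppress with `suppressMessages()`.
#' @param stage short stage label.
#' @param ... passed to [sprintf()].
#' @keywords internal
ts_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}
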