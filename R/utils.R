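# Internal helpers: 1-based inclusive frame windows and seed substreams.

#' @keywords internal
#' @noRd
check_window <- function(w, what = "window", n_frames = NULL) {
  if (is.null(w)) return(invisible(NULL))
  if (!is.numeric(w) || length(w) != 2L || any(!is.finite(w)))
    stop(sprintf("%s must be a numeric vector c(first, last)", what), call. = FALSE)
  w <- as.integer(w)
  if (w[1] < 1L || w[2] < w[1])
    stop(sprintf("%s must satisfy 1 <= first <= last (got [%d, %d])", what, w[1], w[2]),
         call. = FALSE)
  if (!is.null(n_frames) && w[2] > n_frames)
    stop(sprintf("%s [%d, %d] exceeds the %d available frames", what, w[1], w[2], n_frames),
         call. = FALSE)
  invisible(w)
}

# 1-based inclusive interval -> index vector
window_idx <- function(w) seq.int(w[1], w[2])

window_mean <- function(x, w) mean(x[window_idx(w)])

#' Derive a per-replicate substream seed from a master seed.
#'
#' Counter-based: the i-th substream depends only on (seed, i), so adding
#' replicates never reshuffles earlier ones. Kept below 2^31 - 1.
#' @keywords internal
#' @noRd
substream_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 16807) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
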