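# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the caller's `.Random.seed` so that simulator calls are
#' reproducible without disturbing the global RNG stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

soft_threshold <- function(x, tau) sign(x) * pmax(abs(x) - tau, 0)

db_to_amplitude <- function(db) 10^(db / 20)
amplitude_to_db <- function(a) 20 * log10(a)

#' Envelope of the axial analytic signal
#'
#' FFT-based Hilbert envelope applied along the first (axial) dimension of a
#' matrix, column by column.
#' @param v numeric matrix (axial x lateral).
#' @return matrix of envelope magnitudes, same dimensions.
#' @keywords internal
analytic_envelope <- function(v) {
  v <- as.matrix(v)
  n <- nrow(v)
  if (n == 0L) return(v)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1
    if (n > 2L) h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    if (n > 1L) h[2L:((n + 1L) / 2L)] <- 2
  }
  vf <- stats::mvfft(v)
  av <- stats::mvfft(vf * h, inverse = TRUE) / n
  matrix(Mod(av), nrow = n, dimnames = dimnames(v))
}

# Truncated (edge-shrinking) moving sum along a vector: at positions where the
# window extends past the ends it is clipped, not padded.
running_sum_truncated <- function(x, half) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  cs[hi + 1L] - cs[lo]
}

# Truncated moving average over a matrix with a rectangular kernel
# (rows x cols), separable box filter; the divisor is the clipped window size
# so that edges are averages over the in-bounds samples.
box_filter_truncated <- function(v, kernel) {
  v <- as.matrix(v)
  hr <- (kernel[1L] - 1L) %/% 2L
  hc <- (kernel[2L] - 1L) %/% 2L
  num <- apply(v, 2L, running_sum_truncated, half = hr)
  num <- t(apply(num, 1L, running_sum_truncated, half = hc))
  cnt_r <- running_sum_truncated(rep(1, nrow(v)), hr)
  cnt_c <- running_sum_truncated(rep(1, ncol(v)), hc)
  num / outer(cnt_r, cnt_c)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
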