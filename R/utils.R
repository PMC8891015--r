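#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg, call. = FALSE) {
  if (!isTRUE(cond)) stop(msg, call. = call.)
}

#' Zero-phase Gaussian smoothing of a uniformly sampled signal
#'
#' Convolves `x` with a unit-area Gaussian kernel of standard deviation
#' `sd_samples` (truncated at 6 s.d.), using reflected padding so that the
#' output has no phase shift and no edge roll-off towards zero. Used for
#' drift correction (60 s s.d.), time-locked input-resistance smoothing
#' (13 ms s.d.) and derivative-based trace alignment.
#'
#' @param x numeric vector.
#' @param sd_samples kernel standard deviation in samples; `0` returns `x`.
#' @return numeric vector of the same length as `x`.
#' @export
gaussian_smooth <- function(x, sd_samples) {
  stop_if_not(is.numeric(x) && length(x) > 0, "x must be a nonempty numeric vector")
  stop_if_not(is.numeric(sd_samples) && sd_samples >= 0, "sd_samples must be >= 0")
  if (sd_samples == 0) return(as.numeric(x))
  n <- length(x)
  half <- min(ceiling(6 * sd_samples), n - 1L)
  k <- stats::dnorm(seq(-half, half), sd = sd_samples)
  k <- k / sum(k)
  # reflect-pad, then FFT convolution (kernels can span 1e5+ samples)
  xp <- c(rev(x[seq_len(half)]), x, rev(x[n - seq_len(half) + 1L]))
  y <- stats::convolve(xp, rev(k), type = "open")
  y[seq.int(2L * half + 1L, length.out = n)]
}

#' Linear resampling of a uniformly sampled trace
#'
#' @param x numeric vector sampled at `fs_in` Hz (first sample at t = 0).
#' @param fs_in,fs_out input and output sampling rates in Hz.
#' @return numeric vector covering the same time span at `fs_out`.
#' @export
resample_trace <- function(x, fs_in, fs_out) {
  stop_if_not(fs_in > 0 && fs_out > 0, "sampling rates must be positive")
  if (fs_in == fs_out) return(as.numeric(x))
  t_in <- (seq_along(x) - 1) / fs_in
  t_out <- seq(0, t_in[length(t_in)], by = 1 / fs_out)
  stats::approx(t_in, x, xout = t_out, rule = 2)$y
}

#' Shift a trace in time by a (possibly fractional) number of seconds
#'
#' Positive `dt_s` delays the trace (content moves to later times); negative
#' values advance it. Values shifted in from outside the support are held at
#' the trace's corresponding end value, which is the correct continuation for
#' episodes that start and end in a steady (dark) state.
#'
#' @param x numeric vector sampled at `fs` Hz.
#' @param dt_s shift in seconds (positive = delay).
#' @param fs sampling rate in Hz.
#' @export
shift_trace <- function(x, dt_s, fs) {
  if (dt_s == 0) return(as.numeric(x))
  t <- (seq_along(x) - 1) / fs
  stats::approx(t + dt_s, x, xout = t, rule = 2)$y
}

# derive a substream seed from a base seed; kept below 2^31
substream_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629
}

# evaluate expr under a fixed seed, restoring the caller's RNG state after
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
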