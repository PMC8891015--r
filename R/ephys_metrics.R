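# Current- and voltage-clamp analytics: input resistance from current steps,
# time-locked input resistance across holding currents, resting-potential
# screening, derivative-based trace alignment, linear leak subtraction and
# response amplitude.

#' Construct a set of repeated stimulus-locked sweeps
#'
#' Groups repeated presentations of an identical stimulus recorded under
#' different holding currents on a common stimulus-locked time base.
#'
#' @param sweeps numeric matrix, one row per sweep (mV).
#' @param holding_pA holding current of each sweep in pA (hyperpolarizing
#'   currents are negative).
#' @param fs sampling rate in Hz.
#' @param stimulus_id optional stimulus label.
#' @return an object of class `episode_set`.
#' @export
episode_set <- function(sweeps, holding_pA, fs = 1000, stimulus_id = NA_character_) {
  sweeps <- as.matrix(sweeps)
  stop_if_not(nrow(sweeps) == length(holding_pA), "one holding current per sweep")
  structure(list(sweeps = sweeps, holding_pA = as.numeric(holding_pA), fs = fs,
                 stimulus_id = stimulus_id),
            class = "episode_set")
}

#' @export
print.episode_set <- function(x, ...) {
  cat(sprintf("episode_set: %d sweeps x %d samples at %g Hz; holding currents %s pA\n",
              nrow(x$sweeps), ncol(x$sweeps), x$fs,
              paste(format(x$holding_pA), collapse = ", ")))
  invisible(x)
}

#' Input resistance from hyperpolarizing current steps
#'
#' The slope of the least-squares line of steady-state voltage change on
#' injected current (1 s steps of hyperpolarizing current, 2 pA increments
#' starting at -10 pA in the standard protocol). With voltages in mV and
#' currents in pA the slope is in GOhm. The estimate is invariant to the
#' ordering of the steps and to a common voltage offset (the fit has an
#' intercept).
#'
#' @param i_pA injected step currents in pA (at least two distinct values).
#' @param dv_mV steady-state voltage changes in mV.
#' @return input resistance in GOhm.
#' @export
input_resistance_steps <- function(i_pA, dv_mV) {
  stop_if_not(length(i_pA) == length(dv_mV), "currents and voltages differ in length")
  stop_if_not(length(unique(i_pA)) >= 2, "need at least two distinct step currents")
  unname(stats::coef(stats::lm(dv_mV ~ i_pA))[2])
}

#' Time-locked input resistance from repeated sweeps
#'
#' At each time point, regresses voltage across sweeps onto holding current;
#' the slope is the neuron's input resistance at that time (for exactly two
#' holding currents this equals `dV_m / dI`). The resistance trace is then
#' smoothed with a Gaussian filter (13 ms s.d. by default). The regression
#' includes an intercept (the zero-current voltage trajectory), which does
#' not change the slope relative to the two-current difference formula.
#'
#' @param episodes an [episode_set()] with at least two distinct holding
#'   currents.
#' @param smooth_sd_ms Gaussian smoothing s.d. in ms (default 13; `0`
#'   disables smoothing).
#' @return numeric vector: input resistance in GOhm per time point.
#' @export
timelocked_resistance <- function(episodes, smooth_sd_ms = 13) {
  stop_if_not(inherits(episodes, "episode_set"), "need an episode_set")
  I <- episodes$holding_pA
  stop_if_not(length(unique(I)) >= 2, "rank-deficient design: need >= 2 distinct holding currents")
  w <- (I - mean(I)) / sum((I - mean(I))^2)
  r <- as.numeric(crossprod(w, episodes$sweeps))  # slope mV/pA = GOhm
  if (smooth_sd_ms > 0) r <- gaussian_smooth(r, smooth_sd_ms / 1000 * episodes$fs)
  r
}

#' Resting potential and inclusion criterion
#'
#' The resting potential is the most negative membrane potential recorded
#' within the first two minutes after break-in (in darkness, zero holding
#' current). Cells are included only if it is strictly more negative than the
#' criterion (-25 mV by default); a cell sitting exactly at the criterion is
#' rejected.
#'
#' @param vm voltage trace in mV at zero holding current.
#' @param fs sampling rate in Hz.
#' @param criterion_mV inclusion criterion (default -25).
#' @param window_s window after break-in to search (default 120 s).
#' @return list with `resting_mV` and logical `accepted`.
#' @export
resting_potential <- function(vm, fs, criterion_mV = -25, window_s = 120) {
  stop_if_not(length(vm) >= 1, "empty trace")
  n <- min(length(vm), max(1L, round(window_s * fs)))
  v0 <- min(vm[seq_len(n)])
  list(resting_mV = v0, accepted = v0 < criterion_mV)
}

# full cross-correlation of two equal-length vectors; returns the lag (in
# samples) of a relative to b that maximizes their overlap
# normalized cross-correlation peak: the trace's edge regions (filter
# transients, shift padding) are excluded, and each candidate lag is scored
# by the correlation of the trace window with the correspondingly shifted
# template window, normalized by both window norms (plain unnormalized
# correlation biases the peak towards zero lag when the signal is smooth)
xcorr_peak_lag <- function(a, b, max_lag = length(a) %/% 4L) {
  n <- length(a)
  edge <- min(max(max_lag, 1L), (n - 1L) %/% 2L)
  keep_idx <- seq.int(edge + 1L, n - edge)
  aw <- numeric(n)
  aw[keep_idx] <- a[keep_idx]
  cc <- stats::convolve(aw, b, type = "open")  # cc[k] = sum_i aw[i + k - n] b[i]
  lag <- seq.int(-(n - 1L), n - 1L)
  nb2 <- c(0, cumsum(b^2))
  score <- rep(-Inf, length(lag))
  na2 <- sum(aw^2)
  for (k in which(abs(lag) <= min(max_lag, edge))) {
    l <- lag[k]
    w <- nb2[n - edge - l + 1L] - nb2[edge - l + 1L]  # norm of b over the shifted window
    if (w > 0) score[k] <- cc[k] / sqrt(na2 * w)
  }
  lag[which.max(score)]
}

#' Align traces to a template by their low-pass-filtered derivatives
#'
#' Each trace is Gaussian low-pass filtered, differentiated, and
#' cross-correlated with the equally processed template; the lag of the
#' cross-correlation maximum is the trace's temporal offset. Flat traces
#' (no derivative signal) give a typed undefined outcome (`NA` offset).
#'
#' @param traces list of numeric voltage traces (mV), equal length.
#' @param template numeric template trace of the same length.
#' @param fs sampling rate in Hz.
#' @param lowpass_sd_ms Gaussian smoothing s.d. in ms applied before
#'   differentiation (default 50).
#' @param max_lag_s largest offset magnitude considered (default 0.25 s).
#' @return numeric vector of per-trace offsets in seconds (positive: the
#'   trace lags the template); `NA` where undefined.
#' @export
align_by_derivative <- function(traces, template, fs, lowpass_sd_ms = 50,
                                max_lag_s = 0.25) {
  sds <- lowpass_sd_ms / 1000 * fs
  dtemp <- diff(gaussian_smooth(template, sds))
  stop_if_not(stats::sd(dtemp) > 0, "flat template: alignment undefined")
  vapply(traces, function(tr) {
    stop_if_not(length(tr) == length(template), "traces must overlap the template in time")
    if (diff(range(tr)) == 0) return(NA_real_)  # flat trace: offset undefined
    d <- diff(gaussian_smooth(tr, sds))
    if (stats::sd(d) == 0) return(NA_real_)
    xcorr_peak_lag(d, dtemp, max_lag = round(max_lag_s * fs)) / fs
  }, numeric(1))
}

#' Linear leak subtraction for voltage-clamp sweeps
#'
#' Fits the linear leak relation `I_leak = a + b * V` to the mean currents in
#' an event-free pre-pulse window across sweeps at different command
#' voltages, and subtracts the fitted leak from every sweep, isolating the
#' evoked (synaptic) currents. `b` estimates the leak conductance
#' (`1 / R_in`). If a sweep's pre-pulse window is unusually variable
#' (suggesting it overlaps synaptic events) a warning is issued.
#'
#' @param sweeps numeric matrix of clamp currents, one row per sweep (pA).
#' @param v_cmd_mV command voltage of each sweep in mV.
#' @param prepulse_idx column indices of the event-free pre-pulse window.
#' @return list with `evoked` (leak-subtracted current matrix), `a`
#'   (intercept, pA) and `b` (slope, pA/mV = nS).
#' @export
leak_subtract <- function(sweeps, v_cmd_mV, prepulse_idx) {
  sweeps <- as.matrix(sweeps)
  stop_if_not(nrow(sweeps) == length(v_cmd_mV), "one command voltage per sweep")
  stop_if_not(length(prepulse_idx) >= 2, "pre-pulse window too short")
  pre <- sweeps[, prepulse_idx, drop = FALSE]
  sds <- apply(pre, 1, stats::sd)
  scale <- diff(range(sweeps))
  if (any(sds > 3 * stats::median(sds) + 1e-9 * max(scale, 1))) {
    warning("pre-pulse window variance is inhomogeneous across sweeps; it may overlap events")
  }
  fit <- stats::lm(rowMeans(pre) ~ v_cmd_mV)
  a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
  list(evoked = sweeps - (a + b * v_cmd_mV), a = a, b = b)
}

#' Peak-to-peak response amplitude
#'
#' The absolute difference between the maximal and minimal membrane
#' potential of a trace; invariant to additive offsets.
#'
#' @param vm numeric voltage trace (mV).
#' @return `max(vm) - min(vm)` in mV (>= 0).
#' @export
delta_vm <- function(vm) {
  stop_if_not(length(vm) >= 1, "empty trace")
  max(vm) - min(vm)
}
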