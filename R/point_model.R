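# Passive single-compartment conductance model of a T4 neuron.
#
# Five columnar input classes drive the cell: glutamatergic Mi9 (inhibitory,
# E_Glu near rest, tonically active in darkness), cholinergic Tm3/Mi1
# (excitatory) and GABAergic Mi4/C3 (delayed inhibitory). Presynaptic
# voltages are min-max normalized, passed through a rectilinear transfer
# function (threshold + gain) and combined as conductances; the membrane
# potential is the conductance-weighted mean of the reversal potentials.
# The cell is electrotonically compact and capacitive currents are small and
# fast relative to synaptic ones, so no differential equation is needed.

#' Synaptic parameters of the single-compartment T4 model
#'
#' Gains and thresholds are dimensionless (thresholds act on min-max
#' normalized presynaptic voltage, so lie in `[0, 1]`); conductances are
#' expressed relative to an arbitrary reference, so only ratios to `g_leak`
#' are physically meaningful (the model is exactly invariant to scaling all
#' gains and `g_leak` by a common factor).
#'
#' @param gains named numeric vector of synaptic gains for
#'   `Mi9, Tm3, Mi1, Mi4, C3` (all >= 0).
#' @param thresholds named numeric vector of transfer thresholds in `[0, 1]`.
#' @param E_Glu,E_ACh,E_GABA synaptic reversal potentials in mV.
#' @param E_leak leak reversal potential in mV.
#' @param g_leak relative leak conductance (> 0).
#' @return an object of class `synaptic_params`.
#' @export
synaptic_params <- function(gains, thresholds, E_Glu = -71, E_ACh = -21,
                            E_GABA = -68, E_leak = -65, g_leak = 0.5) {
  gains <- unlist(gains)[T4_INPUT_CLASSES]
  thresholds <- unlist(thresholds)[T4_INPUT_CLASSES]
  stop_if_not(!anyNA(gains) && all(gains >= 0), "gains must be named >= 0 for all five classes")
  stop_if_not(!anyNA(thresholds) && all(thresholds >= 0 & thresholds <= 1),
              "thresholds must lie in [0, 1] for all five classes")
  stop_if_not(g_leak > 0, "g_leak must be > 0")
  stop_if_not(all(is.finite(c(E_Glu, E_ACh, E_GABA, E_leak))), "reversal potentials must be finite")
  structure(list(gains = gains, thresholds = thresholds, E_Glu = E_Glu,
                 E_ACh = E_ACh, E_GABA = E_GABA, E_leak = E_leak, g_leak = g_leak),
            class = "synaptic_params")
}

#' @export
print.synaptic_params <- function(x, ...) {
  cat("synaptic_params\n  gains:     ",
      paste(sprintf("%s=%.3g", T4_INPUT_CLASSES, x$gains), collapse = " "), "\n",
      "  thresholds:", paste(sprintf("%s=%.3g", T4_INPUT_CLASSES, x$thresholds), collapse = " "), "\n",
      sprintf("  E_Glu=%g E_ACh=%g E_GABA=%g E_leak=%g mV, g_leak=%g\n",
              x$E_Glu, x$E_ACh, x$E_GABA, x$E_leak, x$g_leak))
  invisible(x)
}

#' The fitted reference parameter set of the T4 model
#'
#' Gains 0.92 (Mi9), 0.35 (Tm3), 0.65 (Mi1), 1.10 (Mi4), 1.49 (C3);
#' thresholds 0.20, 0.35, 0.88, 0.44, 0.70; `E_leak` = -65 mV and
#' `g_leak` = 0.5, with reversal potentials `E_Glu` = -71 mV,
#' `E_ACh` = -21 mV and `E_GABA` = -68 mV.
#'
#' @return a `synaptic_params` object.
#' @export
reference_params <- function() {
  synaptic_params(
    gains = c(Mi9 = 0.92, Tm3 = 0.35, Mi1 = 0.65, Mi4 = 1.10, C3 = 1.49),
    thresholds = c(Mi9 = 0.20, Tm3 = 0.35, Mi1 = 0.88, Mi4 = 0.44, C3 = 0.70))
}

#' Read/write synaptic parameters as JSON or YAML
#'
#' The on-disk representation uses the field names of [synaptic_params()]
#' (`gains`, `thresholds`, `E_Glu`, `E_ACh`, `E_GABA`, `E_leak`, `g_leak`).
#'
#' @param params a `synaptic_params` object.
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_synaptic_params` returns a `synaptic_params` object;
#'   `write_synaptic_params` returns `path` invisibly.
#' @export
write_synaptic_params <- function(params, path) {
  x <- list(gains = as.list(params$gains), thresholds = as.list(params$thresholds),
            E_Glu = params$E_Glu, E_ACh = params$E_ACh, E_GABA = params$E_GABA,
            E_leak = params$E_leak, g_leak = params$g_leak)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_synaptic_params
#' @export
read_synaptic_params <- function(path) {
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path) else yaml::read_yaml(path)
  synaptic_params(gains = unlist(x$gains), thresholds = unlist(x$thresholds),
                  E_Glu = x$E_Glu, E_ACh = x$E_ACh, E_GABA = x$E_GABA,
                  E_leak = x$E_leak, g_leak = x$g_leak)
}

#' Joint min-max normalization of presynaptic voltage traces
#'
#' For each input class, a single minimum and maximum are computed jointly
#' over all of that class's stimulus conditions and used to map every trace
#' into `[0, 1]`. This retains the signal ratios across stimuli and makes the
#' output invariant to adding a constant to all traces of a class.
#'
#' @param traces a named list (one element per class); each element is either
#'   a numeric vector or a list of numeric vectors (one per stimulus
#'   condition).
#' @return the same structure with values in `[0, 1]`.
#' @export
normalize_inputs <- function(traces) {
  stop_if_not(is.list(traces) && length(traces) > 0, "traces must be a nonempty list")
  lapply(traces, function(tr) {
    one <- is.numeric(tr)
    if (one) tr <- list(tr)
    rng <- range(unlist(tr), finite = TRUE)
    stop_if_not(diff(rng) > 0, "degenerate input: flat trace (max equals min)")
    out <- lapply(tr, function(v) (v - rng[1]) / diff(rng))
    if (one) out[[1]] else out
  })
}

#' Rectilinear voltage-to-conductance transfer function
#'
#' Converts a normalized presynaptic voltage into a relative postsynaptic
#' conductance using a threshold below which transmission is zero and a gain.
#' Two conventions are supported: the default continuous form
#' `g = gain * max(0, v - threshold)` and a jump form
#' `g = gain * v * (v > threshold)`.
#'
#' @param v_norm numeric vector of normalized voltages in `[0, 1]`.
#' @param threshold transfer threshold in `[0, 1]`.
#' @param gain synaptic gain (>= 0).
#' @param form `"continuous"` (default) or `"jump"`.
#' @return nonnegative conductance vector; zero wherever `v_norm <= threshold`.
#' @export
transfer <- function(v_norm, threshold, gain, form = c("continuous", "jump")) {
  form <- match.arg(form)
  stop_if_not(threshold >= 0 && threshold <= 1, "threshold must lie in [0, 1]")
  stop_if_not(gain >= 0, "gain must be >= 0")
  if (form == "continuous") gain * pmax(0, v_norm - threshold)
  else gain * v_norm * as.numeric(v_norm > threshold)
}

#' Motion-dependent time shift between columnar inputs
#'
#' For an edge moving at angle `phi_deg` relative to the preferred direction,
#' the columnar receptive-field offset of `theta_deg` (the inter-ommatidial
#' angle, 4.8 degrees) translates into a time shift
#' `dt = theta * cos(phi) / v`. Mi9 conductances are advanced and Mi4/C3
#' conductances delayed by this amount relative to Mi1/Tm3.
#'
#' @param phi_deg edge direction in degrees (0 = preferred direction).
#' @param theta_deg columnar spacing in degrees (default 4.8).
#' @param velocity_deg_s edge velocity in degrees per second (default 30).
#' @return time shift in seconds (positive advances Mi9, delays Mi4/C3).
#' @export
motion_delay <- function(phi_deg, theta_deg = 4.8, velocity_deg_s = 30) {
  stop_if_not(velocity_deg_s > 0, "velocity must be > 0")
  theta_deg * cos(phi_deg * pi / 180) / velocity_deg_s
}

#' Construct a conductance set
#'
#' @param g numeric matrix `time x 5` with columns named
#'   `Mi9, Tm3, Mi1, Mi4, C3`, all values >= 0.
#' @param fs sampling rate in Hz.
#' @return an object of class `conductance_set`.
#' @export
conductance_set <- function(g, fs = 1000) {
  g <- as.matrix(g)
  stop_if_not(all(T4_INPUT_CLASSES %in% colnames(g)), "g needs one column per input class")
  g <- g[, T4_INPUT_CLASSES, drop = FALSE]
  stop_if_not(all(g >= 0), "conductances must be >= 0")
  structure(list(g = g, fs = fs), class = "conductance_set")
}

#' Apply the transfer functions of a parameter set to normalized inputs
#'
#' @param v_norm named list of normalized voltage vectors (one per class, a
#'   common time base).
#' @param params a `synaptic_params` object.
#' @param fs sampling rate in Hz.
#' @inheritParams transfer
#' @return a `conductance_set`.
#' @export
input_conductances <- function(v_norm, params, fs = 1000, form = c("continuous", "jump")) {
  form <- match.arg(form)
  g <- vapply(T4_INPUT_CLASSES,
              function(cl) transfer(v_norm[[cl]], params$thresholds[[cl]],
                                    params$gains[[cl]], form),
              numeric(length(v_norm[[T4_INPUT_CLASSES[1]]])))
  conductance_set(g, fs)
}

# bare-metal voltage equation on a time x 5 conductance matrix (columns in
# canonical order); used by the fitting loop where constructor overhead counts
vm_core <- function(g, E_Glu, E_ACh, E_GABA, E_leak, g_leak) {
  num <- E_Glu * g[, 1L] + E_ACh * (g[, 2L] + g[, 3L]) +
    E_GABA * (g[, 4L] + g[, 5L]) + E_leak * g_leak
  den <- g[, 1L] + g[, 2L] + g[, 3L] + g[, 4L] + g[, 5L] + g_leak
  num / den
}

#' Membrane potential of the passive single-compartment T4 model
#'
#' Computes, pointwise in time,
#' `V_m = (E_Glu g_Mi9 + E_ACh (g_Tm3 + g_Mi1) + E_GABA (g_Mi4 + g_C3) +
#' E_leak g_leak) / (sum g + g_leak)`. As a conductance-weighted mean of the
#' reversal potentials, `V_m` is always bounded by the most extreme reversal
#' potentials involved.
#'
#' @param conductances a `conductance_set`.
#' @param params a `synaptic_params` object.
#' @return numeric vector of membrane potential in mV.
#' @export
simulate_vm <- function(conductances, params) {
  stop_if_not(inherits(conductances, "conductance_set"), "need a conductance_set")
  stop_if_not(params$g_leak > 0, "g_leak must be > 0")
  vm_core(conductances$g, params$E_Glu, params$E_ACh, params$E_GABA,
          params$E_leak, params$g_leak)
}

#' Predicted relative input resistance of the model
#'
#' The input resistance is the inverse of the total conductance; relative to
#' a baseline (dark) epoch, `R_rel(t) = (g_leak + sum g_baseline) /
#' (g_leak + sum g(t))`. Values above 1 mark times at which the total
#' conductance falls below its baseline, e.g. when tonic Mi9 inhibition is
#' released.
#'
#' @param conductances a `conductance_set`.
#' @param params a `synaptic_params` object.
#' @param baseline_idx indices of the baseline epoch (default: first sample).
#' @return numeric vector of relative input resistance (baseline = 1).
#' @export
predicted_input_resistance <- function(conductances, params, baseline_idx = 1L) {
  stop_if_not(length(baseline_idx) >= 1, "empty baseline epoch")
  tot <- rowSums(conductances$g) + params$g_leak
  mean(tot[baseline_idx]) / tot
}

#' Supralinearity of coincident excitation and release from inhibition
#'
#' Compares the voltage excursion evoked by the coincidence of an excitatory
#' conductance event and the release of a tonically active inhibitory
#' conductance with the sum of the excursions evoked by each event alone:
#' `index = dV(coincident) - (dV(excitation alone) + dV(release alone))`,
#' each measured from the tonic baseline. A positive index means the two
#' inputs combine supralinearly (multiplication-like disinhibition); in a
#' passive membrane this holds whenever the excitatory reversal potential
#' lies farther from the leak reversal potential than the inhibitory one.
#'
#' @param params a `synaptic_params` object; `E_ACh` is used as the
#'   excitatory and `E_GABA` as the inhibitory reversal potential.
#' @param exc_event numeric vector: excitatory conductance time course
#'   (zero before the event).
#' @param inh_release_event numeric vector: inhibitory conductance time
#'   course; its first sample defines the tonic pre-event level.
#' @return the linearity index in mV (positive = supralinear).
#' @export
linearity_index <- function(params, exc_event, inh_release_event) {
  stop_if_not(length(exc_event) == length(inh_release_event),
              "event traces must share a time base")
  g_inh0 <- inh_release_event[1]
  vm2 <- function(g_e, g_i) {
    (params$E_ACh * g_e + params$E_GABA * g_i + params$E_leak * params$g_leak) /
      (g_e + g_i + params$g_leak)
  }
  v0 <- vm2(0, g_inh0)
  dv <- function(v) { d <- v - v0; d[which.max(abs(d))] }
  d_coinc <- dv(vm2(exc_event, inh_release_event))
  d_exc <- dv(vm2(exc_event, g_inh0))
  d_rel <- dv(vm2(0, inh_release_event))
  if (all(exc_event == 0)) return(0)
  as.numeric(d_coinc - (d_exc + d_rel))
}

#' Closed-form linearity index for peak conductances
#'
#' Steady-state version of [linearity_index()] on scalar peak conductances
#' (full release of inhibition during the coincident event), convenient for
#' brute-force maps over `(g_exc, g_inh)` and arbitrary reversal potentials.
#'
#' @param g_exc,g_inh peak excitatory conductance and tonic inhibitory
#'   conductance (vectorized).
#' @param E_exc,E_inh,E_leak reversal potentials in mV.
#' @param g_leak leak conductance.
#' @return linearity index in mV (vectorized over `g_exc`/`g_inh`).
#' @export
linearity_index_peak <- function(g_exc, g_inh, E_exc = -21, E_inh = -68,
                                 E_leak = -65, g_leak = 1) {
  v0 <- (E_inh * g_inh + E_leak * g_leak) / (g_inh + g_leak)
  v_coinc <- (E_exc * g_exc + E_leak * g_leak) / (g_exc + g_leak)
  v_exc <- (E_exc * g_exc + E_inh * g_inh + E_leak * g_leak) / (g_exc + g_inh + g_leak)
  v_rel <- E_leak
  (v_coinc - v0) - ((v_exc - v0) + (v_rel - v0))
}

#' Directional tuning predicted by the single-compartment model
#'
#' For each direction `phi`, Mi9 conductances are advanced and Mi4/C3
#' conductances delayed by `motion_delay(phi)` relative to Mi1/Tm3 (emulating
#' the columnar receptive-field offsets under edge motion at 30 degrees per
#' second), the model is simulated, and the peak depolarization from the
#' pre-stimulus baseline is recorded.
#'
#' @param v_norm named list of normalized presynaptic voltage traces measured
#'   (or synthesized) for motion through the aligned receptive-field centres.
#' @param params a `synaptic_params` object.
#' @param directions_deg directions in degrees (default 36 directions).
#' @param fs sampling rate of the traces in Hz.
#' @param theta_deg,velocity_deg_s see [motion_delay()].
#' @param mi9_silenced if `TRUE`, the Mi9 gain is set to zero (the "absence
#'   of Mi9" variant, which broadens the tuning curve).
#' @return a [tuning_curve()] of peak response magnitudes (mV) per direction.
#' @export
tuning_prediction <- function(v_norm, params, directions_deg = seq(0, 350, by = 10),
                              fs = 1000, theta_deg = 4.8, velocity_deg_s = 30,
                              mi9_silenced = FALSE) {
  stop_if_not(length(directions_deg) > 0, "direction list must not be empty")
  p <- params
  if (mi9_silenced) p$gains[["Mi9"]] <- 0
  mags <- vapply(directions_deg, function(phi) {
    dt <- motion_delay(phi, theta_deg, velocity_deg_s)
    v <- v_norm
    v$Mi9 <- shift_trace(v$Mi9, -dt, fs)   # advance
    v$Mi4 <- shift_trace(v$Mi4, +dt, fs)   # delay
    v$C3 <- shift_trace(v$C3, +dt, fs)
    vm <- simulate_vm(input_conductances(v, p, fs), p)
    max(vm - vm[1])
  }, numeric(1))
  tuning_curve(directions_deg, pmax(mags, 0))
}
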