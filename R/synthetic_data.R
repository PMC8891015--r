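# Synthetic electrophysiology: presynaptic voltage responses of the five
# columnar input classes, forward-simulated T4 current-clamp episode sets and
# jittered cell populations. The generator reproduces the qualitative
# signatures the analysis relies on -- Mi9 is tonically depolarized in
# darkness and hyperpolarizes at ON (anticorrelated with luminance), Mi1/Tm3
# are fast ON-depolarizing, Mi4/C3 are delayed ON-depolarizing, and the
# columnar receptive fields are offset by one inter-ommatidial angle (4.8
# degrees) along the preferred-direction axis -- without claiming calibrated
# response amplitudes, which the in vivo data do not constrain.

#' Specification of one presynaptic input class
#'
#' @param class_name one of `Mi9, Tm3, Mi1, Mi4, C3`.
#' @param polarity `"ON-depolarizing"` or `"ON-hyperpolarizing"`.
#' @param latency_ms response latency in ms.
#' @param tau_rise_ms,tau_decay_ms time constants of the double-exponential
#'   response kernel (ms).
#' @param rf_center_deg receptive-field centre `c(azimuth, elevation)` in
#'   degrees.
#' @param rf_width_deg Gaussian receptive-field s.d. in degrees (> 0).
#' @param tonic_level_mV membrane potential in darkness (mV).
#' @param amplitude_mV full-drive response amplitude (mV); signed by
#'   polarity. Amplitudes are free generator parameters, not calibrated
#'   measurements.
#' @param noise_sd_mV additive white Gaussian voltage noise s.d. (mV).
#' @return an object of class `input_class_spec`.
#' @export
input_class_spec <- function(class_name, polarity = c("ON-depolarizing", "ON-hyperpolarizing"),
                             latency_ms = 30, tau_rise_ms = 20, tau_decay_ms = 80,
                             rf_center_deg = c(0, 0), rf_width_deg = 5,
                             tonic_level_mV = -55, amplitude_mV = 15, noise_sd_mV = 0) {
  polarity <- match.arg(polarity)
  stop_if_not(class_name %in% T4_INPUT_CLASSES, "unknown input class")
  stop_if_not(rf_width_deg > 0, "rf_width_deg must be > 0")
  stop_if_not(amplitude_mV > 0, "amplitude_mV must be > 0")
  if (class_name == "Mi9") {
    stop_if_not(polarity == "ON-hyperpolarizing", "Mi9 is ON-hyperpolarizing")
  }
  structure(list(class_name = class_name, polarity = polarity, latency_ms = latency_ms,
                 tau_rise_ms = tau_rise_ms, tau_decay_ms = tau_decay_ms,
                 rf_center_deg = as.numeric(rf_center_deg), rf_width_deg = rf_width_deg,
                 tonic_level_mV = tonic_level_mV, amplitude_mV = amplitude_mV,
                 noise_sd_mV = noise_sd_mV),
            class = "input_class_spec")
}

#' Default input-class specifications of the T4 circuit
#'
#' Mi9 is ON-hyperpolarizing with a tonic depolarized level in darkness;
#' Mi1/Tm3 are fast (30 ms) and Mi4/C3 delayed (150 ms) ON-depolarizing.
#' Receptive-field centres are offset along the preferred-direction (PD)
#' axis by one columnar spacing (4.8 degrees): Mi9 occupies the column that
#' PD motion crosses first (upstream; at `-4.8` degrees along the motion
#' vector of a PD stimulus), Mi1/Tm3 the central column and Mi4/C3 the
#' downstream column, so that PD motion releases Mi9 inhibition before the
#' cholinergic drive and recruits GABAergic inhibition last.
#'
#' @param center_deg `c(azimuth, elevation)` of the central (Mi1/Tm3) column.
#' @param pd_deg direction of the PD axis in degrees (0 = towards increasing
#'   azimuth).
#' @param columnar_offset_deg columnar spacing in degrees (default 4.8).
#' @param noise_sd_mV noise s.d. applied to every class (default 0).
#' @return named list of five [input_class_spec()] objects.
#' @export
default_input_specs <- function(center_deg = c(0, 0), pd_deg = 0,
                                columnar_offset_deg = 4.8, noise_sd_mV = 0) {
  u <- c(cos(pd_deg * pi / 180), sin(pd_deg * pi / 180))
  up <- center_deg - columnar_offset_deg * u    # crossed first by PD motion
  down <- center_deg + columnar_offset_deg * u  # crossed last
  list(
    Mi9 = input_class_spec("Mi9", "ON-hyperpolarizing", latency_ms = 30,
                           rf_center_deg = up, tonic_level_mV = -45,
                           amplitude_mV = 12, noise_sd_mV = noise_sd_mV),
    Tm3 = input_class_spec("Tm3", "ON-depolarizing", latency_ms = 25,
                           tau_rise_ms = 15, tau_decay_ms = 60,
                           rf_center_deg = center_deg, tonic_level_mV = -55,
                           amplitude_mV = 16, noise_sd_mV = noise_sd_mV),
    Mi1 = input_class_spec("Mi1", "ON-depolarizing", latency_ms = 35,
                           tau_rise_ms = 25, tau_decay_ms = 100,
                           rf_center_deg = center_deg, tonic_level_mV = -55,
                           amplitude_mV = 14, noise_sd_mV = noise_sd_mV),
    Mi4 = input_class_spec("Mi4", "ON-depolarizing", latency_ms = 140,
                           tau_decay_ms = 150, rf_center_deg = down,
                           tonic_level_mV = -60, amplitude_mV = 12, noise_sd_mV = noise_sd_mV),
    C3 = input_class_spec("C3", "ON-depolarizing", latency_ms = 160,
                          tau_rise_ms = 15, tau_decay_ms = 110, rf_center_deg = down,
                          tonic_level_mV = -60, amplitude_mV = 13, noise_sd_mV = noise_sd_mV))
}

#' Bundle of generative ground truth for recovery experiments
#'
#' @param params a `synaptic_params` object (within the fitting bounds).
#' @param input_specs named list of five [input_class_spec()] objects.
#' @param seed integer seed.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(params = reference_params(),
                         input_specs = default_input_specs(), seed = 1L) {
  b <- fit_bounds()
  th <- c(params$gains, params$thresholds, params$E_leak, params$g_leak)
  stop_if_not(all(th >= b$lower & th <= b$upper),
              "ground-truth parameters must lie within the fitting bounds")
  stop_if_not(all(T4_INPUT_CLASSES %in% names(input_specs)), "need all five input classes")
  structure(list(params = params, input_specs = input_specs, seed = seed),
            class = "ground_truth")
}

# Gaussian receptive-field weighted luminance drive of one class, at the
# movie frame rate
local_luminance <- function(spec, movie) {
  ext <- movie_extent(movie)
  ctr <- spec$rf_center_deg
  stop_if_not(ctr[1] >= ext["az_min"] && ctr[1] <= ext["az_max"] &&
                ctr[2] >= ext["el_min"] && ctr[2] <= ext["el_max"],
              "receptive-field centre outside movie extent")
  az <- pixel_az(movie); el <- pixel_el(movie)
  w <- outer(stats::dnorm(el, ctr[2], spec$rf_width_deg),
             stats::dnorm(az, ctr[1], spec$rf_width_deg))
  w <- as.numeric(w / sum(w))
  nt <- dim(movie$frames)[1]
  as.numeric(matrix(movie$frames, nrow = nt) %*% w)
}

# unit-area double-exponential kernel at fs; steady-state response to a
# sustained unit drive is 1
double_exp_kernel <- function(tau_rise_ms, tau_decay_ms, fs) {
  t <- seq(0, (tau_decay_ms + 6 * max(tau_rise_ms, tau_decay_ms)) / 1000, by = 1 / fs)
  h <- exp(-t * 1000 / tau_decay_ms) - exp(-t * 1000 / tau_rise_ms)
  h / sum(h)
}

# ground-truth physiological voltage range of a class: [tonic - amp, tonic]
# for ON-hyperpolarizing classes, [tonic, tonic + amp] otherwise
class_voltage_range <- function(spec) {
  if (spec$polarity == "ON-hyperpolarizing") {
    c(spec$tonic_level_mV - spec$amplitude_mV, spec$tonic_level_mV)
  } else {
    c(spec$tonic_level_mV, spec$tonic_level_mV + spec$amplitude_mV)
  }
}

#' Synthetic presynaptic voltage response to a stimulus movie
#'
#' The local luminance in the class's Gaussian receptive field is converted
#' to a rectified contrast drive (relative to the mean screen luminance),
#' filtered with a latency-shifted double-exponential kernel, scaled by the
#' class amplitude with the sign of its polarity, added to the tonic level
#' and corrupted with additive white Gaussian noise. With zero noise the
#' trace is deterministic; ON-hyperpolarizing Mi9 holds its tonic
#' depolarized level in darkness and hyperpolarizes at ON.
#'
#' @param spec an [input_class_spec()].
#' @param movie a `stimulus_movie` whose extent contains the class's
#'   receptive-field centre.
#' @param fs_out output sampling rate in Hz (default 1000).
#' @param seed integer seed for the noise (required when `noise_sd_mV > 0`).
#' @return numeric voltage trace in mV at `fs_out`.
#' @export
synth_presyn_response <- function(spec, movie, fs_out = 1000, seed = NULL) {
  L <- local_luminance(spec, movie)
  v <- resample_trace(L, movie$frame_rate, fs_out)
  drive <- pmin(pmax(2 * (v - 0.5), 0), 1)  # rectified contrast re mean luminance
  h <- double_exp_kernel(spec$tau_rise_ms, spec$tau_decay_ms, fs_out)
  resp <- stats::filter(c(rep(drive[1], length(h)), drive), h, method = "convolution",
                        sides = 1)
  resp <- as.numeric(resp)[length(h) + seq_along(drive)]
  resp <- shift_trace(resp, spec$latency_ms / 1000, fs_out)
  sgn <- if (spec$polarity == "ON-hyperpolarizing") -1 else 1
  out <- spec$tonic_level_mV + sgn * spec$amplitude_mV * resp
  if (spec$noise_sd_mV > 0) {
    stop_if_not(!is.null(seed), "a seed is required for noisy traces")
    out <- out + with_local_seed(seed, stats::rnorm(length(out), 0, spec$noise_sd_mV))
  }
  out
}

# noiseless, ground-truth-normalized presynaptic conductance drive for all
# classes; normalization uses each class's known physiological range so that
# stimuli that do not span the range (e.g. darkness) remain well defined
presyn_norm_gt <- function(gt, movie, fs = 1000) {
  specs <- gt$input_specs[T4_INPUT_CLASSES]
  v <- lapply(specs, function(s) {
    s$noise_sd_mV <- 0
    rng <- class_voltage_range(s)
    pmin(pmax((synth_presyn_response(s, movie, fs) - rng[1]) / diff(rng), 0), 1)
  })
  names(v) <- T4_INPUT_CLASSES
  v
}

#' Synthetic T4 current-clamp episode set
#'
#' For each holding current, one sweep is generated as the forward simulation
#' of the ground-truth single-compartment circuit plus the holding-current
#' voltage offset `I_hold * R_in(t)` and additive Gaussian noise. `R_in(t)`
#' follows the model's total conductance, scaled so that its dark-state value
#' equals `baseline_Rin_GOhm` (5.28 GOhm, the wild-type mean, by default):
#' `R_in(t) = baseline * g_total(dark) / g_total(t)`.
#'
#' @param gt a [ground_truth()] bundle.
#' @param movie a `stimulus_movie`.
#' @param holding_currents_pA holding currents in pA, within `[-10, 0]`.
#' @param baseline_Rin_GOhm dark-state input resistance in GOhm.
#' @param noise_sd_mV additive voltage noise s.d. (mV).
#' @param fs sampling rate in Hz.
#' @param seed integer seed.
#' @return an [episode_set()]; attributes `vm_model` and `rin_GOhm` carry the
#'   noise-free zero-current voltage and the ground-truth resistance trace.
#' @export
synth_t4_episode_set <- function(gt, movie, holding_currents_pA = c(-5, 0),
                                 baseline_Rin_GOhm = 5.28, noise_sd_mV = 0,
                                 fs = 1000, seed = 1L) {
  stop_if_not(length(holding_currents_pA) >= 1, "empty holding-current list")
  stop_if_not(all(holding_currents_pA >= -10 & holding_currents_pA <= 0),
              "holding currents must lie in [-10, 0] pA")
  v_norm <- presyn_norm_gt(gt, movie, fs)
  cond <- input_conductances(v_norm, gt$params, fs)
  vm <- simulate_vm(cond, gt$params)
  g_tot <- rowSums(cond$g) + gt$params$g_leak
  # dark state: all classes at their darkness drive (first sample is dark for
  # movies that begin with a uniform dark/adapted frame)
  rin <- baseline_Rin_GOhm * g_tot[1] / g_tot
  sweeps <- matrix(NA_real_, length(holding_currents_pA), length(vm))
  for (i in seq_along(holding_currents_pA)) {
    sweep <- vm + holding_currents_pA[i] * rin
    if (noise_sd_mV > 0) {
      sweep <- sweep + with_local_seed(substream_seed(seed, i),
                                       stats::rnorm(length(sweep), 0, noise_sd_mV))
    }
    sweeps[i, ] <- sweep
  }
  es <- episode_set(sweeps, holding_currents_pA, fs, stimulus_id = "synthetic-edge")
  attr(es, "vm_model") <- vm
  attr(es, "rin_GOhm") <- rin
  es
}

#' Synthetic population of T4 cells with jittered receptive fields
#'
#' All cells share the same generative circuit but have receptive-field
#' centres jittered on the screen and preferred directions drawn from a
#' given set. Each cell's white-noise membrane-potential response is
#' forward-simulated, and the metadata records the true offsets and PDs so
#' that alignment and receptive-field recovery can be scored against ground
#' truth.
#'
#' @param n_cells number of cells (>= 1).
#' @param rf_scatter_deg s.d. of the receptive-field centre jitter (degrees).
#' @param pd_distribution vector of preferred directions (degrees) sampled
#'   uniformly per cell.
#' @param gt a [ground_truth()] bundle (its input specs define the column
#'   layout relative to each cell's centre).
#' @param movie a `stimulus_movie` (typically white noise).
#' @param center_deg mean receptive-field centre on the screen.
#' @param fs sampling rate in Hz.
#' @param noise_sd_mV additive voltage noise per cell (mV).
#' @param seed integer seed.
#' @return list of cells, each with `vm`, `fs`, `true_offset_deg`,
#'   `true_pd_deg`.
#' @export
synth_population <- function(n_cells, rf_scatter_deg = 0, pd_distribution = 0,
                             gt = ground_truth(), movie, center_deg = c(0, 0),
                             fs = 1000, noise_sd_mV = 0, seed = 1L) {
  stop_if_not(n_cells >= 1, "n_cells must be >= 1")
  draws <- with_local_seed(seed, list(
    off = matrix(stats::rnorm(2 * n_cells, 0, rf_scatter_deg), ncol = 2),
    pd = sample(rep(pd_distribution, length.out = max(n_cells, length(pd_distribution))),
                n_cells, replace = TRUE)))
  lapply(seq_len(n_cells), function(i) {
    ctr <- center_deg + draws$off[i, ]
    specs <- default_input_specs(center_deg = ctr, pd_deg = draws$pd[i])
    gti <- gt
    gti$input_specs <- specs
    v_norm <- presyn_norm_gt(gti, movie, fs)
    vm <- simulate_vm(input_conductances(v_norm, gt$params, fs), gt$params)
    if (noise_sd_mV > 0) {
      vm <- vm + with_local_seed(substream_seed(seed, 1000 + i),
                                 stats::rnorm(length(vm), 0, noise_sd_mV))
    }
    list(vm = vm, fs = fs, true_offset_deg = ctr - center_deg, true_pd_deg = draws$pd[i])
  })
}

#' Aligned presynaptic drives for tuning predictions
#'
#' Emulates the aligned single-column measurement underlying direction
#' tuning predictions: every input class responds to the same edge crossing
#' its own receptive-field centre (i.e. all centres co-located), so the
#' traces carry no columnar time shifts. [tuning_prediction()] then applies
#' the direction-dependent shifts `motion_delay(phi)` synthetically.
#'
#' @param gt a [ground_truth()] bundle.
#' @param polarity `"ON"` or `"OFF"` edge.
#' @param fs sampling rate in Hz.
#' @param velocity_deg_s edge speed (default 30).
#' @return named list of normalized class drives on a common time base.
#' @export
synth_aligned_inputs <- function(gt, polarity = "ON", fs = 1000, velocity_deg_s = 30) {
  ext <- c(0, 33.6, 0, 8.4)
  ctr <- c(16.8, 4.2)
  specs <- default_input_specs(center_deg = ctr, pd_deg = 0, columnar_offset_deg = 0)
  gta <- gt
  gta$input_specs <- specs
  mv <- make_edge(edge_spec(polarity, 0, velocity_deg_s, ext),
                  frame_rate = 60, pixel_pitch = 2.8, pre_s = 0.4, post_s = 0.4)
  presyn_norm_gt(gta, mv, fs)
}

#' Synthetic four-condition stimulus/response set for model fitting
#'
#' Builds the four standard conditions (ON and OFF edges moving in the
#' preferred and in the null direction at 30 degrees per second through the
#' circuit's receptive fields), returns the jointly min-max normalized
#' presynaptic drives and the ground-truth T4 voltage responses with
#' optional additive noise. This is the input contract of the fitting and
#' posterior-sampling routines.
#'
#' @param gt a [ground_truth()] bundle.
#' @param fs sampling rate in Hz.
#' @param noise_sd_mV noise added to the T4 voltage traces (mV).
#' @param velocity_deg_s edge speed (default 30).
#' @param seed integer seed.
#' @return list with `v_norm` (per condition: named list of normalized class
#'   drives), `t4` (per condition: T4 voltage trace), `vm_true` (noise-free
#'   responses), `fs` and `conditions`.
#' @export
synth_condition_set <- function(gt, fs = 1000, noise_sd_mV = 0,
                                velocity_deg_s = 30, seed = 1L) {
  ext <- c(0, 33.6, 0, 8.4)  # 12 x 3 px corridor; columns sit mid-field
  ctr <- c(16.8, 4.2)
  specs <- default_input_specs(center_deg = ctr, pd_deg = 0)
  gtl <- gt
  gtl$input_specs <- specs
  conds <- list(
    ON_PD = edge_spec("ON", 0, velocity_deg_s, ext),
    ON_ND = edge_spec("ON", 180, velocity_deg_s, ext),
    OFF_PD = edge_spec("OFF", 0, velocity_deg_s, ext),
    OFF_ND = edge_spec("OFF", 180, velocity_deg_s, ext))
  v_norm <- lapply(conds, function(sp) {
    presyn_norm_gt(gtl, make_edge(sp, frame_rate = 60, pixel_pitch = 2.8,
                                  pre_s = 0.3, post_s = 0.3), fs)
  })
  vm_true <- lapply(v_norm, function(v) simulate_vm(input_conductances(v, gt$params, fs),
                                                    gt$params))
  t4 <- vm_true
  if (noise_sd_mV > 0) {
    t4 <- lapply(seq_along(vm_true), function(i) {
      vm_true[[i]] + with_local_seed(substream_seed(seed, i),
                                     stats::rnorm(length(vm_true[[i]]), 0, noise_sd_mV))
    })
    names(t4) <- names(vm_true)
  }
  list(v_norm = v_norm, t4 = t4, vm_true = vm_true, fs = fs, conditions = names(conds))
}
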