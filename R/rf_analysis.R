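# Reverse-correlation receptive fields, z-scoring/screening/averaging, and
# directional tuning statistics (preferred direction, L_dir, Voigt-profile
# response amplitudes).

#' Construct a directional tuning curve
#'
#' @param phi_deg direction angles in degrees.
#' @param magnitude nonnegative response magnitudes (mV or normalized).
#' @param normalized logical flag: magnitudes are min-max normalized.
#' @return an object of class `tuning_curve` (a data frame with columns
#'   `phi_deg` and `magnitude`).
#' @export
tuning_curve <- function(phi_deg, magnitude, normalized = FALSE) {
  stop_if_not(length(phi_deg) == length(magnitude), "phi and magnitude lengths differ")
  stop_if_not(all(magnitude >= 0), "magnitudes must be >= 0")
  structure(data.frame(phi_deg = as.numeric(phi_deg) %% 360, magnitude = magnitude),
            normalized = normalized, class = c("tuning_curve", "data.frame"))
}

#' Remove slow voltage drift from a membrane-potential trace
#'
#' Subtracts a zero-phase Gaussian low-pass filtered version of the signal
#' (default standard deviation 60 s), removing electrode drift while leaving
#' stimulus-evoked fluctuations intact.
#'
#' @param vm numeric voltage trace (mV).
#' @param fs sampling rate in Hz.
#' @param sigma_s filter standard deviation in seconds (default 60).
#' @return drift-corrected trace with approximately zero mean on long
#'   stationary recordings.
#' @export
drift_correct <- function(vm, fs, sigma_s = 60) {
  vm - gaussian_smooth(vm, sigma_s * fs)
}

#' Spatiotemporal receptive field by reverse correlation
#'
#' Computes `K(x, tau) = sum_t S(x, t - tau) * V_m(t) * dt` for lags `tau`
#' covering `lag_range_s` at the stimulus frame rate. `V_m` should be
#' baseline-subtracted (e.g. drift-corrected) and is resampled to the
#' stimulus clock, making the kernel independent of the physiological
#' sampling rate. The correlation is linear in `V_m`.
#'
#' @param movie a `stimulus_movie`.
#' @param vm voltage trace in mV, time-locked to the movie (first sample at
#'   the first frame).
#' @param fs_vm sampling rate of `vm` in Hz (default: the movie frame rate).
#' @param lag_range_s lag window in seconds (default `c(-0.5, 3)`).
#' @return an object of class `spatiotemporal_rf` with fields `K`
#'   (array `elevation x azimuth x lag`), `lags_s`, `pixel_pitch`, `origin`
#'   and `frame_rate`.
#' @export
reverse_correlate <- function(movie, vm, fs_vm = movie$frame_rate,
                              lag_range_s = c(-0.5, 3)) {
  stop_if_not(inherits(movie, "stimulus_movie"), "movie must be a stimulus_movie")
  fr <- movie$frame_rate
  v <- resample_trace(vm, fs_vm, fr)
  nt <- dim(movie$frames)[1]
  if (length(v) < nt && length(v) >= nt - 2) {  # resampling boundary slack
    v <- c(v, rep(v[length(v)], nt - length(v)))
  }
  stop_if_not(length(v) >= nt, "vm shorter than the stimulus")
  v <- v[seq_len(nt)]
  lag_idx <- seq.int(round(lag_range_s[1] * fr), round(lag_range_s[2] * fr))
  stop_if_not(nt > max(abs(lag_idx)), "vm shorter than the maximum lag")
  n_el <- dim(movie$frames)[2]; n_az <- dim(movie$frames)[3]
  S <- matrix(movie$frames, nrow = nt)
  K <- array(0, dim = c(n_el, n_az, length(lag_idx)))
  dt <- 1 / fr
  for (j in seq_along(lag_idx)) {
    l <- lag_idx[j]
    tt <- seq.int(max(1L, 1L + l), min(nt, nt + l))
    K[, , j] <- matrix(crossprod(S[tt - l, , drop = FALSE], v[tt]) * dt, n_el, n_az)
  }
  structure(list(K = K, lags_s = lag_idx / fr, pixel_pitch = movie$pixel_pitch,
                 origin = movie$origin, frame_rate = fr,
                 screen_extent = movie_extent(movie)),
            class = "spatiotemporal_rf")
}

#' Z-score, screen and centre a receptive field
#'
#' Converts the kernel into standard scores (relative to the mean and s.d. of
#' a reference region, by default the whole kernel), locates the extremum
#' (the maximum or minimum with the highest absolute value) and applies the
#' two inclusion criteria: a clear peak (at least `peak_sd` standard
#' deviations) and a receptive-field centre at least `edge_margin_deg` from
#' the screen bezel. Accepted kernels are re-referenced in space so that the
#' extremum sits at 0 degrees. Rejection is a typed outcome (an object with
#' `accepted = FALSE` and a `reason`), not an error.
#'
#' @param rf a `spatiotemporal_rf`.
#' @param peak_sd peak criterion in standard deviations (default 4).
#' @param edge_margin_deg minimum distance of the centre from the screen edge
#'   in degrees (default 22.48, i.e. 8 pixels of 2.8 degrees).
#' @param reference z-scoring reference region: `"all"` (whole kernel,
#'   default) or `"prezero"` (negative lags only).
#' @return an object of class `rf_screen`: the input plus `z` (z-scored
#'   kernel), `extremum` (indices, location in degrees, z value, sign),
#'   `accepted` and `reason`.
#' @export
zscore_center_filter <- function(rf, peak_sd = 4, edge_margin_deg = 22.48,
                                 reference = c("all", "prezero")) {
  reference <- match.arg(reference)
  ref <- if (reference == "all") rf$K else rf$K[, , rf$lags_s < 0, drop = FALSE]
  z <- (rf$K - mean(ref)) / stats::sd(ref)
  idx <- arrayInd(which.max(abs(z)), dim(z))
  zpk <- z[idx[1], idx[2], idx[3]]
  az <- rf$origin[1] + (idx[2] - 1) * rf$pixel_pitch
  el <- rf$origin[2] + (idx[1] - 1) * rf$pixel_pitch
  ext <- rf$screen_extent
  edge_dist <- min(az - ext["az_min"], ext["az_max"] - az,
                   el - ext["el_min"], ext["el_max"] - el)
  out <- rf
  out$z <- z
  out$extremum <- list(el_idx = idx[1], az_idx = idx[2], lag_idx = idx[3],
                       az_deg = az, el_deg = el, lag_s = rf$lags_s[idx[3]],
                       z = zpk, sign = sign(zpk))
  if (abs(zpk) < peak_sd) {
    out$accepted <- FALSE
    out$reason <- sprintf("peak %.2f s.d. below the %g s.d. criterion", abs(zpk), peak_sd)
  } else if (edge_dist < edge_margin_deg) {
    out$accepted <- FALSE
    out$reason <- sprintf("centre %.2f deg from the bezel (< %g deg)", edge_dist, edge_margin_deg)
  } else {
    out$accepted <- TRUE
    out$reason <- "accepted"
    out$origin <- c(rf$origin[1] - az, rf$origin[2] - el)  # extremum at 0 deg
  }
  class(out) <- c("rf_screen", "spatiotemporal_rf")
  out
}

# bilinear sampling of map (rows = el, cols = az) at scattered points;
# points outside the grid return NA
sample_map <- function(map, az, el, az_p, el_p) {
  pracma::interp2(x = az, y = el, Z = map, xp = pmin(pmax(az_p, min(az)), max(az)),
                  yp = pmin(pmax(el_p, min(el)), max(el)), method = "linear")
}

#' Average centred spatial receptive fields across cells
#'
#' Takes the spatial z-score map of each (accepted, centred) receptive field
#' at its extremum lag, optionally rotates each map so that the cell's
#' preferred direction points along 0 degrees, crops all maps to the largest
#' common region holding data from every cell, averages, upsamples by linear
#' interpolation and smooths with a Gaussian filter.
#'
#' @param rfs list of `rf_screen` objects (accepted ones).
#' @param upsample integer upsampling factor (default 10).
#' @param smooth_sd_px Gaussian smoothing s.d. in original pixels
#'   (default 1.8).
#' @param rotate_to_pd logical; rotate each map by its cell's preferred
#'   direction before averaging.
#' @param pd_deg numeric vector of preferred directions (required when
#'   `rotate_to_pd = TRUE`).
#' @return a list with the averaged `map` (matrix elevation x azimuth),
#'   axes `az_deg`, `el_deg` and the pre-smoothing average `map_raw`.
#' @export
average_rfs <- function(rfs, upsample = 10, smooth_sd_px = 1.8,
                        rotate_to_pd = FALSE, pd_deg = NULL) {
  stop_if_not(length(rfs) >= 1, "need at least one receptive field")
  if (rotate_to_pd) stop_if_not(length(pd_deg) == length(rfs), "one PD per cell required")
  maps <- lapply(seq_along(rfs), function(i) {
    rf <- rfs[[i]]
    m <- rf$z[, , rf$extremum$lag_idx]
    az <- rf$origin[1] + (seq_len(ncol(m)) - 1) * rf$pixel_pitch
    el <- rf$origin[2] + (seq_len(nrow(m)) - 1) * rf$pixel_pitch
    list(map = m, az = az, el = el, pitch = rf$pixel_pitch)
  })
  pitch <- maps[[1]]$pitch
  # largest common region around the (centred) extremum
  az_lo <- max(vapply(maps, function(m) min(m$az), 0))
  az_hi <- min(vapply(maps, function(m) max(m$az), 0))
  el_lo <- max(vapply(maps, function(m) min(m$el), 0))
  el_hi <- min(vapply(maps, function(m) max(m$el), 0))
  stop_if_not(az_hi >= az_lo && el_hi >= el_lo, "no common spatial region")
  az_c <- seq(az_lo, az_hi, by = pitch)
  el_c <- seq(el_lo, el_hi, by = pitch)
  acc <- matrix(0, length(el_c), length(az_c))
  grid_az <- matrix(az_c, length(el_c), length(az_c), byrow = TRUE)
  grid_el <- matrix(el_c, length(el_c), length(az_c))
  for (i in seq_along(maps)) {
    m <- maps[[i]]
    if (rotate_to_pd) {
      # sample the source map at coordinates rotated by +PD so that the
      # cell's PD maps onto the 0-degree axis of the common grid
      a <- pd_deg[i] * pi / 180
      src_az <- cos(a) * grid_az - sin(a) * grid_el
      src_el <- sin(a) * grid_az + cos(a) * grid_el
      vals <- sample_map(m$map, m$az, m$el, as.numeric(src_az), as.numeric(src_el))
      acc <- acc + matrix(vals, length(el_c), length(az_c))
    } else {
      vals <- sample_map(m$map, m$az, m$el, as.numeric(grid_az), as.numeric(grid_el))
      acc <- acc + matrix(vals, length(el_c), length(az_c))
    }
  }
  avg <- acc / length(maps)
  # upsample by linear interpolation, then Gaussian-smooth
  az_u <- seq(min(az_c), max(az_c), length.out = (length(az_c) - 1) * upsample + 1)
  el_u <- seq(min(el_c), max(el_c), length.out = (length(el_c) - 1) * upsample + 1)
  up <- matrix(sample_map(avg, az_c, el_c,
                          as.numeric(matrix(az_u, length(el_u), length(az_u), byrow = TRUE)),
                          as.numeric(matrix(el_u, length(el_u), length(az_u)))),
               length(el_u), length(az_u))
  sm <- up
  sd_up <- smooth_sd_px * upsample
  if (sd_up > 0 && min(dim(up)) > 1) {
    for (r in seq_len(nrow(sm))) sm[r, ] <- gaussian_smooth(sm[r, ], sd_up)
    for (c in seq_len(ncol(sm))) sm[, c] <- gaussian_smooth(sm[, c], sd_up)
  }
  list(map = sm, az_deg = az_u, el_deg = el_u, map_raw = avg,
       az_deg_raw = az_c, el_deg_raw = el_c)
}

#' Preferred direction as the resultant of direction-tagged response vectors
#'
#' Each response magnitude defines a Euclidean vector pointing in its
#' stimulus direction; the preferred direction (PD) is the direction of the
#' resultant of all vectors. A vanishing resultant (e.g. perfectly symmetric
#' responses) yields a typed "undefined PD" outcome.
#'
#' @param magnitude nonnegative response magnitudes.
#' @param phi_deg stimulus directions in degrees (same length).
#' @return a list with `pd_deg` (in `[0, 360)`, `NA` if undefined),
#'   `defined` and `resultant` (the resultant magnitude).
#' @export
preferred_direction <- function(magnitude, phi_deg) {
  stop_if_not(length(magnitude) >= 2, "need at least two directions")
  stop_if_not(all(magnitude >= 0), "magnitudes must be >= 0")
  a <- phi_deg * pi / 180
  x <- sum(magnitude * cos(a)); y <- sum(magnitude * sin(a))
  r <- sqrt(x^2 + y^2)
  if (r < 1e-9 * max(sum(magnitude), 1e-300)) {
    return(list(pd_deg = NA_real_, defined = FALSE, resultant = 0))
  }
  list(pd_deg = (atan2(y, x) * 180 / pi) %% 360, defined = TRUE, resultant = r)
}

#' Directional tuning index L_dir
#'
#' `L_dir = | sum_phi v(phi) / sum_phi |v(phi)| |`: the magnitude of the
#' resultant vector divided by the sum of the individual vectors'
#' magnitudes. Lies in `[0, 1]`; 1 when all response mass points in a single
#' direction, 0 under full symmetry.
#'
#' @inheritParams preferred_direction
#' @return scalar in `[0, 1]`.
#' @export
ldir <- function(magnitude, phi_deg) {
  stop_if_not(all(magnitude >= 0), "magnitudes must be >= 0")
  stop_if_not(any(magnitude > 0), "all-zero responses: L_dir undefined")
  a <- phi_deg * pi / 180
  sqrt(sum(magnitude * cos(a))^2 + sum(magnitude * sin(a))^2) / sum(magnitude)
}

# Faddeeva function w(z) = exp(-z^2) erfc(-iz) for Im(z) >= 0, by Humlicek's
# four-region rational approximation (relative accuracy ~1e-4, the standard
# scheme for Voigt line-shape evaluation; the naive erf route overflows for
# near-real arguments).
faddeeva_w <- function(z) {
  x <- Re(z); y <- Im(z)
  t <- complex(real = y, imaginary = -x)
  s <- abs(x) + y
  w <- complex(length.out = length(z))
  r1 <- s >= 15
  if (any(r1)) {
    tt <- t[r1]
    w[r1] <- tt * 0.5641896 / (0.5 + tt * tt)
  }
  r2 <- !r1 & s >= 5.5
  if (any(r2)) {
    tt <- t[r2]; u <- tt * tt
    w[r2] <- tt * (1.410474 + u * 0.5641896) / (0.75 + u * (3 + u))
  }
  r3 <- !r1 & !r2 & (y >= 0.195 * abs(x) - 0.176)
  if (any(r3)) {
    tt <- t[r3]
    w[r3] <- (16.4955 + tt * (20.20933 + tt * (11.96482 + tt * (3.778987 + tt * 0.5642236)))) /
      (16.4955 + tt * (38.82363 + tt * (39.27121 + tt * (21.69274 + tt * (6.699398 + tt)))))
  }
  r4 <- !r1 & !r2 & !r3
  if (any(r4)) {
    tt <- t[r4]; u <- tt * tt
    num <- tt * (36183.31 - u * (3321.9905 - u * (1540.787 - u * (219.0313 - u *
             (35.76683 - u * (1.320522 - u * 0.56419))))))
    den <- 32066.6 - u * (24322.84 - u * (9022.228 - u * (2186.181 - u *
             (364.2191 - u * (61.57037 - u * (1.841439 - u))))))
    w[r4] <- exp(u) - num / den
  }
  w
}

#' Voigt profile (Gaussian-Lorentzian convolution), peak-normalized
#'
#' Evaluated through the Faddeeva function `w(z) = exp(-z^2) erfc(-iz)`
#' (Humlicek's rational approximation); reduces to a Gaussian for
#' `gamma = 0` and to a Lorentzian for `sigma -> 0`.
#'
#' @param x abscissa.
#' @param center profile centre.
#' @param sigma Gaussian standard deviation (>= 0).
#' @param gamma Lorentzian half-width (>= 0).
#' @return profile values scaled to 1 at `center`.
#' @export
voigt_profile <- function(x, center, sigma, gamma) {
  sigma <- abs(sigma); gamma <- abs(gamma)
  if (sigma < 1e-12) {            # pure Lorentzian limit
    if (gamma < 1e-12) return(as.numeric(x == center))
    return(gamma^2 / ((x - center)^2 + gamma^2))
  }
  z <- complex(real = (x - center) / (sigma * sqrt(2)),
               imaginary = rep(gamma / (sigma * sqrt(2)), length(x)))
  z0 <- complex(real = 0, imaginary = gamma / (sigma * sqrt(2)))
  Re(faddeeva_w(z)) / Re(faddeeva_w(z0))
}

# fit offset + amplitude * voigt(t) on a window; returns fitted peak height
# (amplitude above offset) or NA on failure
fit_voigt_peak <- function(t, y) {
  win <- diff(range(t))
  resid_fn <- function(p) y - (p[5] + p[1] * voigt_profile(t, p[2], p[3], p[4]))
  out <- try(suppressWarnings(minpack.lm::nls.lm(
    par = c(amp = max(y) - min(y), ctr = t[which.max(y)], sg = win / 8,
            gm = 1e-3 * win, off = min(y)),
    lower = c(0, min(t), 1e-6 * win, 0, -Inf),
    upper = c(Inf, max(t), 2 * win, 2 * win, Inf),
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 200))), silent = TRUE)
  if (inherits(out, "try-error") || !out$info %in% 1:4 || !all(is.finite(out$par))) {
    return(NA_real_)
  }
  unname(out$par[1])
}

#' Directional tuning from moving-edge episodes
#'
#' For each direction, subtracts the 1 s pre-stimulus baseline, locates the
#' raw peak response and fits a Voigt profile to the membrane potential in a
#' 700 ms window surrounding it; the response magnitude `|v(phi)|` is the
#' maximum of the fitted profile. If the fit does not converge the raw peak
#' amplitude is used instead (with a warning). Optionally the curve is
#' aligned post hoc so that the preferred direction sits at 0 degrees and
#' min-max normalized.
#'
#' @param episodes named list: direction (degrees, as names) -> mean voltage
#'   trace (mV), stimulus-locked, including a 1 s pre-stimulus baseline.
#' @param fs sampling rate in Hz.
#' @param window_ms width of the fit window around the raw peak (default 700).
#' @param baseline_s pre-stimulus baseline duration in seconds (default 1).
#' @param normalize align the PD to 0 degrees and min-max normalize.
#' @return a [tuning_curve()]; attributes `pd_deg` and `ldir` carry the
#'   preferred direction and tuning index of the unaligned curve.
#' @export
tuning_from_edges <- function(episodes, fs, window_ms = 700, baseline_s = 1,
                              normalize = FALSE) {
  stop_if_not(length(episodes) >= 1, "no episodes given")
  phi <- as.numeric(names(episodes))
  stop_if_not(!anyNA(phi), "episode names must be directions in degrees")
  half <- round(window_ms / 2000 * fs)
  mags <- vapply(seq_along(episodes), function(i) {
    v <- episodes[[i]]
    nb <- max(1L, min(round(baseline_s * fs), length(v) - 1L))
    y <- v - mean(v[seq_len(nb)])
    ipk <- which.max(y)
    sel <- max(1L, ipk - half):min(length(y), ipk + half)
    a <- fit_voigt_peak((sel - ipk) / fs, y[sel])
    if (is.na(a)) {
      warning("Voigt fit did not converge; using raw peak amplitude")
      a <- max(y)
    }
    max(a, 0)
  }, numeric(1))
  pd <- if (length(phi) >= 2) preferred_direction(mags, phi)
        else list(pd_deg = phi[1], defined = FALSE, resultant = mags[1])
  l <- if (any(mags > 0) && length(phi) >= 2) ldir(mags, phi) else NA_real_
  if (normalize) {
    if (pd$defined) {
      shift <- phi[which.min(abs(((phi - pd$pd_deg + 180) %% 360) - 180))]
      phi <- (phi - shift) %% 360
    }
    rng <- range(mags)
    if (diff(rng) > 0) mags <- (mags - rng[1]) / diff(rng)
  }
  tc <- tuning_curve(phi, mags, normalized = normalize)
  attr(tc, "pd_deg") <- pd$pd_deg
  attr(tc, "ldir") <- l
  tc
}

#' Write a tuning curve to CSV
#' @param tc a `tuning_curve`.
#' @param path output file.
#' @export
write_tuning_curve <- function(tc, path) {
  utils::write.csv(as.data.frame(tc), path, row.names = FALSE)
  invisible(path)
}
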