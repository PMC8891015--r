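# Visual stimulus generation: spatiotemporal binary white noise, moving ON/OFF
# contrast edges and drifting square-wave gratings on a flat virtual screen
# (azimuth/elevation in degrees), plus a photodiode-style luminance readout.

#' Construct a stimulus movie
#'
#' A `stimulus_movie` is a luminance array over `(time, elevation, azimuth)`
#' with values in `[0, 1]`, a uniform frame rate and a square pixel pitch.
#' Time is always the first array axis.
#'
#' @param frames numeric array `time x elevation x azimuth`, values in `[0,1]`.
#' @param frame_rate frames per second (> 0).
#' @param pixel_pitch pixel size in degrees (> 0).
#' @param origin angular coordinate `c(azimuth, elevation)` in degrees of the
#'   centre of pixel `(1, 1)`.
#' @return an object of class `stimulus_movie`.
#' @export
stimulus_movie <- function(frames, frame_rate, pixel_pitch, origin = c(0, 0)) {
  stop_if_not(is.array(frames) && length(dim(frames)) == 3, "frames must be a 3-d array")
  stop_if_not(all(is.finite(frames)) && min(frames) >= 0 && max(frames) <= 1,
              "luminance values must lie in [0, 1]")
  stop_if_not(is.numeric(frame_rate) && frame_rate > 0, "frame_rate must be > 0")
  stop_if_not(is.numeric(pixel_pitch) && pixel_pitch > 0, "pixel_pitch must be > 0")
  structure(list(frames = frames, frame_rate = frame_rate,
                 pixel_pitch = pixel_pitch, origin = as.numeric(origin)),
            class = "stimulus_movie")
}

#' @export
print.stimulus_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("stimulus_movie: %d frames (%.1f s at %g Hz), %d x %d px of %g deg\n",
              d[1], d[1] / x$frame_rate, x$frame_rate, d[3], d[2], x$pixel_pitch))
  invisible(x)
}

#' Frame time stamps of a movie (seconds, first frame at t = 0)
#' @param movie a `stimulus_movie`.
#' @export
movie_times <- function(movie) (seq_len(dim(movie$frames)[1]) - 1) / movie$frame_rate

# pixel-centre coordinates in degrees
pixel_az <- function(movie) movie$origin[1] + (seq_len(dim(movie$frames)[3]) - 1) * movie$pixel_pitch
pixel_el <- function(movie) movie$origin[2] + (seq_len(dim(movie$frames)[2]) - 1) * movie$pixel_pitch

movie_extent <- function(movie) {
  az <- pixel_az(movie); el <- pixel_el(movie); h <- movie$pixel_pitch / 2
  c(az_min = min(az) - h, az_max = max(az) + h, el_min = min(el) - h, el_max = max(el) + h)
}

#' Binary spatiotemporal white-noise stimulus
#'
#' Each pixel is an independent Bernoulli(0.5) draw per frame, emulating the
#' 60 Hz binary white-noise stimulus with 2.8 degree pixels used for
#' receptive-field mapping.
#'
#' @param width_px,height_px screen size in pixels (azimuth, elevation).
#' @param duration_s stimulus duration in seconds (> 0).
#' @param frame_rate sample rate in Hz (default 60).
#' @param pixel_pitch pixel size in degrees (default 2.8).
#' @param seed integer seed; the movie is reproducible under a fixed seed.
#' @param origin angular coordinate of pixel (1, 1).
#' @return a `stimulus_movie`.
#' @export
make_white_noise <- function(width_px, height_px, duration_s, frame_rate = 60,
                             pixel_pitch = 2.8, seed, origin = c(0, 0)) {
  stop_if_not(width_px >= 1 && height_px >= 1, "screen must be at least 1 x 1 px")
  stop_if_not(duration_s > 0, "duration_s must be > 0")
  stop_if_not(!missing(seed), "a seed is required")
  nt <- max(1L, round(duration_s * frame_rate))
  frames <- with_local_seed(seed, array(stats::rbinom(nt * height_px * width_px, 1L, 0.5),
                                        dim = c(nt, height_px, width_px)))
  stimulus_movie(frames, frame_rate, pixel_pitch, origin)
}

#' Specification of a moving contrast edge
#'
#' @param polarity `"ON"` (dark-to-bright) or `"OFF"` (bright-to-dark).
#' @param direction_deg direction of motion in degrees, in `[0, 360)`;
#'   0 degrees moves towards increasing azimuth, 90 towards increasing elevation.
#' @param velocity_deg_s edge speed in degrees per second (> 0).
#' @param extent_deg field of view `c(az_min, az_max, el_min, el_max)` degrees.
#' @return an object of class `edge_spec`.
#' @export
edge_spec <- function(polarity = c("ON", "OFF"), direction_deg, velocity_deg_s = 30,
                      extent_deg = c(0, 42, 0, 28)) {
  polarity <- match.arg(polarity)
  direction_deg <- direction_deg %% 360
  stop_if_not(velocity_deg_s > 0, "velocity must be > 0")
  stop_if_not(length(extent_deg) == 4 && extent_deg[2] > extent_deg[1] &&
                extent_deg[4] > extent_deg[3], "invalid extent")
  structure(list(polarity = polarity, direction_deg = direction_deg,
                 velocity_deg_s = velocity_deg_s, extent_deg = as.numeric(extent_deg)),
            class = "edge_spec")
}

#' Movie of a straight contrast edge traversing the field of view
#'
#' The luminance step is orthogonal to the direction of motion and sweeps the
#' full extent at the specified velocity, entering from the upstream boundary.
#' ON edges turn the field from dark to bright, OFF edges from bright to dark.
#' Edges are anti-aliased by fractional pixel coverage (linear ramp over one
#' pixel pitch along the motion axis), which keeps onset-time differences
#' between points exactly `distance / velocity` even on coarse grids.
#'
#' @param spec an [edge_spec()].
#' @param frame_rate frames per second.
#' @param pixel_pitch pixel size in degrees.
#' @param pre_s,post_s stationary padding (seconds) before motion onset and
#'   after the edge has fully crossed the field.
#' @return a `stimulus_movie`.
#' @export
make_edge <- function(spec, frame_rate = 60, pixel_pitch = 2.8, pre_s = 0.5, post_s = 0.5) {
  stop_if_not(inherits(spec, "edge_spec"), "spec must be an edge_spec")
  ext <- spec$extent_deg
  stop_if_not(ext[2] - ext[1] >= pixel_pitch && ext[4] - ext[3] >= pixel_pitch,
              "extent smaller than one pixel")
  n_az <- max(1L, floor((ext[2] - ext[1]) / pixel_pitch))
  n_el <- max(1L, floor((ext[4] - ext[3]) / pixel_pitch))
  origin <- c(ext[1] + pixel_pitch / 2, ext[3] + pixel_pitch / 2)
  az <- origin[1] + (seq_len(n_az) - 1) * pixel_pitch
  el <- origin[2] + (seq_len(n_el) - 1) * pixel_pitch
  phi <- spec$direction_deg * pi / 180
  # coordinate along the motion axis for every pixel centre (el x az grid)
  u <- outer(sin(phi) * el, cos(phi) * az, `+`)
  u_min <- min(u) - pixel_pitch / 2
  u_max <- max(u) + pixel_pitch / 2
  travel_s <- (u_max - u_min) / spec$velocity_deg_s
  nt <- ceiling((pre_s + travel_s + post_s) * frame_rate) + 1L
  t <- (seq_len(nt) - 1) / frame_rate
  frames <- array(0, dim = c(nt, n_el, n_az))
  for (k in seq_len(nt)) {
    front <- u_min + spec$velocity_deg_s * max(0, t[k] - pre_s)
    cover <- pmin(pmax((front - (u - pixel_pitch / 2)) / pixel_pitch, 0), 1)
    frames[k, , ] <- if (spec$polarity == "ON") cover else 1 - cover
  }
  stimulus_movie(frames, frame_rate, pixel_pitch, origin)
}

#' Drifting full-contrast square-wave grating
#'
#' @param wavelength_deg spatial wavelength in degrees (> 0).
#' @param temporal_freq_hz drift temporal frequency in Hz (>= 0); the drift
#'   speed is `wavelength_deg * temporal_freq_hz` degrees per second.
#' @param direction_deg direction of motion in degrees.
#' @param duration_s movie duration in seconds.
#' @param frame_rate frames per second.
#' @param pixel_pitch pixel size in degrees.
#' @param extent_deg field of view `c(az_min, az_max, el_min, el_max)`.
#' @return a `stimulus_movie`.
#' @export
make_grating <- function(wavelength_deg, temporal_freq_hz, direction_deg = 0,
                         duration_s = 4, frame_rate = 60, pixel_pitch = 2.8,
                         extent_deg = c(0, 42, 0, 28)) {
  stop_if_not(wavelength_deg > 0, "wavelength must be > 0")
  stop_if_not(temporal_freq_hz >= 0, "temporal frequency must be >= 0")
  ext <- extent_deg
  n_az <- max(1L, floor((ext[2] - ext[1]) / pixel_pitch))
  n_el <- max(1L, floor((ext[4] - ext[3]) / pixel_pitch))
  origin <- c(ext[1] + pixel_pitch / 2, ext[3] + pixel_pitch / 2)
  az <- origin[1] + (seq_len(n_az) - 1) * pixel_pitch
  el <- origin[2] + (seq_len(n_el) - 1) * pixel_pitch
  phi <- direction_deg * pi / 180
  u <- outer(sin(phi) * el, cos(phi) * az, `+`)
  nt <- max(1L, round(duration_s * frame_rate))
  t <- (seq_len(nt) - 1) / frame_rate
  frames <- array(0, dim = c(nt, n_el, n_az))
  for (k in seq_len(nt)) {
    phase <- (u / wavelength_deg - temporal_freq_hz * t[k]) %% 1
    frames[k, , ] <- as.numeric(phase < 0.5)
  }
  stimulus_movie(frames, frame_rate, pixel_pitch, origin)
}

#' Photodiode-style luminance readout at a point on the screen
#'
#' Returns the mean luminance per frame over a circular aperture, emulating
#' the photodiode check used to verify stimulus alignment (a 5 degree wide
#' area of the screen).
#'
#' @param movie a `stimulus_movie`.
#' @param point_deg `c(azimuth, elevation)` in degrees; must lie inside the
#'   movie extent.
#' @param aperture_deg aperture diameter in degrees (default 5).
#' @return numeric vector of per-frame mean luminance.
#' @export
luminance_at <- function(movie, point_deg, aperture_deg = 5) {
  stop_if_not(inherits(movie, "stimulus_movie"), "movie must be a stimulus_movie")
  ext <- movie_extent(movie)
  stop_if_not(point_deg[1] >= ext["az_min"] && point_deg[1] <= ext["az_max"] &&
                point_deg[2] >= ext["el_min"] && point_deg[2] <= ext["el_max"],
              "point outside movie extent")
  az <- pixel_az(movie); el <- pixel_el(movie)
  d2 <- outer((el - point_deg[2])^2, (az - point_deg[1])^2, `+`)
  sel <- d2 <= (aperture_deg / 2)^2
  if (!any(sel)) { # aperture smaller than one pixel: use the nearest pixel
    sel <- d2 == min(d2)
  }
  idx <- which(sel)
  nt <- dim(movie$frames)[1]
  m <- matrix(movie$frames, nrow = nt)
  rowMeans(m[, idx, drop = FALSE])
}
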