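# Shared fixtures, all generated in code.

# write an unbranched SWC chain of n points along z, total length `len_um`
write_chain_swc <- function(n, len_um = 60, radius = 0.4, path = tempfile(fileext = ".swc")) {
  z <- seq(0, len_um, length.out = n)
  writeLines(sprintf("%d 3 0 0 %.6f %g %d", seq_len(n), z, radius,
                     c(-1, seq_len(n - 1))), path)
  path
}

# write a random SWC tree of n points (random parent among earlier points)
write_random_tree_swc <- function(n, seed, path = tempfile(fileext = ".swc")) {
  set.seed(seed)
  xyz <- matrix(0, n, 3)
  parent <- c(-1L, integer(n - 1))
  for (i in 2:n) {
    parent[i] <- sample.int(i - 1L, 1L)
    xyz[i, ] <- xyz[parent[i], ] + stats::rnorm(3, 0, 3)
  }
  r <- stats::runif(n, 0.2, 0.8)
  writeLines(sprintf("%d 3 %.5f %.5f %.5f %.4f %d", seq_len(n),
                     xyz[, 1], xyz[, 2], xyz[, 3], r, parent), path)
  path
}

# dense reference solution of the steady-state cable equation
dense_steady <- function(system, injections_pA = NULL, synapses = list()) {
  A <- as.matrix(system$M)
  rhs <- system$E_leak_mV * 1e-3 * system$g_leak
  if (!is.null(injections_pA)) rhs <- rhs + injections_pA * 1e-12
  for (s in synapses) {
    k <- match(s$site, system$ids)
    A[k, k] <- A[k, k] + s$g_nS * 1e-9
    rhs[k] <- rhs[k] + s$g_nS * 1e-9 * s$E_mV * 1e-3
  }
  as.numeric(solve(A, rhs)) * 1e3
}

# a dark->bright ON edge movie whose columns sit mid-field (matches the
# synthetic condition-set geometry)
fixture_edge_movie <- function(polarity = "ON", direction = 0) {
  make_edge(edge_spec(polarity, direction, 30, c(0, 33.6, 0, 8.4)),
            frame_rate = 60, pixel_pitch = 2.8, pre_s = 0.4, post_s = 0.3)
}

fixture_gt <- function() ground_truth(seed = 1L)

# interpolated time at which a monotone-increasing trace crosses `level`
crossing_time <- function(t, y, level = 0.5) {
  i <- which(y >= level)[1]
  if (is.na(i) || i == 1) return(NA_real_)
  t[i - 1] + (level - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
}
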