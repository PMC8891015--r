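test_that("drift correction removes slow components and never adds variance", {
  fs <- 100
  expect_equal(drift_correct(rep(3.3, 2000), fs, sigma_s = 2), rep(0, 2000))
  # slow ramp + fast wiggle: ramp removed, wiggle preserved (centre of trace)
  t <- seq(0, 60, by = 1 / fs)
  x <- 0.05 * t + sin(2 * pi * 4 * t)
  y <- drift_correct(x, fs, sigma_s = 5)
  mid <- 2000:4000
  expect_lt(stats::sd(y[mid] - sin(2 * pi * 4 * t)[mid]), 0.1)
  set.seed(1)
  n <- stats::rnorm(5000)
  expect_lte(stats::var(drift_correct(n, fs, sigma_s = 1)), stats::var(n))
})

test_that("reverse correlation is linear in vm and finds planted kernels", {
  mv <- make_white_noise(8, 6, 60, seed = 4, origin = c(-9.8, -7))
  S <- mv$frames
  vm0 <- rep(0, dim(S)[1])
  expect_true(all(reverse_correlate(mv, vm0)$K == 0))
  # vm = pixel (3,4) luminance delayed by 5 frames -> extremum exactly there
  vm <- c(rep(0, 5), S[seq_len(dim(S)[1] - 5), 3, 4]) - 0.5
  sc <- zscore_center_filter(reverse_correlate(mv, vm), edge_margin_deg = 0)
  expect_equal(sc$extremum$el_idx, 3)
  expect_equal(sc$extremum$az_idx, 4)
  expect_equal(sc$extremum$lag_s, 5 / 60)
  expect_true(sc$accepted)
  # anticorrelated response: same location, negative extremum
  sc2 <- zscore_center_filter(reverse_correlate(mv, -vm), edge_margin_deg = 0)
  expect_equal(sc2$extremum$sign, -1)
  expect_equal(sc2$extremum$az_idx, 4)
  # linearity: K(a vm1 + b vm2) = a K(vm1) + b K(vm2)
  vm2 <- S[, 2, 2] - 0.5
  K1 <- reverse_correlate(mv, vm)$K
  K2 <- reverse_correlate(mv, vm2)$K
  K12 <- reverse_correlate(mv, 2 * vm - 3 * vm2)$K
  expect_equal(K12, 2 * K1 - 3 * K2, tolerance = 1e-9)
  expect_error(reverse_correlate(mv, vm[1:100]), "shorter")
})

test_that("the lag axis covers the requested range at the stimulus frame rate", {
  mv <- make_white_noise(2, 2, 30, seed = 1)
  rf <- reverse_correlate(mv, stats::rnorm(dim(mv$frames)[1]))
  expect_equal(rf$lags_s[1], -0.5)
  expect_equal(rf$lags_s[length(rf$lags_s)], 3.0)
  expect_equal(diff(rf$lags_s)[1], 1 / 60)
})

test_that("z-score screening rejects weak peaks and edge-adjacent centres", {
  mv <- make_white_noise(8, 6, 60, seed = 4, origin = c(-9.8, -7))
  S <- mv$frames
  vm <- S[, 3, 4] - 0.5
  # strong planted peak, far from the bezel with margin 0: accepted + centred
  sc <- zscore_center_filter(reverse_correlate(mv, vm), edge_margin_deg = 0)
  expect_true(sc$accepted)
  expect_equal(sc$origin[1] + (sc$extremum$az_idx - 1) * sc$pixel_pitch, 0)
  # same cell fails the 22.48-degree bezel criterion on this small screen
  sc_edge <- zscore_center_filter(reverse_correlate(mv, vm))
  expect_false(sc_edge$accepted)
  expect_match(sc_edge$reason, "bezel")
  # pure membrane noise is mostly rejected at the 4-s.d. criterion
  rej <- 0
  for (i in 1:40) {
    noise <- with(list(s = 3000 + i),
                  { set.seed(s); gaussian_smooth(stats::rnorm(dim(S)[1]), 28 / 1000 * 60) })
    scn <- zscore_center_filter(reverse_correlate(mv, noise - mean(noise)),
                                edge_margin_deg = 0)
    rej <- rej + !scn$accepted
  }
  expect_gt(rej / 40, 0.5)
})

test_that("averaging centred fields sharpens with PD rotation on synthetic cells", {
  mv <- make_white_noise(9, 9, 60, seed = 6, origin = c(-11.2, -11.2))
  pop <- synth_population(4, rf_scatter_deg = 2.0, gt = fixture_gt(), movie = mv, seed = 3)
  scs <- lapply(pop, function(cell) {
    zscore_center_filter(reverse_correlate(mv, cell$vm - mean(cell$vm), fs_vm = cell$fs),
                         edge_margin_deg = 0)
  })
  expect_true(all(vapply(scs, `[[`, logical(1), "accepted")))
  # identical fields average to themselves (pre-smoothing)
  av1 <- average_rfs(list(scs[[1]], scs[[1]]))
  m <- scs[[1]]$z[, , scs[[1]]$extremum$lag_idx]
  expect_equal(max(av1$map_raw, na.rm = TRUE), max(m), tolerance = 1e-9)
  av <- average_rfs(scs)
  expect_true(max(av$map_raw, na.rm = TRUE) > 4)
  expect_equal(length(av$az_deg), (length(av$az_deg_raw) - 1) * 10 + 1)
  expect_error(average_rfs(list()), "at least one")
})

test_that("preferred direction is the resultant angle with typed degenerate outcome", {
  expect_equal(preferred_direction(c(0, 1, 0, 0), c(0, 90, 180, 270))$pd_deg, 90)
  sym <- preferred_direction(rep(1, 8), seq(0, 315, by = 45))
  expect_false(sym$defined)
  expect_true(is.na(sym$pd_deg))
  # cosine-tuned magnitudes peaked at 45 degrees
  phi <- seq(0, 350, by = 10)
  mag <- pmax(0, cos((phi - 45) * pi / 180))
  expect_equal(preferred_direction(mag, phi)$pd_deg, 45, tolerance = 1e-6)
  expect_error(preferred_direction(1, 0), "two")
})

test_that("L_dir spans [0, 1] with the stated edge cases and scale invariance", {
  expect_equal(ldir(c(0, 3, 0), c(0, 90, 180)), 1)
  expect_equal(ldir(c(2, 2), c(0, 180)), 0)
  phi <- seq(0, 350, by = 10)
  narrow <- exp(cos((phi - 40) * pi / 180) / 0.2)
  broad <- exp(cos((phi - 40) * pi / 180) / 0.4)  # 2x broader tuning
  expect_gt(ldir(narrow, phi), ldir(broad, phi))
  expect_equal(ldir(narrow, phi), ldir(narrow * 13.7, phi))
  expect_true(ldir(stats::runif(36), phi) >= 0 && ldir(stats::runif(36), phi) <= 1)
  expect_error(ldir(rep(0, 4), c(0, 90, 180, 270)), "all-zero")
})

test_that("Voigt amplitudes recover planted peaks and degrade gracefully", {
  fs <- 1000
  t <- seq(0, 3, by = 1 / fs)
  gauss <- 10 * exp(-(t - 1.5)^2 / (2 * 0.05^2))  # Voigt with zero Lorentzian width
  tc <- tuning_from_edges(list("0" = -60 + c(rep(0, fs), gauss[-(1:fs)])), fs)
  expect_equal(tc$magnitude, 10, tolerance = 1e-3)
  vo <- 7 * voigt_profile(t, 1.5, 0.08, 0.04)
  tc2 <- tuning_from_edges(list("0" = -60 + c(rep(0, fs), vo[-(1:fs)])), fs)
  expect_equal(tc2$magnitude, 7, tolerance = 1e-3)
  # flat trace: amplitude ~ 0
  tcf <- tuning_from_edges(list("0" = rep(-60, 3000)), fs)
  expect_lt(tcf$magnitude, 1e-6)
})

test_that("tuning curves from episodes align to PD and normalize to [0, 1]", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  phi <- seq(0, 315, by = 45)
  episodes <- lapply(phi, function(p) {
    amp <- 2 + 10 * exp(cos((p - 90) * pi / 180) / 0.5)
    -60 + c(rep(0, fs), amp * exp(-(t[-(1:fs)] - 1.4)^2 / (2 * 0.08^2)))
  })
  names(episodes) <- phi
  tc <- tuning_from_edges(episodes, fs, normalize = TRUE)
  expect_equal(attr(tc, "pd_deg"), 90, tolerance = 5)
  expect_equal(tc$magnitude[tc$phi_deg == 0], 1)  # PD aligned to zero
  expect_equal(min(tc$magnitude), 0)
  expect_true(all(tc$magnitude >= 0 & tc$magnitude <= 1))
  expect_true(attr(tc, "ldir") > 0 && attr(tc, "ldir") < 1)
})
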