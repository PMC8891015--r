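gmat <- function(...) {
  g <- matrix(0, 4, 5, dimnames = list(NULL, T4_INPUT_CLASSES))
  args <- list(...)
  for (nm in names(args)) g[, nm] <- args[[nm]]
  conductance_set(g)
}

test_that("joint min-max normalization preserves ratios and offsets cancel", {
  tr <- list(Mi1 = list(seq(-70, -60, by = 1), seq(-70, -65, by = 0.5)))
  out <- normalize_inputs(tr)
  expect_equal(max(out$Mi1[[1]]), 1)
  expect_equal(max(out$Mi1[[2]]), 0.5)
  expect_equal(min(out$Mi1[[1]]), 0)
  # idempotence on already-[0,1] input
  expect_equal(normalize_inputs(list(x = c(0, 0.3, 1)))$x, c(0, 0.3, 1))
  # shift invariance
  shifted <- lapply(tr$Mi1, `+`, 12.5)
  expect_equal(normalize_inputs(list(Mi1 = shifted))$Mi1, out$Mi1)
  expect_error(normalize_inputs(list(flat = rep(-60, 5))), "degenerate")
})

test_that("rectilinear transfer thresholds and scales as specified", {
  expect_equal(transfer(0.5, 0.2, 0.92), 0.276)
  expect_equal(transfer(c(0, 0.1, 0.2), 0.2, 1.5), c(0, 0, 0))
  expect_equal(transfer(seq(0, 1, 0.1), 0.4, 0), rep(0, 11))
  # jump convention: discontinuous at threshold, passes v itself
  expect_equal(transfer(0.5, 0.2, 2, form = "jump"), 1.0)
  expect_equal(transfer(0.2, 0.2, 2, form = "jump"), 0)
  expect_error(transfer(0.5, 1.2, 1), "threshold")
})

test_that("motion delay follows theta cos(phi) / v", {
  expect_equal(motion_delay(0), 0.16)
  expect_equal(motion_delay(60), 0.08)
  expect_equal(motion_delay(90), 0, tolerance = 1e-12)
  expect_equal(motion_delay(180), -0.16)
  expect_error(motion_delay(0, velocity_deg_s = 0), "velocity")
})

test_that("membrane voltage is the conductance-weighted mean of reversals", {
  p <- reference_params()
  expect_equal(simulate_vm(gmat(), p), rep(-65, 4))
  # hand-computed weighted mean: Mi9 0.5 vs leak 0.5
  expect_equal(simulate_vm(gmat(Mi9 = 0.5), p)[1], (-71 * 0.5 - 65 * 0.5) / 1, tolerance = 1e-12)
  expect_equal(simulate_vm(gmat(Mi9 = 0.5), p)[1], -68.0)
  # saturating cholinergic drive converges on E_ACh
  expect_equal(simulate_vm(gmat(Tm3 = 1e9), p)[1], -21, tolerance = 1e-6)
})

test_that("voltage stays within the convex hull of reversal potentials", {
  p <- reference_params()
  set.seed(42)
  for (i in 1:50) {
    g <- matrix(stats::runif(20, 0, 5), 4, 5, dimnames = list(NULL, T4_INPUT_CLASSES))
    vm <- simulate_vm(conductance_set(g), p)
    expect_true(all(vm >= min(p$E_Glu, p$E_ACh, p$E_GABA, p$E_leak) - 1e-9))
    expect_true(all(vm <= max(p$E_Glu, p$E_ACh, p$E_GABA, p$E_leak) + 1e-9))
  }
})

test_that("scaling all gains and g_leak by c leaves the voltage unchanged", {
  p <- reference_params()
  v_norm <- lapply(stats::setNames(T4_INPUT_CLASSES, T4_INPUT_CLASSES),
                   function(cl) stats::runif(200))
  vm1 <- simulate_vm(input_conductances(v_norm, p), p)
  for (cc in c(0.1, 3.7)) {
    ps <- p
    ps$gains <- p$gains * cc
    ps$g_leak <- p$g_leak * cc
    expect_equal(simulate_vm(input_conductances(v_norm, ps), ps), vm1, tolerance = 1e-12)
  }
})

test_that("relative input resistance mirrors total conductance changes", {
  p <- reference_params()
  g <- matrix(0, 3, 5, dimnames = list(NULL, T4_INPUT_CLASSES))
  g[, "Mi9"] <- c(0.5, 0.25, 0)  # tonic inhibition released over time
  ps <- p; ps$g_leak <- 0.5
  r <- predicted_input_resistance(conductance_set(g), ps, baseline_idx = 1)
  expect_equal(r[1], 1.0)
  expect_equal(r[3], 2.0)  # full release halves the total conductance
  # adding excitation at fixed inhibition always lowers R
  g2 <- g; g2[, "Tm3"] <- 0.4
  r2 <- predicted_input_resistance(conductance_set(g2), ps, baseline_idx = 1)
  expect_true(all(r2[2:3] < r[2:3]))
  expect_error(predicted_input_resistance(conductance_set(g), ps, integer(0)), "baseline")
})

test_that("coincident excitation and release from inhibition is supralinear", {
  p <- synaptic_params(gains = stats::setNames(rep(1, 5), T4_INPUT_CLASSES),
                       thresholds = stats::setNames(rep(0, 5), T4_INPUT_CLASSES),
                       E_leak = -65, g_leak = 1)
  # square events: excitation on at sample 2; inhibition (tonic 1) released then
  idx <- linearity_index(p, exc_event = c(0, 1, 0), inh_release_event = c(1, 0, 1))
  expect_equal(idx, 6.8333, tolerance = 1e-4)
  expect_equal(linearity_index(p, c(0, 0, 0), c(1, 0, 1)), 0)
  # two excitatory conductances combine sublinearly in a passive membrane
  vm2 <- function(ge) (-21 * ge - 65) / (ge + 1)
  dv_each <- vm2(1) - vm2(0)
  dv_both <- vm2(2) - vm2(0)
  expect_equal(dv_each, 22)
  expect_equal(dv_both, 29 + 1 / 3, tolerance = 1e-12)
  expect_lt(dv_both, 2 * dv_each)
})

test_that("supralinearity holds on the conductance grid and fails only when E_exc nears E_leak", {
  g <- seq(0.1, 5, length.out = 50)
  grid <- outer(g, g, function(a, b) linearity_index_peak(a, b, -21, -68, -65, 1))
  expect_true(all(grid > 0))
  # exception regime: excitatory reversal closer to leak than the inhibitory one
  grid2 <- outer(g, g, function(a, b) linearity_index_peak(a, b, -64, -68, -65, 1))
  expect_true(any(grid2 < 0))
})

test_that("tuning prediction peaks at the preferred direction and Mi9 sharpens it", {
  gt <- fixture_gt()
  va <- synth_aligned_inputs(gt)
  tc <- tuning_prediction(va, gt$params)
  expect_equal(tc$phi_deg[which.max(tc$magnitude)], 0)
  tc0 <- tuning_prediction(va, gt$params, mi9_silenced = TRUE)
  mm <- function(x) (x - min(x)) / (max(x) - min(x))
  hw <- function(tcv) {  # half-width at half-maximum: first 0.5 crossing off PD
    sel <- tcv$phi_deg <= 180
    phi <- tcv$phi_deg[sel]
    y <- mm(tcv$magnitude)[sel]
    i <- which(y < 0.5)[1]
    phi[i - 1] + (y[i - 1] - 0.5) / (y[i - 1] - y[i]) * (phi[i] - phi[i - 1])
  }
  expect_gt(hw(tc0), hw(tc))                    # silencing Mi9 broadens tuning
  expect_lt(ldir(mm(tc0$magnitude), tc0$phi_deg),
            ldir(mm(tc$magnitude), tc$phi_deg))  # and lowers L_dir
  # all gains zero: flat response at baseline
  p0 <- gt$params; p0$gains[] <- 0
  tcf <- tuning_prediction(va, p0)
  expect_true(all(tcf$magnitude == 0))
  expect_error(tuning_prediction(va, gt$params, directions_deg = numeric(0)), "empty")
})

test_that("parameters round-trip through JSON and YAML", {
  p <- reference_params()
  for (ext in c(".json", ".yaml")) {
    f <- tempfile(fileext = ext)
    write_synaptic_params(p, f)
    q <- read_synaptic_params(f)
    expect_equal(q$gains, p$gains)
    expect_equal(q$thresholds, p$thresholds)
    expect_equal(q$g_leak, p$g_leak)
    expect_equal(q$E_ACh, p$E_ACh)
  }
})

test_that("single-compartment steady state matches the cable model within 0.1 mV", {
  # the capacitance-free voltage equation is the steady state of the full
  # dynamic membrane equation; run the cable model on one compartment with
  # matched conductance ratios for >= 5 membrane time constants
  p <- reference_params()
  g_rel <- c(Mi9 = 0.3, Tm3 = 0.8, Mi1 = 0.2, Mi4 = 0.4, C3 = 0.1)
  gset <- gmat(Mi9 = 0.3, Tm3 = 0.8, Mi1 = 0.2, Mi4 = 0.4, C3 = 0.1)
  vm_point <- simulate_vm(gset, p)[1]
  swc <- write_chain_swc(2, len_um = 50, radius = 0.5)
  sys <- assemble_cable(read_swc(swc), cable_params(E_leak_mV = p$E_leak))
  scale_nS <- sum(sys$g_leak) * 1e9 / p$g_leak  # map relative g to siemens
  syn <- list(
    list(site = 1, g_nS = g_rel[["Mi9"]] * scale_nS, E_mV = p$E_Glu),
    list(site = 1, g_nS = (g_rel[["Tm3"]] + g_rel[["Mi1"]]) * scale_nS, E_mV = p$E_ACh),
    list(site = 1, g_nS = (g_rel[["Mi4"]] + g_rel[["C3"]]) * scale_nS, E_mV = p$E_GABA))
  v <- rep(p$E_leak, sys$n)
  for (k in seq_len(1500)) v <- step_dynamic(sys, v, synapses = syn)  # 150 ms
  expect_lt(abs(v[1] - vm_point), 0.1)
})
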