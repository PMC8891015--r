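test_that("SWC parsing builds the compartment tree and flags malformed files", {
  f <- tempfile(fileext = ".swc")
  writeLines(c("# toy", "1 1 0 0 0 1 -1", "2 3 0 0 5 0.5 1", "3 3 0 5 5 0.5 1"), f)
  m <- read_swc(f)
  expect_equal(nrow(m), 3)
  expect_equal(sum(m$parent != -1), 2)
  expect_equal(m$diam_um, c(2, 1, 1))
  expect_equal(m$length_um[2], 5)

  writeLines(c("1 1 0 0 0 1 -1", "2 3 0 0 5 0.5 9"), f)
  expect_error(read_swc(f), "line 2.*unknown parent 9")
  writeLines(c("1 1 0 0 0 -1 -1"), f)
  expect_error(read_swc(f), "radius")
  writeLines(c("1 1 0 0 0 1 -1", "2 3 0 0 5 0.5 3", "3 3 0 0 9 0.5 2"), f)
  expect_error(read_swc(f), "cycle|unknown")
  writeLines(c("1 1 0 0 0 1 -1", "2 1 1 0 0 1 -1"), f)
  expect_error(read_swc(f), "exactly one root")
})

test_that("assembly follows the cylinder closed forms and Kirchhoff consistency", {
  # 100 um x 1 um cylinder at R_m = 28 kOhm cm^2 -> R_in = R_m / area
  sys <- assemble_cable(read_swc(write_chain_swc(501, len_um = 100, radius = 0.5)))
  r_closed <- 28e3 / (pi * 1e-4 * 100e-4) / 1e9  # GOhm
  # end injection sees coth(L/lambda) x the lumped value (~+0.7% here)
  expect_equal(input_resistance_at(sys, 1), r_closed, tolerance = 0.01)
  # doubling R_a halves axial conductances, leaves membrane terms unchanged
  m <- read_swc(write_chain_swc(11))
  s1 <- assemble_cable(m, cable_params(R_a_ohm_cm = 150))
  s2 <- assemble_cable(m, cable_params(R_a_ohm_cm = 300))
  expect_equal(s1$g_leak, s2$g_leak)
  off1 <- s1$M[1, 2]; off2 <- s2$M[1, 2]
  expect_equal(off2 / off1, 0.5, tolerance = 1e-12)
  # row sums minus membrane terms vanish (axial currents cancel)
  rs <- Matrix::rowSums(s1$M) - s1$g_leak
  expect_true(all(abs(rs) < 1e-18))
  expect_error(assemble_cable(data.frame()), "cable_morphology")
})

test_that("steady solves match dense brute force to 1e-9 on random trees", {
  for (seed in 1:3) {
    sys <- assemble_cable(read_swc(write_random_tree_swc(50, seed)))
    inj <- numeric(sys$n); inj[sample.int(sys$n, 3)] <- c(1, -0.5, 2)
    syn <- list(list(site = sys$ids[10], g_nS = 0.05, E_mV = -21))
    v <- solve_steady(sys, injections_pA = inj, synapses = syn)
    vd <- dense_steady(sys, injections_pA = inj, synapses = syn)
    expect_lt(max(abs(v - vd)) / max(abs(vd)), 1e-9)
  }
  # resting state with no input is E_leak everywhere; E_syn = E_leak is inert
  sys <- assemble_cable(read_swc(write_chain_swc(20)))
  expect_equal(solve_steady(sys), rep(-65, 20), tolerance = 1e-9)
  expect_equal(solve_steady(sys, synapses = list(list(site = 5, g_nS = 1, E_mV = -65))),
               rep(-65, 20), tolerance = 1e-9)
})

test_that("two-compartment steady state matches the hand-solved 2x2 system", {
  sys <- assemble_cable(read_swc(write_chain_swc(2, len_um = 40, radius = 0.5)))
  ga <- -as.numeric(sys$M[1, 2])
  gm <- sys$g_leak
  I <- 2e-12
  A <- matrix(c(gm[1] + ga, -ga, -ga, gm[2] + ga), 2, 2)
  vh <- solve(A, c(-65e-3 * gm[1] + I, -65e-3 * gm[2])) * 1e3
  v <- solve_steady(sys, injections_pA = c(2, 0))
  expect_equal(v, as.numeric(vh), tolerance = 1e-12)
})

test_that("implicit stepping is a fixed point at rest and relaxes with tau = R_m C_m", {
  sys <- assemble_cable(read_swc(write_chain_swc(2, len_um = 50, radius = 0.5)))
  v <- rep(-65, 2)
  for (k in 1:50) v <- step_dynamic(sys, v)
  expect_equal(v, rep(-65, 2), tolerance = 1e-12)
  # constant current step relaxes to the steady state with tau = 28 ms
  inj <- c(2, 0)
  vs <- solve_steady(sys, injections_pA = inj)
  v <- rep(-65, 2); tr <- numeric(3000)
  for (k in 1:3000) { v <- step_dynamic(sys, v, injections_pA = inj); tr[k] <- v[1] }
  expect_lt(abs(tr[3000] - vs[1]), 0.01)
  dv <- vs[1] - tr
  sel <- which(dv > 1e-4 * max(dv))
  tau_ms <- -1 / stats::coef(stats::lm(log(dv[sel]) ~ I((sel) * 0.1)))[2]
  expect_equal(unname(tau_ms), 28, tolerance = 0.01)
  expect_error(step_dynamic(sys, v, dt_s = 0), "dt")
})

test_that("PI clamp holds the soma at command and reports settled currents", {
  sys <- assemble_cable(read_swc(write_chain_swc(30, len_um = 60, radius = 0.4)))
  # no driving force: holding current decays to zero
  out <- run_voltage_clamp(sys, clamp_config(rep(-65, 400), site = 1))
  expect_lt(abs(out$i_pA[400]), 1e-6)
  # 10 mV step: soma within 0.1 mV, current matches R_in
  out2 <- run_voltage_clamp(sys, clamp_config(rep(-55, 800), site = 1))
  expect_lt(abs(out2$v_site_mV[800] + 55), 0.1)
  expect_equal(out2$i_pA[800], 10 / input_resistance_at(sys, 1), tolerance = 1e-4)
  # synaptic pulse at the clamped compartment with E_syn = V_cmd evokes ~0
  ev <- list(list(site = 1, g_nS = 0.05, E_mV = -55, onset_s = 0.05, duration_s = 0.02))
  out3 <- run_voltage_clamp(sys, clamp_config(rep(-55, 800), site = 1), events = ev)
  evoked <- out3$i_pA[550:700] - out3$i_pA[499]
  expect_lt(max(abs(evoked)), 1e-3)
})

test_that("reversal estimates recover E_syn at the clamp site and shift distally", {
  sys <- assemble_cable(read_swc(write_chain_swc(30, len_um = 60, radius = 0.4)))
  rv <- iv_reversal(sys, seq(-80, -10, by = 10),
                    synapse = list(site = 1, g_nS = 0.05, E_mV = -21), clamp_site = 1)
  expect_equal(rv$E_rev_mV, -21, tolerance = 0.05)
  expect_false(rv$extrapolated)
  # space-clamped single compartment: exact to solver tolerance
  sys1 <- assemble_cable(read_swc(write_chain_swc(2, len_um = 50, radius = 0.5)))
  rv1 <- iv_reversal(sys1, c(-80, -50, -20, 0),
                     synapse = list(site = 1, g_nS = 0.05, E_mV = -21), clamp_site = 1)
  expect_equal(rv1$E_rev_mV, -21, tolerance = 1e-3)
  # distal insertion on a poorly clamped tree: the local voltage is attenuated
  # towards E_leak, so the zero crossing moves AWAY from E_leak (space clamp)
  sysl <- assemble_cable(read_swc(write_chain_swc(60, len_um = 400, radius = 0.1)),
                         cable_params(R_a_ohm_cm = 400))
  rvd <- suppressWarnings(
    iv_reversal(sysl, seq(-80, 20, by = 20),
                synapse = list(site = 60, g_nS = 0.05, E_mV = -21), clamp_site = 1))
  expect_gt(abs(rvd$E_rev_mV - (-65)), abs(-21 - (-65)))
  expect_error(iv_reversal(sys, c(-80, -60),
                           synapse = list(site = 1, g_nS = 0.05, E_mV = -21),
                           clamp_site = 1), "three")
})

test_that("steady transfer is attenuating, reciprocal and robust to R_a/R_m", {
  sys <- assemble_cable(read_swc(write_chain_swc(25, len_um = 120, radius = 0.2)))
  expect_equal(transfer_attenuation(sys, 1, 1), 1)
  att <- vapply(c(5, 10, 18, 25), function(k) transfer_attenuation(sys, 1, k), numeric(1))
  expect_true(all(diff(att) < 0))       # monotone decay with path length
  expect_true(all(att > 0 & att <= 1))
  # two-compartment closed form: g_ax / (g_ax + g_m,target)
  s2 <- assemble_cable(read_swc(write_chain_swc(2, len_um = 40, radius = 0.5)))
  ga <- -as.numeric(s2$M[1, 2])
  expect_equal(transfer_attenuation(s2, 1, 2), ga / (ga + s2$g_leak[2]), tolerance = 1e-9)
  # reciprocity: the transfer resistance matrix of a passive tree is symmetric
  for (seed in 4:6) {
    sysr <- assemble_cable(read_swc(write_random_tree_swc(20, seed)))
    a <- sysr$ids[3]; b <- sysr$ids[17]
    v0 <- solve_steady(sysr)
    inj_a <- numeric(sysr$n); inj_a[3] <- 1
    inj_b <- numeric(sysr$n); inj_b[17] <- 1
    dva <- solve_steady(sysr, injections_pA = inj_a) - v0
    dvb <- solve_steady(sysr, injections_pA = inj_b) - v0
    expect_equal(dva[17], dvb[3], tolerance = 1e-9)
  }
  # varying R_a in [50, 400] and R_m in [7, 112] changes the attenuation of
  # the toy dendrite only within a bounded factor
  atts <- c()
  for (ra in c(50, 150, 400)) for (rm in c(7, 28, 112)) {
    s <- assemble_cable(read_swc(write_chain_swc(25, len_um = 120, radius = 0.2)),
                        cable_params(R_a_ohm_cm = ra, R_m_kohm_cm2 = rm))
    atts <- c(atts, transfer_attenuation(s, 1, 25))
  }
  expect_true(all(atts > 0 & atts <= 1))
  expect_lt(max(atts) / min(atts), 3)
})
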