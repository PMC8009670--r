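test_that("steady-state current reduces to the leak when active conductances are off", {
  p <- quiet_cell_params(g_pic = 0, g_out = 0, g_leak = 0.5, E_rest = -70)
  expect_equal(steady_state_current(p, p$E_rest), 0)
  expect_equal(steady_state_current(p, p$E_rest + 10), 10 * p$g_leak)
  expect_equal(steady_state_current(p, p$E_rest - 7), -7 * p$g_leak)
})

test_that("the leak-subtracted I-V has an interior negative peak", {
  o <- oracle_pic_features(sim_cell_params())
  expect_gt(o$peak_voltage, -80)
  expect_lt(o$peak_voltage, -40)
  expect_gt(o$amplitude, 0)
  # edges are above the interior minimum
  p <- sim_cell_params()
  expect_gt(nonleak_current(p, -80), o$min_current)
  expect_gt(nonleak_current(p, -40), o$min_current)
})

test_that("noiseless instantaneous VC response equals the closed-form current", {
  p <- quiet_cell_params(C = 0)
  sw <- simulate_vclamp_ramp(p, ramp_spec(-80, -40, 5, 0.5), 1000)
  expect_lt(max(abs(sw$response - steady_state_current(p, sw$command))), 1e-9)
  # with capacitance the deviation is exactly the constant C dV/dt offset
  p2 <- quiet_cell_params(C = 4)
  sw2 <- simulate_vclamp_ramp(p2, ramp_spec(-80, -40, 5, 0.5), 1000)
  ramp_idx <- which(diff(sw2$command) > 0)
  offs <- (sw2$response - steady_state_current(p2, sw2$command))[ramp_idx[-1]]
  expect_equal(unique(round(offs, 12)), 4 * 5 / 1000)
})

test_that("instantaneous PIC gives no hysteresis; slow PIC shifts the descending peak", {
  p <- quiet_cell_params(C = 0)
  sw <- simulate_vclamp_ramp(p, ramp_spec(-80, -40, 5, 0.5), 2000)
  limbs <- split_ramp(sw)
  asc <- limbs$ascending; desc <- limbs$descending
  # responses at matched voltages are identical
  i <- match(round(asc$voltage, 6), round(desc$voltage, 6))
  ok <- !is.na(i)
  expect_lt(max(abs(asc$current[ok] - desc$current[i[ok]])), 1e-9)

  p2 <- sim_cell_params(tau_pic = 0.5, noise_sd = 0, C = 0)
  sw2 <- simulate_vclamp_ramp(p2, ramp_spec(-80, -40, 5, 0.5), 2000)
  ex <- extract_vclamp(sw2)
  expect_lt(ex$pic$peak_voltage_desc, ex$pic$peak_voltage_asc)
})

test_that("same seed gives bit-identical traces and cohorts", {
  p <- sim_cell_params(noise_sd = 0.2, seed = 77)
  a <- simulate_vclamp_ramp(p, ramp_spec(-80, -40, 5, 0.2), 1000)
  b <- simulate_vclamp_ramp(p, ramp_spec(-80, -40, 5, 0.2), 1000)
  expect_identical(a$response, b$response)

  spec <- test_cohort_spec(n = 1L, nonfiring = FALSE)
  spec <- spec[1:2]
  c1 <- sample_cohort(spec, seed = 5)
  c2 <- sample_cohort(spec, seed = 5)
  expect_identical(c1, c2)
  c3 <- sample_cohort(spec, seed = 6)
  expect_false(identical(c1[[1]]$sweeps[[1]]$response,
                         c3[[1]]$sweeps[[1]]$response))
})

test_that("current ramps below rheobase stay silent; above they fire", {
  p <- quiet_cell_params(spike_threshold = -52, V_reset = -60, seed = 2)
  rheo <- rheobase_current(p)
  sub <- simulate_cclamp_ramp(p, ramp_spec(0, rheo - 0.3, 2.5, 0.5), 5000)
  expect_length(detect_spikes(sub)$spike_times, 0L)
  supra <- simulate_cclamp_ramp(p, ramp_spec(0, rheo + 2, 2.5, 0.5), 5000)
  expect_gt(length(detect_spikes(supra)$spike_times), 5L)
})

test_that("ascending spike count matches a 10x finer reference integration", {
  p <- quiet_cell_params(spike_threshold = -52, V_reset = -60, seed = 2)
  rheo <- rheobase_current(p)
  ramp <- ramp_spec(0, rheo + 2, 2.5, 0.5)
  coarse <- simulate_cclamp_ramp(p, ramp, 5000)
  fine <- simulate_cclamp_ramp(p, ramp, 50000)
  apex_c <- coarse$time[which.max(coarse$command)]
  apex_f <- fine$time[which.max(fine$command)]
  n_c <- sum(attr(coarse, "spike_times_true") <= apex_c)
  n_f <- sum(attr(fine, "spike_times_true") <= apex_f)
  expect_lte(abs(n_c - n_f), 1L)
})

test_that("a large slow PIC produces negative delta-I hysteresis", {
  p <- sim_cell_params(g_leak = 0.4, E_rest = -68, spike_threshold = -54,
                       V_reset = -56, tau_pic = 0.5, adapt_increment = 0,
                       noise_sd = 0, seed = 4)
  p <- calibrate_g_pic(8, p)
  rheo <- rheobase_current(p)
  sw <- simulate_cclamp_ramp(p, ramp_spec(0, rheo + 3, 2.5, 1), 5000)
  m <- recruitment_measures(sw, detect_spikes(sw))
  expect_lt(m$delta_i, 0)
})

test_that("cohort sampling honours counts, truncation and correlation", {
  expect_length(sample_cohort(test_cohort_spec(n = 0L, nonfiring = FALSE),
                              seed = 1), 0L)
  cells <- test_cohort()
  expect_length(cells, 6 * 3 + 4)
  gl <- vapply(cells, function(c) c$ground_truth$params$g_leak, numeric(1))
  expect_true(all(gl > 0))
  # drawn targets correlate between cell size and PIC amplitude
  tg <- t(vapply(cells, function(c)
    c(c$ground_truth$targets$g_leak, c$ground_truth$targets$pic_amplitude),
    numeric(2)))
  keep <- !vapply(cells, function(c) isTRUE(c$ground_truth$nonfiring), TRUE)
  expect_gt(cor(tg[keep, 1], tg[keep, 2]), 0.3)
  # ground truth sidecar is consistent with the brute-force oracle
  for (cell in cells[c(1, 8, 15)]) {
    o <- oracle_pic_features(do.call(sim_cell_params, cell$ground_truth$params))
    expect_equal(o$amplitude, cell$ground_truth$oracle$amplitude)
    expect_equal(o$peak_voltage, cell$ground_truth$oracle$peak_voltage)
  }
})

test_that("extracted cohort means track the group targets", {
  tab <- test_feature_table()
  cells <- test_cohort()
  targets <- t(vapply(cells, function(c) c(
    g = c$ground_truth$targets$g_leak,
    amp = c$ground_truth$targets$pic_amplitude), numeric(2)))
  rownames(targets) <- vapply(cells, `[[`, "", "cell_id")
  common <- intersect(rownames(targets), tab$cell_id)
  i <- match(common, tab$cell_id)
  j <- match(common, rownames(targets))
  # per-cell recovery, not just means: conductance tight, amplitude looser
  # (the leak fit inherits the PIC tail for hyperpolarized-onset cells)
  expect_lt(median(abs(tab$input_conductance[i] / targets[j, "g"] - 1)), 0.03)
  expect_lt(median(abs(tab$pic_amplitude_asc[i] - targets[j, "amp"])), 0.5)
})

test_that("PIC amplitude versus conductance reproduces the correlated-cohort regression", {
  tab <- test_feature_table()
  tab <- tab[tab$firing_class == "repetitive" & tab$age_group == "P30-P60", ]
  r <- regress_with_ci(tab$input_conductance, tab$pic_amplitude_asc)
  expect_gt(r$slope, 0)
  expect_gt(r$r2, 0.2)
  expect_lt(r$r2, 0.95)
})
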