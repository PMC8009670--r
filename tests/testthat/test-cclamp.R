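# Builds a current-clamp sweep with a flat membrane potential and
# stereotyped AP waveforms inserted at chosen times; ground truth for the
# detector without any model dynamics.
synthetic_cc_sweep <- function(spike_times, fs = 10000, dur = 4,
                               v_base = -65, peak = 20, ramp_peak = 8) {
  n <- round(dur * fs)
  tt <- seq(0, by = 1 / fs, length.out = n)
  cmd <- ifelse(tt <= dur / 2, ramp_peak * tt / (dur / 2),
                ramp_peak * (2 - 2 * tt / dur))
  V <- rep(v_base, n)
  n_rise <- round(0.4e-3 * fs); n_fall <- round(0.6e-3 * fs)
  wf <- c(seq(v_base, peak, length.out = n_rise + 1)[-1],
          seq(peak, v_base, length.out = n_fall + 1)[-1])
  for (ts in spike_times) {
    i <- which.min(abs(tt - ts))
    j <- min(n, i + length(wf))
    V[(i + 1):j] <- wf[seq_len(j - i)]
  }
  trace_sweep(tt, cmd, V, "CC", fs, ramp_spec(0, ramp_peak, ramp_peak / (dur / 2), 0))
}

test_that("the dV/dt detector finds exactly the inserted spikes", {
  sw <- synthetic_cc_sweep(numeric(0))
  expect_length(detect_spikes(sw)$spike_times, 0L)

  times <- c(0.5, 0.9, 1.2, 1.6, 2.4, 3.1)
  sw2 <- synthetic_cc_sweep(times)
  tr <- detect_spikes(sw2)
  expect_length(tr$spike_times, length(times))
  expect_lt(max(abs(tr$spike_times - times)), 3e-4)
  expect_true(all(tr$peak_voltages >= tr$threshold_crossing_voltages + 20))

  # on simulated cells, detections match the generator's insertion times
  p <- sim_cell_params(tau_pic = 0, noise_sd = 2, seed = 9)
  rheo <- rheobase_current(p)
  sim <- simulate_cclamp_ramp(p, ramp_spec(0, rheo + 2, 2.5, 0.5), 5000)
  truth <- attr(sim, "spike_times_true")
  tr2 <- detect_spikes(sim)
  expect_length(tr2$spike_times, length(truth))
  expect_lt(max(abs(tr2$spike_times - truth)), 3e-4)
  # first-spike threshold crossing sits at the generator's threshold
  expect_lt(abs(tr2$threshold_crossing_voltages[1] - p$spike_threshold), 1)
})

test_that("the detector refuses unsuitable sweeps", {
  sw <- synthetic_cc_sweep(c(1), fs = 2000)
  expect_error(detect_spikes(sw), class = "picquant_resolution_error")
  p <- quiet_cell_params()
  vc <- simulate_vclamp_ramp(p, ramp_spec(-80, -40, 5, 0.2), 1000)
  expect_error(detect_spikes(vc), class = "picquant_protocol_error")
})

test_that("recruitment bookkeeping handles single spikes and short trains", {
  one <- synthetic_cc_sweep(2.1)
  tr <- detect_spikes(one)
  m <- recruitment_measures(one, tr)
  expect_equal(m$recruitment_current, m$derecruitment_current)
  expect_equal(m$delta_i, 0)
  expect_true(is.na(m$delta_f))

  none <- recruitment_measures(one, structure(list(spike_times = numeric(0)),
                                              class = "spike_train"))
  expect_true(all(is.na(unlist(none))))

  # delta_i identity holds on every simulated cell
  tab <- test_feature_table()
  i <- !is.na(tab$delta_i)
  expect_true(any(i))
  expect_equal(tab$delta_i[i],
               tab$derecruitment_current[i] - tab$recruitment_current[i],
               tolerance = 1e-12)
})

test_that("noiseless recruitment matches the quasi-static rheobase", {
  p <- quiet_cell_params(spike_threshold = -52, V_reset = -60, seed = 3)
  rheo <- rheobase_current(p)
  sw <- simulate_cclamp_ramp(p, ramp_spec(0, rheo + 2, 1, 0.5), 10000)
  m <- recruitment_measures(sw, detect_spikes(sw))
  expect_lt(abs(m$recruitment_current - rheo), 0.1)
})

test_that("instantaneous F-I assigns constant ISIs to the right frequency", {
  sw <- synthetic_cc_sweep(seq(0.5, 1.5, by = 0.02))
  tr <- detect_spikes(sw)
  fi <- instantaneous_fi(sw, tr)
  expect_true(all(abs(fi$ascending$frequency - 50) < 0.5))
  expect_equal(nrow(fi$ascending), length(tr$spike_times) - 1L)
  # fewer than three spikes on a limb yields an empty series
  fi2 <- instantaneous_fi(synthetic_cc_sweep(c(0.5, 0.8)),
                          detect_spikes(synthetic_cc_sweep(c(0.5, 0.8))))
  expect_equal(nrow(fi2$ascending), 0L)
})

test_that("symmetric noiseless cells give mirrored F-I limbs", {
  p <- quiet_cell_params(spike_threshold = -52, V_reset = -60,
                         adapt_increment = 0, seed = 3)
  rheo <- rheobase_current(p)
  sw <- simulate_cclamp_ramp(p, ramp_spec(0, rheo + 2, 2, 0.5), 10000)
  fi <- instantaneous_fi(sw, detect_spikes(sw))
  expect_lte(abs(nrow(fi$ascending) - nrow(fi$descending)), 1L)
  # frequencies agree at matched currents
  ov <- range(fi$ascending$current)
  grid <- seq(ov[1] + 0.2, ov[2] - 0.2, length.out = 20)
  fa <- approx(fi$ascending$current, fi$ascending$frequency, grid)$y
  fd <- approx(fi$descending$current, fi$descending$frequency, grid)$y
  expect_lt(median(abs(fa - fd)), 2)
})

test_that("the SPR/PR changepoint recovers planted structure", {
  # a perfectly linear noiseless series: the PR covers everything
  cur <- seq(1, 4, by = 0.1)
  lin <- data.frame(current = cur, frequency = 10 + 9.3 * cur)
  s <- segment_spr_pr(lin, "ascending")
  expect_length(s$pr_index, nrow(lin))
  expect_equal(s$transition_current, min(cur))
  expect_equal(fi_gain(lin, s$pr_index), 9.3, tolerance = 1e-9)

  # a two-segment series breaks within 0.2 nA of the planted kink
  for (spacing in c(0.05, 0.1)) {
    cu <- seq(2, 8, by = spacing)
    fr <- ifelse(cu <= 5, 75 - 25 * (5 - cu), 75 + 9 * (cu - 5))
    tw <- segment_spr_pr(data.frame(current = cu, frequency = fr), "ascending")
    expect_lt(abs(tw$transition_current - 5), 0.2)
    expect_equal(fi_gain(data.frame(current = cu, frequency = fr), tw$pr_index),
                 9, tolerance = 0.05)
  }

  # too few points: everything undefined
  short <- lin[1:5, ]
  s3 <- segment_spr_pr(short, "ascending")
  expect_true(is.na(s3$transition_current))
  expect_true(is.na(fi_gain(short, s3$pr_index)))
})

test_that("a noisy linear F-I yields a gain inside its analytic confidence band", {
  set.seed(42)
  cur <- seq(3, 6, length.out = 30)
  freq <- 5 + 9.3 * cur + rnorm(30, 0, 2)
  fi <- data.frame(current = cur, frequency = freq)
  slope <- fi_gain(fi, seq_len(30))
  se <- 2 / sqrt(sum((cur - mean(cur))^2))  # known-noise OLS slope SD
  expect_lt(abs(slope - 9.3), qnorm(0.999) * se)
})

test_that("voltage threshold is invariant to time origin and sampling rate", {
  p <- quiet_cell_params(spike_threshold = -52, V_reset = -60, seed = 6)
  rheo <- rheobase_current(p)
  ramp <- ramp_spec(0, rheo + 2, 2.5, 0.5)
  sw10 <- simulate_cclamp_ramp(p, ramp, 10000)
  vth10 <- recruitment_measures(sw10, detect_spikes(sw10))$v_threshold

  shifted <- trace_sweep(sw10$time + 5, sw10$command, sw10$response, "CC",
                         sw10$sampling_rate, sw10$protocol)
  vth_sh <- recruitment_measures(shifted, detect_spikes(shifted))$v_threshold
  expect_equal(vth_sh, vth10)

  sw20 <- simulate_cclamp_ramp(p, ramp, 20000)
  vth20 <- recruitment_measures(sw20, detect_spikes(sw20))$v_threshold
  expect_lte(abs(vth20 - vth10), 0.2)
})

test_that("firing classification follows the ramp/step rule", {
  many <- structure(list(spike_times = seq(0.5, 3, length.out = 40)),
                    class = "spike_train")
  few <- structure(list(spike_times = c(1.2, 1.4)), class = "spike_train")
  one <- structure(list(spike_times = 2), class = "spike_train")
  none <- structure(list(spike_times = numeric(0)), class = "spike_train")
  expect_identical(classify_firing(many), "repetitive")
  expect_identical(classify_firing(few, one), "non_firing")
  expect_identical(classify_firing(few, none), "repetitive")

  # simulated hypoexcitable cells classify as non-firing, normal cells fire
  tab <- test_feature_table()
  cells <- test_cohort()
  nf_ids <- vapply(cells[vapply(cells, function(c)
    isTRUE(c$ground_truth$nonfiring), TRUE)], `[[`, "", "cell_id")
  in_tab <- intersect(nf_ids, tab$cell_id)
  expect_true(length(in_tab) >= 2)
  expect_true(all(tab$firing_class[match(in_tab, tab$cell_id)] == "non_firing"))
  expect_true(mean(tab$firing_class == "repetitive") > 0.6)
  # non-firing rows keep voltage-clamp features but no F-I features
  nf_rows <- tab[tab$firing_class == "non_firing", ]
  expect_true(all(is.na(nf_rows$recruitment_current)))
  expect_true(all(is.finite(nf_rows$input_conductance)))
})

test_that("descending gains exceed ascending gains on average", {
  tab <- test_feature_table()
  ok <- is.finite(tab$fi_gain_asc) & is.finite(tab$fi_gain_desc)
  expect_true(sum(ok) >= 8)
  expect_gt(mean(tab$fi_gain_desc[ok]), mean(tab$fi_gain_asc[ok]))
})
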