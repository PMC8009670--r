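# Trace-level simulators: voltage-clamp and current-clamp responses of the
# synthetic motoneuron to triangular ramps and square steps.
#
# Unit bookkeeping: with C in nF, currents in nA and voltages in mV,
# dV/dt [mV/s] = 1000 * I/C, and the capacitive current under a ramp of
# s mV/s is C * s / 1000 nA (a constant +/- offset per limb that the leak
# fit absorbs into its intercept, as in real recordings).

ramp_command <- function(ramp, sampling_rate) {
  dt <- 1 / sampling_rate
  half <- (ramp$peak_level - ramp$start_level) / ramp$speed
  n_base <- round(ramp$baseline_duration * sampling_rate)
  n_half <- round(half * sampling_rate)
  tt <- seq(0, by = dt, length.out = n_base + 2 * n_half + 1)
  cmd <- c(rep(ramp$start_level, n_base),
           ramp$start_level + ramp$speed * dt * seq(0, n_half - 1),
           ramp$peak_level,
           ramp$peak_level - ramp$speed * dt * seq(1, n_half))
  list(time = tt, command = cmd, n_base = n_base, apex = n_base + n_half + 1)
}

step_command <- function(step, sampling_rate) {
  dt <- 1 / sampling_rate
  n_base <- round(step$baseline_duration * sampling_rate)
  n_step <- round(step$step_duration * sampling_rate)
  tt <- seq(0, by = dt, length.out = 2 * n_base + n_step)
  cmd <- c(rep(step$baseline_level, n_base),
           rep(step$step_level, n_step),
           rep(step$baseline_level, n_base))
  list(time = tt, command = cmd)
}

#' Simulate a voltage-clamp triangular ramp
#'
#' The command is a triangular voltage ramp (e.g. -80 to -40 mV at 5 mV/s);
#' the response is the model clamp current: leak + outward current
#' (instantaneous) + PIC with optional first-order activation + capacitive
#' offset + Gaussian noise. With `tau_pic = 0` and `noise_sd = 0` the
#' response minus the capacitive offset equals [steady_state_current()]
#' exactly at every sample.
#'
#' @param params a [sim_cell_params()].
#' @param ramp a [ramp_spec()] in mV units.
#' @param sampling_rate Hz, >= 100.
#' @return a [trace_sweep()] in VC mode.
#' @export
simulate_vclamp_ramp <- function(params,
                                 ramp = ramp_spec(-80, -40, 5, 1),
                                 sampling_rate = 10000) {
  if (sampling_rate < 100)
    pq_stop("sampling_rate must be >= 100 Hz", "picquant_param_error")
  rc <- ramp_command(ramp, sampling_rate)
  V <- rc$command
  dt <- 1 / sampling_rate
  m_inf <- pic_activation(params, V)
  if (params$tau_pic > 0) {
    # first-order PIC activation: m[i] = (1-a) m_inf[i] + a m[i-1],
    # a linear recursion evaluated with stats::filter
    a <- exp(-dt / params$tau_pic)
    m <- as.numeric(stats::filter(m_inf * (1 - a), a, method = "recursive",
                                  init = m_inf[1]))
  } else m <- m_inf
  I <- params$g_leak * (V - params$E_rest) +
    params$g_pic * m * (V - params$E_pic) +
    params$g_out * boltzmann(V, params$V_half_out, params$k_out) * (V - params$E_out)
  dVdt <- c(0, diff(V)) / dt                     # mV/s
  I <- I + params$C * dVdt / 1000                # capacitive offset, nA
  if (params$noise_sd > 0) {
    set.seed(derive_seed(params$seed, 1L))
    I <- I + stats::rnorm(length(I), 0, params$noise_sd)
  }
  trace_sweep(rc$time, V, I, "VC", sampling_rate, ramp)
}

# Stereotyped action-potential waveform inserted at each threshold crossing:
# linear rise (well above the 10 mV/ms detection criterion) to an
# overshooting peak, then fall to the reset potential. Returns the waveform
# samples that replace the integrated voltage.
ap_waveform <- function(v_start, v_reset, sampling_rate,
                        overshoot = 45, rise_ms = 0.4, fall_ms = 0.6) {
  n_rise <- max(2L, round(rise_ms * 1e-3 * sampling_rate))
  n_fall <- max(2L, round(fall_ms * 1e-3 * sampling_rate))
  peak <- v_start + overshoot
  c(seq(v_start, peak, length.out = n_rise + 1L)[-1L],
    seq(peak, v_reset, length.out = n_fall + 1L)[-1L])
}

integrate_cclamp <- function(params, time, I_inj, sampling_rate, noisy) {
  dt <- 1 / sampling_rate
  n <- length(time)
  V <- numeric(n); V[1] <- rest_voltage(params, I_inj[1])
  m <- pic_activation(params, V[1])
  I_adapt <- 0
  a_pic <- if (params$tau_pic > 0) exp(-dt / params$tau_pic) else 0
  a_adp <- exp(-dt / params$tau_adapt)
  spikes <- numeric(0)
  noise_scale <- if (noisy && params$noise_sd > 0) params$noise_sd * sqrt(dt) else 0
  if (noise_scale > 0) eps <- stats::rnorm(n, 0, noise_scale)
  i <- 1L
  while (i < n) {
    v <- V[i]
    m_inf <- pic_activation(params, v)
    m <- if (params$tau_pic > 0) m_inf + (m - m_inf) * a_pic else m_inf
    I_ion <- params$g_leak * (v - params$E_rest) +
      params$g_pic * m * (v - params$E_pic) +
      params$g_out * boltzmann(v, params$V_half_out, params$k_out) * (v - params$E_out)
    v_next <- v + dt * 1000 * (I_inj[i] - I_ion - I_adapt) / params$C
    if (noise_scale > 0) v_next <- v_next + eps[i]
    I_adapt <- I_adapt * a_adp
    if (v_next >= params$spike_threshold) {
      spikes <- c(spikes, time[i])
      wf <- ap_waveform(params$spike_threshold, params$V_reset, sampling_rate)
      j <- min(n, i + length(wf))
      V[(i + 1L):j] <- wf[seq_len(j - i)]
      I_adapt <- I_adapt + params$adapt_increment
      m <- pic_activation(params, params$V_reset)
      i <- j
    } else {
      V[i + 1L] <- v_next
      i <- i + 1L
    }
  }
  list(V = V, spikes = spikes)
}

# Injected current at the first threshold crossing of the noiseless
# subthreshold dynamics under a ramp (no spike insertion; used to correct
# the threshold calibration for membrane and PIC lag). NA if no crossing.
dynamic_recruitment <- function(params, ramp, sampling_rate = 2000) {
  rc <- ramp_command(ramp, sampling_rate)
  dt <- 1 / sampling_rate
  v <- rest_voltage(params, rc$command[1])
  m <- pic_activation(params, v)
  a_pic <- if (params$tau_pic > 0) exp(-dt / params$tau_pic) else 0
  for (i in seq_along(rc$time)) {
    m_inf <- pic_activation(params, v)
    m <- if (params$tau_pic > 0) m_inf + (m - m_inf) * a_pic else m_inf
    I_ion <- params$g_leak * (v - params$E_rest) +
      params$g_pic * m * (v - params$E_pic) +
      params$g_out * boltzmann(v, params$V_half_out, params$k_out) * (v - params$E_out)
    v <- v + dt * 1000 * (rc$command[i] - I_ion) / params$C
    if (v >= params$spike_threshold) return(rc$command[i])
  }
  NA_real_
}

#' Simulate a current-clamp triangular ramp
#'
#' Integrate-and-fire dynamics with the PIC, the outward current and
#' spike-triggered adaptation; at each threshold crossing a stereotyped AP
#' waveform (rise >> 10 mV/ms, ~1 ms wide, overshooting) is inserted so the
#' downstream dV/dt spike detector operates as on real traces. True spike
#' insertion times are attached as attribute `spike_times_true`.
#'
#' @param params a [sim_cell_params()].
#' @param ramp a [ramp_spec()] in nA units.
#' @param sampling_rate Hz; >= 5000 (AP insertion needs the resolution).
#' @return a [trace_sweep()] in CC mode.
#' @export
simulate_cclamp_ramp <- function(params, ramp, sampling_rate = 10000) {
  if (sampling_rate < 5000)
    pq_stop("sampling_rate < 5 kHz is too coarse for spike insertion",
            "picquant_param_error")
  rc <- ramp_command(ramp, sampling_rate)
  set.seed(derive_seed(params$seed, 2L))
  out <- integrate_cclamp(params, rc$time, rc$command, sampling_rate,
                          noisy = TRUE)
  sw <- trace_sweep(rc$time, rc$command, out$V, "CC", sampling_rate, ramp)
  attr(sw, "spike_times_true") <- out$spikes
  sw
}

#' Simulate a current-clamp square step
#'
#' @param params a [sim_cell_params()].
#' @param step a [step_spec()] in nA units.
#' @param sampling_rate Hz, >= 5000.
#' @return a [trace_sweep()] in CC mode.
#' @export
simulate_cclamp_step <- function(params, step, sampling_rate = 10000) {
  if (sampling_rate < 5000)
    pq_stop("sampling_rate < 5 kHz is too coarse for spike insertion",
            "picquant_param_error")
  sc <- step_command(step, sampling_rate)
  set.seed(derive_seed(params$seed, 3L))
  out <- integrate_cclamp(params, sc$time, sc$command, sampling_rate,
                          noisy = TRUE)
  sw <- trace_sweep(sc$time, sc$command, out$V, "CC", sampling_rate, step)
  attr(sw, "spike_times_true") <- out$spikes
  sw
}
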