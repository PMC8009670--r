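# Conductance-based point-motoneuron model used by the synthetic data
# generator. The leak-subtracted I-V of real motoneurons under a slow
# triangular voltage ramp is N-shaped: a Boltzmann-activated lumped inward
# current (the PIC stand-in, Na+/Ca2+ components merged) pulls the curve
# down between roughly -55 and -40 mV, and an opposing outward Boltzmann
# current turns it back up near the apex, producing an interior negative
# peak. A first-order activation time constant on the PIC generates the
# ascending/descending hysteresis seen on real ramps.

#' Parameters of the synthetic motoneuron
#'
#' All conductances in uS, voltages in mV, capacitance in nF, times in s,
#' currents in nA. The defaults describe a mid-sized adult mouse motoneuron.
#'
#' @param g_leak leak conductance (uS); equals the input conductance the
#'   voltage-clamp chain should recover.
#' @param E_rest leak reversal = resting potential (mV).
#' @param C membrane capacitance (nF).
#' @param g_pic maximal conductance of the lumped persistent inward current.
#' @param V_half_pic,k_pic Boltzmann half-activation and slope of the PIC.
#' @param E_pic PIC reversal potential (mV, depolarized).
#' @param tau_pic PIC activation time constant (s); 0 = instantaneous.
#' @param g_out,V_half_out,k_out,E_out opposing outward Boltzmann current.
#' @param spike_threshold integrate-and-fire threshold (mV).
#' @param V_reset post-spike reset potential (mV).
#' @param adapt_increment adaptation current added at each spike (nA).
#' @param tau_adapt adaptation decay time constant (s).
#' @param noise_sd noise scale: clamp-current SD (nA) in VC, membrane-voltage
#'   diffusion (mV/sqrt(s)) in CC.
#' @param seed integer seed used by the trace simulators.
#' @return an object of class `sim_cell_params`.
#' @export
sim_cell_params <- function(g_leak = 0.5, E_rest = -70, C = 4,
                            g_pic = 0.08, V_half_pic = -50, k_pic = 2.5,
                            E_pic = 30, tau_pic = 0,
                            g_out = 0.15, V_half_out = -35, k_out = 5,
                            E_out = -85,
                            spike_threshold = -52, V_reset = -60,
                            adapt_increment = 0.12, tau_adapt = 0.25,
                            noise_sd = 0, seed = 1L) {
  p <- list(g_leak = g_leak, E_rest = E_rest, C = C,
            g_pic = g_pic, V_half_pic = V_half_pic, k_pic = k_pic,
            E_pic = E_pic, tau_pic = tau_pic,
            g_out = g_out, V_half_out = V_half_out, k_out = k_out,
            E_out = E_out,
            spike_threshold = spike_threshold, V_reset = V_reset,
            adapt_increment = adapt_increment, tau_adapt = tau_adapt,
            noise_sd = noise_sd, seed = as.integer(seed))
  if (any(c(g_leak, g_pic, g_out) < 0))
    pq_stop("conductances must be >= 0", "picquant_param_error")
  if (k_pic <= 0 || k_out <= 0)
    pq_stop("Boltzmann slopes must be > 0", "picquant_param_error")
  if (!(E_pic > spike_threshold && spike_threshold > E_rest && E_rest > E_out))
    pq_stop("require E_pic > spike_threshold > E_rest > E_out",
            "picquant_param_error")
  structure(p, class = "sim_cell_params")
}

boltzmann <- function(V, V_half, k) 1 / (1 + exp(-(V - V_half) / k))

#' PIC steady-state activation
#' @keywords internal
pic_activation <- function(params, V) boltzmann(V, params$V_half_pic, params$k_pic)

#' Non-leak (active) steady-state current
#'
#' The PIC plus outward-current component of the model I-V; this is the
#' ground truth that voltage-clamp leak subtraction should recover.
#'
#' @param params a [sim_cell_params()].
#' @param V voltage(s) in mV.
#' @return current in nA (negative = inward).
#' @export
nonleak_current <- function(params, V) {
  params$g_pic * pic_activation(params, V) * (V - params$E_pic) +
    params$g_out * boltzmann(V, params$V_half_out, params$k_out) * (V - params$E_out)
}

#' Total steady-state clamp current
#'
#' `I(V) = g_leak (V - E_rest) + g_pic m_inf(V)(V - E_pic) +
#'  g_out n_inf(V)(V - E_out)` with Boltzmann activations. The non-leak part
#' is the ground-truth leak-subtracted current.
#'
#' @inheritParams nonleak_current
#' @return current in nA.
#' @export
steady_state_current <- function(params, V) {
  stopifnot(all(is.finite(V)))
  params$g_leak * (V - params$E_rest) + nonleak_current(params, V)
}

#' Brute-force ground-truth PIC features
#'
#' Evaluates the non-leak model current on a fine voltage grid and reports
#' the interior negative peak: the oracle against which the measurement
#' chain is validated.
#'
#' @param params a [sim_cell_params()].
#' @param v_range voltage range searched (mV).
#' @param dv grid step (mV).
#' @return list with `amplitude` (nA, >= 0), `peak_voltage` (mV) and the
#'   grid minimum value `min_current` (nA).
#' @export
oracle_pic_features <- function(params, v_range = c(-80, -40), dv = 0.01) {
  V <- seq(v_range[1], v_range[2], by = dv)
  I <- nonleak_current(params, V)
  i <- which.min(I)
  list(amplitude = max(0, -I[i]), peak_voltage = V[i], min_current = I[i])
}

#' Effective resting potential of the model
#'
#' Most hyperpolarized zero of the total steady-state membrane current at
#' a given holding current; slightly depolarized relative to `E_rest`
#' because a small fraction of the PIC is open at rest.
#'
#' @param params a [sim_cell_params()].
#' @param I_hold holding current (nA).
#' @return membrane voltage (mV).
#' @export
rest_voltage <- function(params, I_hold = 0) {
  V <- seq(params$E_out + 1, params$spike_threshold - 0.25, by = 0.05)
  f <- steady_state_current(params, V) - I_hold
  i <- which(f[-1] >= 0 & f[-length(f)] < 0)
  if (!length(i)) return(params$E_rest)
  stats::uniroot(function(v) steady_state_current(params, v) - I_hold,
                 lower = V[i[1]], upper = V[i[1] + 1], tol = 1e-8)$root
}

#' Quasi-static rheobase of the noiseless model
#'
#' Under a slow current ramp the membrane tracks its I-V nullcline; the
#' cell escapes to a spike when the injected current exceeds the largest
#' steady-state current required on the path from rest to threshold.
#'
#' @param params a [sim_cell_params()].
#' @param dv search grid step (mV).
#' @return rheobase current (nA).
#' @export
rheobase_current <- function(params, dv = 0.01) {
  V <- seq(params$E_rest, params$spike_threshold, by = dv)
  max(steady_state_current(params, V))
}

#' Solve g_pic for a target ground-truth PIC amplitude
#'
#' Inverts [oracle_pic_features()] in `g_pic` (monotone) with the outward
#' conductance tied to the PIC (`g_out = g_out_base + g_out_ratio * g_pic`)
#' so the interior negative peak survives across the cohort range.
#'
#' @param target_amplitude desired leak-subtracted amplitude (nA, >= 0).
#' @param params template parameters.
#' @param g_out_base,g_out_ratio outward-conductance coupling.
#' @return a `sim_cell_params` with calibrated `g_pic` and `g_out`.
#' @export
calibrate_g_pic <- function(target_amplitude, params = sim_cell_params(),
                            g_out_base = 0.02, g_out_ratio = 0.4) {
  stopifnot(target_amplitude >= 0)
  amp_at <- function(g) {
    p <- params; p$g_pic <- g; p$g_out <- g_out_base + g_out_ratio * g
    oracle_pic_features(p)$amplitude
  }
  if (target_amplitude < 1e-9) {
    params$g_pic <- 0; params$g_out <- g_out_base
    return(params)
  }
  hi <- 0.05
  while (amp_at(hi) < target_amplitude && hi < 64) hi <- hi * 2
  g <- stats::uniroot(function(g) amp_at(g) - target_amplitude,
                      lower = 0, upper = hi, tol = 1e-7)$root
  params$g_pic <- g
  params$g_out <- g_out_base + g_out_ratio * g
  params
}

#' Solve the spike threshold for a target quasi-static rheobase
#'
#' [rheobase_current()] is nondecreasing in the threshold; when the PIC
#' makes the target unreachable (the required current plateaus once the
#' escape point falls below PIC onset) the threshold is clamped to the
#' search bound and the attainable rheobase is returned.
#'
#' @param target_rheobase desired recruitment current (nA).
#' @param params template parameters.
#' @param bounds threshold search interval (mV).
#' @return a `sim_cell_params` with calibrated `spike_threshold` (and
#'   `V_reset` kept 8 mV below it).
#' @export
calibrate_threshold <- function(target_rheobase, params = sim_cell_params(),
                                bounds = c(-72, -30)) {
  rheo_at <- function(th) { p <- params; p$spike_threshold <- th; rheobase_current(p) }
  lo <- max(bounds[1], params$E_rest + 3)
  hi <- bounds[2]
  th <- if (target_rheobase <= rheo_at(lo)) lo
        else if (target_rheobase >= rheo_at(hi)) hi
        else stats::uniroot(function(th) rheo_at(th) - target_rheobase,
                            lower = lo, upper = hi, tol = 1e-6)$root
  params$spike_threshold <- th
  params$V_reset <- th - 8
  params
}
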