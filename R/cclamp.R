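# Current-clamp measurement chain: dV/dt spike detection, voltage
# threshold, recruitment/de-recruitment, instantaneous F-I construction,
# subprimary/primary range segmentation, gains, and firing classification.

#' Detect spikes with the 10 mV/ms dV/dt criterion
#'
#' A spike is an upward crossing of dV/dt through `dvdt_crit` (dV/dt from
#' a smoothed first difference over `smooth_ms`) followed within 2 ms by a
#' voltage peak at least 20 mV above the crossing voltage; crossings within
#' the 2 ms refractory window of the previous spike are discarded. The
#' voltage threshold of each spike is the membrane voltage at the crossing.
#'
#' @param sweep a CC-mode [trace_sweep()] sampled at >= 5 kHz.
#' @param dvdt_crit slope criterion (mV/ms), default 10.
#' @param smooth_ms smoothing window for the first difference (ms).
#' @return object of class `spike_train` with `spike_times` (s),
#'   `threshold_crossing_voltages` (mV), `peak_voltages` (mV).
#' @export
detect_spikes <- function(sweep, dvdt_crit = 10, smooth_ms = 0.2) {
  if (sweep$mode != "CC")
    pq_stop("detect_spikes expects a CC sweep", "picquant_protocol_error")
  fs <- sweep$sampling_rate
  if (fs < 5000)
    pq_stop("sampling_rate < 5 kHz: dV/dt criterion unreliable",
            "picquant_resolution_error")
  V <- sweep$response
  dt_ms <- 1000 / fs
  dvdt <- moving_average(c(0, diff(V)) / dt_ms, round(smooth_ms / dt_ms))
  up <- which(dvdt[-1] >= dvdt_crit & dvdt[-length(dvdt)] < dvdt_crit)
  win <- round(2 / dt_ms)                      # 2 ms in samples
  times <- numeric(0); vth <- numeric(0); vpk <- numeric(0)
  last <- -Inf
  for (i in up) {
    if (sweep$time[i] - last < 2e-3) next
    j <- min(length(V), i + win)
    pk <- max(V[i:j])
    if (pk >= V[i] + 20) {
      times <- c(times, sweep$time[i])
      vth <- c(vth, V[i])
      vpk <- c(vpk, pk)
      last <- sweep$time[i]
    }
  }
  structure(list(spike_times = times, threshold_crossing_voltages = vth,
                 peak_voltages = vpk), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes", length(x$spike_times)))
  if (length(x$spike_times))
    cat(sprintf(", t in [%.3f, %.3f] s, V_th %.1f mV (first)",
                min(x$spike_times), max(x$spike_times),
                x$threshold_crossing_voltages[1]))
  cat("\n"); invisible(x)
}

# Injected current at given times (linear interpolation of the command).
current_at <- function(sweep, t) {
  stats::approx(sweep$time, sweep$command, xout = t, rule = 2)$y
}

ramp_apex_time <- function(sweep) sweep$time[which.max(sweep$command)]

#' Recruitment and de-recruitment measures
#'
#' @param sweep the CC ramp sweep.
#' @param train its [detect_spikes()] result.
#' @return list with `recruitment_current`, `derecruitment_current`,
#'   `delta_i` (derecruitment - recruitment, nA), `v_threshold` (mV, first
#'   spike), `delta_f` (Hz, last ISI frequency - first ISI frequency,
#'   `NA` with fewer than 3 spikes). All `NA` for an empty train.
#' @export
recruitment_measures <- function(sweep, train) {
  ns <- length(train$spike_times)
  if (ns == 0L)
    return(list(recruitment_current = NA_real_, derecruitment_current = NA_real_,
                delta_i = NA_real_, v_threshold = NA_real_, delta_f = NA_real_))
  rec <- current_at(sweep, train$spike_times[1])
  der <- current_at(sweep, train$spike_times[ns])
  isi <- diff(train$spike_times)
  delta_f <- if (ns >= 3L) 1 / isi[length(isi)] - 1 / isi[1] else NA_real_
  list(recruitment_current = rec, derecruitment_current = der,
       delta_i = der - rec,
       v_threshold = train$threshold_crossing_voltages[1],
       delta_f = delta_f)
}

#' Instantaneous frequency-current series per ramp limb
#'
#' One point per adjacent spike pair: frequency 1/ISI against the injected
#' current at the ISI time midpoint; pairs are assigned to the ascending or
#' descending limb by the ramp apex time.
#'
#' @param sweep the CC ramp sweep.
#' @param train its [detect_spikes()] result.
#' @return list with `ascending` and `descending` data.frames (`current`
#'   nA, `frequency` Hz, ordered by time); a limb with fewer than 3 spikes
#'   yields an empty data.frame.
#' @export
instantaneous_fi <- function(sweep, train) {
  apex <- ramp_apex_time(sweep)
  limb_series <- function(tt) {
    if (length(tt) < 3L)
      return(data.frame(current = numeric(0), frequency = numeric(0)))
    mid <- (tt[-1] + tt[-length(tt)]) / 2
    data.frame(current = current_at(sweep, mid),
               frequency = 1 / diff(tt))
  }
  list(ascending = limb_series(train$spike_times[train$spike_times <= apex]),
       descending = limb_series(train$spike_times[train$spike_times > apex]))
}

#' Segment the subprimary and primary firing ranges
#'
#' Deterministic surrogate for the visual rule: starting from the ramp
#' apex and walking backward, the primary-range window grows while the
#' residual SD of the running linear fit stays below
#' `max(c1 * sd_apex, c2)` (with `sd_apex` the residual SD of the initial
#' apex window) and the local slope stays within `c3` times the apex-window
#' slope. The transition is the first point violating the rule.
#'
#' @param fi_series one limb's data.frame from [instantaneous_fi()]
#'   (points ordered by time; the apex end is the tail for the ascending
#'   limb and the head for the descending limb).
#' @param side `"ascending"` or `"descending"`.
#' @param c1,c2,c3 rule constants (defaults 2, 3 Hz, 2).
#' @param apex_window initial window size in points.
#' @return list with `transition_current` (nA), `transition_frequency`
#'   (Hz), `pr_index` (integer indices of the primary-range points in
#'   `fi_series`); all `NA`/empty when no stable apex window exists or
#'   fewer than 6 points are available.
#' @export
segment_spr_pr <- function(fi_series, side = c("ascending", "descending"),
                           c1 = 2, c2 = 3, c3 = 2, apex_window = 10) {
  side <- match.arg(side)
  n <- nrow(fi_series)
  empty <- list(transition_current = NA_real_, transition_frequency = NA_real_,
                pr_index = integer(0))
  if (n < 6L) return(empty)
  # order points from the apex outward
  ord <- if (side == "ascending") n:1 else 1:n
  cur <- fi_series$current[ord]
  freq <- fi_series$frequency[ord]
  w0 <- min(apex_window, n - 1L)
  fit_stats <- function(k) {
    f <- stats::lm.fit(cbind(1, cur[1:k]), freq[1:k])
    list(slope = unname(f$coefficients[2]),
         sd = sqrt(sum(f$residuals^2) / max(1, k - 2)))
  }
  apex <- fit_stats(w0)
  sd_lim <- max(c1 * apex$sd, c2)
  if (!is.finite(apex$slope)) return(empty)
  k_ok <- w0
  for (k in (w0 + 1L):n) {
    # residuals of the candidate point (and the next, to confirm) against
    # the running fit over the accepted window
    f <- stats::lm.fit(cbind(1, cur[1:(k - 1L)]), freq[1:(k - 1L)])
    res_at <- function(j) abs(freq[j] - (f$coefficients[1] +
                                           f$coefficients[2] * cur[j]))
    viol <- res_at(k) > sd_lim && (k == n || res_at(k + 1L) > sd_lim)
    local <- fit_stats_local(cur, freq, k, w0)
    if (viol || abs(local) > c3 * max(abs(apex$slope), 1e-12)) break
    k_ok <- k
  }
  if (k_ok == n) {
    # perfectly stable down to the first point: PR covers the whole series
    trans <- k_ok
  } else {
    # refine the boundary by a two-segment least-squares fit around the
    # break (the walk overshoots by a few points before the rule trips)
    lo <- max(w0, k_ok - 2L * w0); hi <- min(n - 2L, k_ok + w0)
    js <- lo:hi
    rss <- vapply(js, function(j) {
      f1 <- stats::lm.fit(cbind(1, cur[1:j]), freq[1:j])
      f2 <- stats::lm.fit(cbind(1, cur[(j + 1L):n]), freq[(j + 1L):n])
      sum(f1$residuals^2) + sum(f2$residuals^2)
    }, numeric(1))
    k_ok <- js[which.min(rss)]
    trans <- k_ok + 1L         # first point beyond the PR = SPR/PR boundary
  }
  pr <- sort(ord[1:k_ok])
  list(transition_current = cur[trans], transition_frequency = freq[trans],
       pr_index = pr)
}

# slope over the w0 points nearest the candidate end of the window
fit_stats_local <- function(cur, freq, k, w0) {
  i0 <- max(1L, k - w0 + 1L)
  f <- stats::lm.fit(cbind(1, cur[i0:k]), freq[i0:k])
  unname(f$coefficients[2])
}

#' F-I gain over the primary range
#'
#' OLS slope of frequency on current over the primary-range points only.
#'
#' @param fi_series one limb's F-I data.frame.
#' @param pr_index primary-range indices from [segment_spr_pr()].
#' @return gain in Hz/nA, `NA` when the PR is undefined or has < 4 points.
#' @export
fi_gain <- function(fi_series, pr_index) {
  if (length(pr_index) < 4L) return(NA_real_)
  f <- stats::lm.fit(cbind(1, fi_series$current[pr_index]),
                     fi_series$frequency[pr_index])
  unname(f$coefficients[2])
}

#' Classify a cell as repetitively firing or non-firing
#'
#' A cell is `non_firing` when its current ramp evokes at most
#' `max_ramp_spikes` spikes while a current step (when present) still
#' evokes at least one; otherwise `repetitive`.
#'
#' @param ramp_train [detect_spikes()] result of the CC ramp.
#' @param step_train optional [detect_spikes()] result of a CC step.
#' @param max_ramp_spikes cutoff (default 4, "a single or a few APs").
#' @return `"repetitive"` or `"non_firing"`.
#' @export
classify_firing <- function(ramp_train, step_train = NULL,
                            max_ramp_spikes = 4L) {
  n_ramp <- length(ramp_train$spike_times)
  step_ok <- is.null(step_train) || length(step_train$spike_times) >= 1L
  if (n_ramp <= max_ramp_spikes && step_ok) "non_firing" else "repetitive"
}

#' Resting membrane potential from the pre-ramp baseline
#'
#' Mean response over the pre-ramp baseline; the drift (difference between
#' the means of the first and last fifth of the baseline) is reported for
#' the stability QC.
#'
#' @param sweep the CC ramp sweep.
#' @param min_baseline_s minimum usable baseline (s).
#' @return list with `rmp` (mV) and `drift` (mV); both `NA` when the
#'   baseline is shorter than `min_baseline_s`.
#' @export
measure_rmp <- function(sweep, min_baseline_s = 0.5) {
  base <- sweep$protocol$baseline_duration
  if (is.null(base) || base < min_baseline_s)
    return(list(rmp = NA_real_, drift = NA_real_))
  idx <- which(sweep$time < base)
  v <- sweep$response[idx]
  k <- max(1L, length(v) %/% 5L)
  list(rmp = mean(v), drift = mean(v[seq(length(v) - k + 1L, length(v))]) -
         mean(v[seq_len(k)]))
}

#' Full current-clamp extraction for one cell
#'
#' Runs spike detection, recruitment measures, F-I construction, SPR/PR
#' segmentation and gains on the CC ramp (plus the optional CC step for
#' firing classification).
#'
#' @param ramp_sweep the CC ramp [trace_sweep()].
#' @param step_sweep optional CC step sweep.
#' @param ... forwarded to [segment_spr_pr()].
#' @return list of class `fi_measure` with the recruitment fields,
#'   `spr_pr_transition_current`, `spr_pr_transition_frequency`,
#'   `gain_asc`, `gain_desc`, `firing_class`, `rmp`, `rmp_drift`, and the
#'   underlying `train` / `fi` objects.
#' @export
extract_cclamp <- function(ramp_sweep, step_sweep = NULL, ...) {
  train <- detect_spikes(ramp_sweep)
  step_train <- if (!is.null(step_sweep)) detect_spikes(step_sweep)
  cls <- classify_firing(train, step_train)
  rmp <- measure_rmp(ramp_sweep)
  rec <- recruitment_measures(ramp_sweep, train)
  if (cls == "non_firing") {
    return(structure(c(list(recruitment_current = NA_real_,
                            derecruitment_current = NA_real_,
                            delta_i = NA_real_, v_threshold = NA_real_,
                            delta_f = NA_real_,
                            spr_pr_transition_current = NA_real_,
                            spr_pr_transition_frequency = NA_real_,
                            gain_asc = NA_real_, gain_desc = NA_real_,
                            firing_class = cls, rmp = rmp$rmp,
                            rmp_drift = rmp$drift),
                       list(train = train)), class = "fi_measure"))
  }
  fi <- instantaneous_fi(ramp_sweep, train)
  seg_a <- segment_spr_pr(fi$ascending, "ascending", ...)
  seg_d <- segment_spr_pr(fi$descending, "descending", ...)
  structure(c(rec,
              list(spr_pr_transition_current = seg_a$transition_current,
                   spr_pr_transition_frequency = seg_a$transition_frequency,
                   gain_asc = fi_gain(fi$ascending, seg_a$pr_index),
                   gain_desc = fi_gain(fi$descending, seg_d$pr_index),
                   firing_class = cls, rmp = rmp$rmp, rmp_drift = rmp$drift,
                   train = train, fi = fi)),
            class = "fi_measure")
}
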