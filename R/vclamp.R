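# Voltage-clamp measurement chain: limb splitting, linear leak fit over the
# subthreshold window, leak subtraction, and extraction of PIC amplitude,
# onset, peak and end voltages from the leak-subtracted I-V.

#' Split a triangular ramp sweep into ascending and descending limbs
#'
#' The command is median-filter denoised, the split is at the command
#' maximum, and any plateau at the apex (or residual baseline at either
#' end) is assigned to neither limb, so each limb is strictly monotonic
#' in command.
#'
#' @param sweep a VC-mode [trace_sweep()] with a triangular command.
#' @return list with `ascending` and `descending`, each a data.frame with
#'   columns `time`, `voltage` (commanded, mV), `current` (nA).
#' @export
split_ramp <- function(sweep) {
  if (sweep$mode != "VC")
    pq_stop("split_ramp expects a VC sweep", "picquant_protocol_error")
  cmd <- if (length(sweep$command) >= 9) stats::runmed(sweep$command, 5) else sweep$command
  rng <- range(cmd)
  if (diff(rng) < 1)
    pq_stop("command is not a triangular ramp (flat)", "picquant_protocol_error")
  tol <- diff(rng) * 1e-4 + 1e-9
  at_max <- which(cmd >= rng[2] - tol)
  at_min <- which(cmd <= rng[1] + tol)
  first_max <- min(at_max); last_max <- max(at_max)
  if (first_max <= 2L || last_max >= length(cmd) - 1L)
    pq_stop("command is not triangular (no interior apex)",
            "picquant_protocol_error")
  asc_start <- if (any(at_min < first_max)) max(at_min[at_min < first_max]) + 1L else 1L
  desc_end <- if (any(at_min > last_max)) min(at_min[at_min > last_max]) - 1L else length(cmd)
  asc <- asc_start:(first_max - 1L)
  desc <- (last_max + 1L):desc_end
  seg <- function(idx) data.frame(time = sweep$time[idx], voltage = cmd[idx],
                                  current = sweep$response[idx])
  list(ascending = seg(asc), descending = seg(desc))
}

#' Fit the linear leak over a subthreshold voltage window
#'
#' Ordinary least squares of clamp current on commanded voltage over the
#' window (default -80 to -65 mV, where the PIC is still closed). The slope
#' is the input conductance in uS (nA/mV); the intercept absorbs the
#' constant capacitive offset of the ramp limb.
#'
#' @param segment a limb data.frame from [split_ramp()].
#' @param window `c(low, high)` voltage window in mV.
#' @return object of class `leak_fit` with fields `slope` (uS), `intercept`
#'   (nA), `window`, `residual_sd` (nA), `n_points`.
#' @export
fit_leak <- function(segment, window = c(-80, -65)) {
  sel <- segment$voltage >= window[1] & segment$voltage <= window[2]
  n <- sum(sel)
  if (n < 10)
    pq_stop(sprintf("only %d samples inside the leak window [%g, %g]",
                    n, window[1], window[2]),
            "picquant_insufficient_data_error")
  fit <- stats::lm.fit(cbind(1, segment$voltage[sel]),
                       segment$current[sel])
  res_sd <- if (n > 2) sqrt(sum(fit$residuals^2) / (n - 2)) else 0
  structure(list(slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 window = window, residual_sd = res_sd, n_points = n),
            class = "leak_fit")
}

#' @export
print.leak_fit <- function(x, ...) {
  cat(sprintf("<leak_fit> G_in = %.4f uS, intercept %.3f nA, window [%g, %g] mV, n = %d, residual SD %.4f nA\n",
              x$slope, x$intercept, x$window[1], x$window[2], x$n_points,
              x$residual_sd))
  invisible(x)
}

#' Subtract the fitted leak from a ramp limb
#'
#' @param segment limb data.frame from [split_ramp()].
#' @param fit a [fit_leak()] result from the same cell.
#' @return data.frame with `time`, `voltage` and leak-subtracted `current`.
#' @export
subtract_leak <- function(segment, fit) {
  data.frame(time = segment$time, voltage = segment$voltage,
             current = segment$current -
               (fit$slope * segment$voltage + fit$intercept))
}

#' Measure PIC features on the leak-subtracted limbs
#'
#' Amplitude is the magnitude of the maximal downward deflection of the
#' smoothed leak-subtracted current on each limb (0 when the curve never
#' goes negative); peak voltage is the commanded voltage at that minimum
#' (earliest ascending / latest descending sample on ties). Onset voltage
#' is the first ascending voltage at which the subtracted current stays
#' below `-max(k_sd * residual_sd, floor_nA)` over a sustained `width_mv`
#' of command; end voltage applies the same criterion to the descending
#' limb, taking the last (most hyperpolarized) sustained sample. When no
#' sample meets the onset criterion the PIC is recorded as absent (onset
#' and end missing).
#'
#' @param asc_sub,desc_sub leak-subtracted limbs from [subtract_leak()].
#' @param residual_sd residual SD of the leak fit (nA), used by the onset
#'   criterion.
#' @param smooth_mv moving-average smoothing width in mV of command.
#' @param k_sd,floor_nA,width_mv onset-criterion constants.
#' @return object of class `pic_measure`.
#' @export
measure_pic <- function(asc_sub, desc_sub, residual_sd = 0,
                        smooth_mv = 0.5, k_sd = 3, floor_nA = 0.05,
                        width_mv = 1) {
  smooth_limb <- function(seg) {
    dv <- stats::median(abs(diff(seg$voltage)))
    k <- if (dv > 0) round(smooth_mv / dv) else 1L
    moving_average(seg$current, k)
  }
  asc_s <- smooth_limb(asc_sub)
  desc_s <- smooth_limb(desc_sub)

  # earliest ascending minimum; latest descending minimum on ties
  i_asc <- which.min(asc_s)
  i_desc <- length(desc_s) + 1L - which.min(rev(desc_s))
  thr <- max(k_sd * residual_sd, floor_nA)

  sustained_run <- function(active, voltage, width) {
    # indices opening a run over which `active` holds for >= width mV
    r <- rle(active)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- r$values &
      abs(voltage[ends] - voltage[starts]) >= width
    list(starts = starts[ok], ends = ends[ok])
  }

  asc_runs <- sustained_run(asc_s < -thr, asc_sub$voltage, width_mv)
  desc_runs <- sustained_run(desc_s < -thr, desc_sub$voltage, width_mv)
  onset <- if (length(asc_runs$starts)) asc_sub$voltage[asc_runs$starts[1]] else NA_real_
  end_v <- if (length(desc_runs$ends)) desc_sub$voltage[desc_runs$ends[length(desc_runs$ends)]] else NA_real_

  structure(list(
    amplitude_asc = max(0, -asc_s[i_asc]),
    amplitude_desc = max(0, -desc_s[i_desc]),
    peak_voltage_asc = asc_sub$voltage[i_asc],
    peak_voltage_desc = desc_sub$voltage[i_desc],
    onset_voltage = onset, end_voltage = end_v,
    residual_sd = residual_sd), class = "pic_measure")
}

#' Full voltage-clamp extraction for one cell
#'
#' Splits the VC ramp and fits the leak on each limb separately: the slope
#' (input conductance) is reported from the ascending fit, while the
#' limb-specific intercepts absorb the equal-and-opposite capacitive
#' offsets of the two ramp limbs. Each limb is then leak-subtracted with
#' its own fit and the PIC is measured.
#'
#' @param sweep a VC-mode ramp [trace_sweep()].
#' @param leak_window leak-fit voltage window (mV).
#' @param ... forwarded to [measure_pic()].
#' @return list with `leak_fit` (ascending-limb fit, carries G_in) and
#'   `pic` (a `pic_measure`).
#' @export
extract_vclamp <- function(sweep, leak_window = c(-80, -65), ...) {
  limbs <- split_ramp(sweep)
  fit_asc <- fit_leak(limbs$ascending, leak_window)
  fit_desc <- fit_leak(limbs$descending, leak_window)
  pic <- measure_pic(subtract_leak(limbs$ascending, fit_asc),
                     subtract_leak(limbs$descending, fit_desc),
                     residual_sd = fit_asc$residual_sd, ...)
  list(leak_fit = fit_asc, pic = pic)
}
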