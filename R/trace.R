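# Core containers for ramp recordings. Canonical units everywhere:
# mV, nA, s, Hz, uS (note uS = nA/mV, so conductance is the slope of an
# I-V line with no unit conversion).

#' Ramp protocol description
#'
#' @param start_level,peak_level ramp start and apex levels (mV in VC, nA in CC).
#' @param speed ramp speed (mV/s or nA/s), strictly positive.
#' @param baseline_duration seconds of constant `start_level` before the ramp.
#' @return an object of class `ramp_spec`.
#' @export
ramp_spec <- function(start_level, peak_level, speed, baseline_duration = 1) {
  stopifnot(is.numeric(start_level), is.numeric(peak_level), is.numeric(speed))
  if (peak_level <= start_level) pq_stop("peak_level must exceed start_level", "picquant_protocol_error")
  if (speed <= 0) pq_stop("ramp speed must be positive", "picquant_protocol_error")
  structure(list(start_level = start_level, peak_level = peak_level,
                 speed = speed, baseline_duration = baseline_duration),
            class = "ramp_spec")
}

#' Step protocol description
#'
#' @param baseline_level,step_level pre-step and step levels (nA in CC).
#' @param step_duration seconds at `step_level`.
#' @param baseline_duration seconds before (and after) the step.
#' @return an object of class `step_spec`.
#' @export
step_spec <- function(baseline_level, step_level, step_duration,
                      baseline_duration = 0.5) {
  structure(list(baseline_level = baseline_level, step_level = step_level,
                 step_duration = step_duration,
                 baseline_duration = baseline_duration),
            class = "step_spec")
}

#' A single recorded (or simulated) sweep
#'
#' Holds one protocol's time/command/response series. In VC mode the command
#' is membrane voltage (mV) and the response is clamp current (nA); in CC
#' mode the command is injected current (nA) and the response is membrane
#' voltage (mV).
#'
#' @param time seconds, uniformly sampled, monotonically increasing.
#' @param command command series (mV in VC, nA in CC).
#' @param response response series (nA in VC, mV in CC).
#' @param mode `"VC"` or `"CC"`.
#' @param sampling_rate Hz; must agree with `1/median(diff(time))` to 0.1%.
#' @param protocol a [ramp_spec()] or [step_spec()].
#' @return an object of class `trace_sweep`.
#' @export
trace_sweep <- function(time, command, response, mode, sampling_rate,
                        protocol = NULL) {
  mode <- match.arg(mode, c("VC", "CC"))
  n <- length(time)
  if (n < 2L || length(command) != n || length(response) != n)
    pq_stop("time, command and response must have equal length >= 2",
            "picquant_format_error")
  dt <- stats::median(diff(time))
  if (dt <= 0 || any(diff(time) <= 0))
    pq_stop("time must be strictly increasing", "picquant_format_error")
  if (abs(sampling_rate * dt - 1) > 1e-3)
    pq_stop("sampling_rate inconsistent with the time base (>0.1%)",
            "picquant_format_error")
  structure(list(time = as.numeric(time), command = as.numeric(command),
                 response = as.numeric(response), mode = mode,
                 sampling_rate = sampling_rate, protocol = protocol),
            class = "trace_sweep")
}

#' @export
print.trace_sweep <- function(x, ...) {
  cat(sprintf("<trace_sweep> %s, %d samples @ %g Hz, command [%.3g, %.3g], response [%.3g, %.3g]\n",
              x$mode, length(x$time), x$sampling_rate,
              min(x$command), max(x$command), min(x$response), max(x$response)))
  invisible(x)
}

#' One cell's sweeps plus metadata
#'
#' @param cell_id,animal_id identifier strings.
#' @param genotype `"WT"` or `"mSOD1"`.
#' @param age_days integer age at recording, > 0.
#' @param sweeps list of [trace_sweep()] objects.
#' @param rmp resting membrane potential (mV), `NA` before extraction.
#' @param ground_truth optional named list of simulator ground truth.
#' @return an object of class `cell_record`.
#' @export
cell_record <- function(cell_id, animal_id, genotype, age_days, sweeps,
                        rmp = NA_real_, ground_truth = NULL) {
  genotype <- match.arg(genotype, c("WT", "mSOD1"))
  age_days <- as.integer(age_days)
  if (is.na(age_days) || age_days <= 0L)
    pq_stop("age_days must be a positive integer", "picquant_format_error")
  if (!is.list(sweeps) || !all(vapply(sweeps, inherits, TRUE, "trace_sweep")))
    pq_stop("sweeps must be a list of trace_sweep objects", "picquant_format_error")
  structure(list(cell_id = as.character(cell_id),
                 animal_id = as.character(animal_id),
                 genotype = genotype, age_days = age_days,
                 sweeps = sweeps, rmp = rmp, ground_truth = ground_truth),
            class = "cell_record")
}

#' @export
print.cell_record <- function(x, ...) {
  cat(sprintf("<cell_record> %s (%s, P%d, animal %s): %d sweep(s) [%s], RMP %s mV\n",
              x$cell_id, x$genotype, x$age_days, x$animal_id, length(x$sweeps),
              paste(vapply(x$sweeps, `[[`, "", "mode"), collapse = ","),
              ifelse(is.na(x$rmp), "not measured", sprintf("%.1f", x$rmp))))
  invisible(x)
}

# First sweep of a given mode and (optionally) protocol class, or NULL.
get_sweep <- function(cell, mode, protocol_class = "ramp_spec") {
  for (sw in cell$sweeps) {
    if (sw$mode == mode &&
        (is.null(protocol_class) || inherits(sw$protocol, protocol_class)))
      return(sw)
  }
  NULL
}
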