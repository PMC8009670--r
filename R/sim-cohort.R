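# Cohort-level sampling: whole populations of synthetic motoneurons whose
# extracted properties emulate the published group distributions
# (genotype x age group), with a Gaussian-copula correlation between cell
# size (leak conductance) and PIC amplitude.

#' Specification of one cohort group
#'
#' Targets are given on the scale of the *measured* quantities (what the
#' extraction chain should recover), not raw model parameters: per-cell
#' `g_pic` is solved from the target PIC amplitude against the brute-force
#' oracle, and the spike threshold from the target recruitment current
#' against the quasi-static rheobase.
#'
#' @param genotype `"WT"` or `"mSOD1"`.
#' @param age_group one of `"P30-P60"`, `"P60-P90"`, `"P90-P120"`.
#' @param n number of cells.
#' @param age_range integer day range cells are drawn from (uniform).
#' @param g_leak,pic_amp,rmp,recruit,pic_peak_v length-2 `c(mean, sd)`
#'   target distributions (uS, nA, mV, nA, mV).
#' @param rho correlation between g_leak and PIC amplitude.
#' @param nonfiring logical: generate hypoexcitable cells (tiny PIC, strong
#'   spike-frequency adaptation) that fire at most a few spikes on a ramp
#'   while still spiking to a step.
#' @return a list of class `cohort_group_spec`.
#' @export
cohort_group_spec <- function(genotype, age_group, n, age_range,
                              g_leak, pic_amp, rmp, recruit, pic_peak_v,
                              rho = 0.74, nonfiring = FALSE) {
  stopifnot(n >= 0, length(g_leak) == 2, g_leak[2] >= 0, abs(rho) <= 1)
  structure(list(genotype = match.arg(genotype, c("WT", "mSOD1")),
                 age_group = age_group, n = as.integer(n),
                 age_range = age_range, g_leak = g_leak, pic_amp = pic_amp,
                 rmp = rmp, recruit = recruit, pic_peak_v = pic_peak_v,
                 rho = rho, nonfiring = nonfiring),
            class = "cohort_group_spec")
}

#' Cohort specification emulating the published group summaries
#'
#' Six genotype x age-group blocks with the published per-group cell counts
#' and mean/SD of input conductance, PIC amplitude, RMP, recruitment current
#' and PIC peak voltage; optionally the two small populations of non-firing
#' cells (7 WT around P100, 6 mSOD1 around P75).
#'
#' @param include_nonfiring add the hypoexcitable non-firing cells.
#' @param rho g_leak-PIC correlation (default 0.74, i.e. r^2 ~ 0.55).
#' @return list of [cohort_group_spec()] blocks, class `cohort_spec`.
#' @export
table1_cohort_spec <- function(include_nonfiring = FALSE, rho = 0.74) {
  g <- list(
    cohort_group_spec("WT",    "P30-P60",  19, c(31, 59),  c(0.42, 0.16), c(2.30, 2.17), c(-62.38, 5.52), c(4.73, 3.14), c(-43.83, 4.79), rho),
    cohort_group_spec("mSOD1", "P30-P60",  15, c(31, 59),  c(0.72, 0.18), c(6.73, 3.28), c(-71.45, 8.78), c(6.21, 2.51), c(-52.32, 4.20), rho),
    cohort_group_spec("WT",    "P60-P90",  16, c(60, 89),  c(0.46, 0.16), c(2.47, 1.69), c(-60.98, 5.35), c(5.28, 2.64), c(-42.89, 6.94), rho),
    cohort_group_spec("mSOD1", "P60-P90",  24, c(60, 89),  c(0.42, 0.15), c(2.75, 2.40), c(-66.18, 5.63), c(4.53, 3.38), c(-44.88, 5.24), rho),
    cohort_group_spec("WT",    "P90-P120", 15, c(90, 123), c(0.60, 0.15), c(4.12, 3.69), c(-64.71, 7.42), c(5.43, 3.07), c(-48.34, 5.89), rho),
    cohort_group_spec("mSOD1", "P90-P120", 14, c(90, 123), c(0.33, 0.13), c(1.90, 1.78), c(-61.99, 5.43), c(2.19, 1.56), c(-46.24, 6.27), rho))
  if (include_nonfiring) {
    g <- c(g, list(
      cohort_group_spec("WT",    "P90-P120", 7, c(84, 116), c(0.38, 0.20), c(0.60, 0.49), c(-63, 6), c(6.5, 2.0), c(-45, 5), rho, nonfiring = TRUE),
      cohort_group_spec("mSOD1", "P60-P90",  6, c(52, 98),  c(0.38, 0.20), c(0.60, 0.49), c(-63, 6), c(6.5, 2.0), c(-45, 5), rho, nonfiring = TRUE)))
  }
  structure(g, class = c("cohort_spec", "list"))
}

# Draw one cell's calibrated parameters + target record for a group.
draw_cell_params <- function(grp, seed, vhalf_peak_offset = 6,
                             tau_pic = 0.3, noise_vc = 0.1, noise_cc = 2,
                             cc_speed = 2.5, cc_margin = 4) {
  set.seed(seed)
  # Gaussian copula: correlated normals -> uniforms -> truncated marginals
  z1 <- stats::rnorm(1)
  z2 <- grp$rho * z1 + sqrt(1 - grp$rho^2) * stats::rnorm(1)
  g_leak <- qtnorm_lower(stats::pnorm(z1), grp$g_leak[1], grp$g_leak[2], 0.08)
  pic_amp <- qtnorm_lower(stats::pnorm(z2), grp$pic_amp[1], grp$pic_amp[2], 0.05)
  recruit <- qtnorm_lower(stats::runif(1), grp$recruit[1], grp$recruit[2], 0.3)
  peak_v <- min(-41, max(-60, stats::rnorm(1, grp$pic_peak_v[1], grp$pic_peak_v[2])))
  # keep rest well below PIC half-activation so the cell does not float
  # depolarized at rest (PIC essentially closed at RMP, as in accepted cells)
  rmp <- min(peak_v - 14, max(-84, stats::rnorm(1, grp$rmp[1], grp$rmp[2])))
  age <- as.integer(round(stats::runif(1, grp$age_range[1], grp$age_range[2])))
  p <- sim_cell_params(g_leak = g_leak, E_rest = rmp,
                       V_half_pic = peak_v - vhalf_peak_offset,
                       spike_threshold = rmp + 12, V_reset = rmp + 4,
                       tau_pic = tau_pic, noise_sd = noise_vc, seed = seed)
  p <- calibrate_g_pic(pic_amp, p)
  p <- calibrate_threshold(recruit, p)
  # corrective passes: the quasi-static calibration ignores membrane and
  # PIC activation lag under the ramp, which raises the realized
  # recruitment; shift the static target down by the measured lag
  st <- recruit
  for (it in 1:2) {
    apex <- max(recruit, rheobase_current(p)) + cc_margin
    dyn <- dynamic_recruitment(p, ramp_spec(0, apex, cc_speed, 1))
    if (!is.finite(dyn) || abs(dyn - recruit) < 0.05) break
    st <- max(0.3, st - (dyn - recruit))
    p <- calibrate_threshold(st, p)
  }
  if (grp$nonfiring) {
    p$adapt_increment <- 4
    p$tau_adapt <- 3
  }
  list(params = p, age = age, noise_cc = noise_cc,
       targets = list(g_leak = g_leak, pic_amplitude = pic_amp, rmp = rmp,
                      recruitment_current = recruit, pic_peak_voltage = peak_v))
}

#' Sample a synthetic cohort
#'
#' For every group block, draws per-cell parameters from truncated-normal
#' marginals with the requested g_leak-PIC correlation, calibrates each
#' cell against the measurement oracles, and simulates one voltage-clamp
#' ramp, one current-clamp ramp and one current-clamp step per cell.
#' Per-cell sub-seeds are derived from `seed`, so the same seed yields a
#' bit-identical cohort. Ground truth (parameters, oracle PIC features,
#' quasi-static rheobase, drawn targets) travels in each record's
#' `ground_truth` field.
#'
#' @param spec a `cohort_spec` (list of [cohort_group_spec()]).
#' @param seed integer master seed.
#' @param vc_rate,cc_rate sampling rates (Hz) for the two modes.
#' @param cc_speed current-clamp ramp speed (nA/s).
#' @param cc_margin how far above each cell's rheobase the current ramp
#'   apex reaches (nA).
#' @param with_step include a square current step sweep per cell.
#' @return list of [cell_record()]s.
#' @export
sample_cohort <- function(spec, seed = 1L, vc_rate = 5000, cc_rate = 5000,
                          cc_speed = 2.5, cc_margin = 4, with_step = TRUE) {
  cells <- list()
  idx <- 0L
  for (grp in spec) {
    if (grp$n == 0L) next
    for (k in seq_len(grp$n)) {
      idx <- idx + 1L
      sub <- derive_seed(seed, idx)
      d <- draw_cell_params(grp, sub, cc_speed = cc_speed, cc_margin = cc_margin)
      p <- d$params
      vc <- simulate_vclamp_ramp(p, ramp_spec(-80, -40, 5, 1), vc_rate)
      rheo <- rheobase_current(p)
      p_cc <- p; p_cc$noise_sd <- d$noise_cc
      cc <- simulate_cclamp_ramp(
        p_cc, ramp_spec(0, rheo + cc_margin, cc_speed, 1), cc_rate)
      sweeps <- list(vc, cc)
      if (with_step) {
        sweeps <- c(sweeps, list(simulate_cclamp_step(
          p_cc, step_spec(0, rheo + 2, 0.5, 0.5), cc_rate)))
      }
      tag <- if (grp$nonfiring) "nf" else "f"
      cid <- sprintf("%s_%s_%s%02d", grp$genotype,
                     gsub("[^0-9A-Za-z]", "", grp$age_group), tag, k)
      cells[[idx]] <- cell_record(
        cell_id = cid,
        animal_id = sprintf("%s_a%02d", grp$genotype, 1L + (idx - 1L) %/% 3L),
        genotype = grp$genotype, age_days = d$age, sweeps = sweeps,
        ground_truth = list(
          params = unclass(p), seed = sub, nonfiring = grp$nonfiring,
          oracle = oracle_pic_features(p), rheobase = rheo,
          targets = d$targets,
          spike_times_cc = attr(cc, "spike_times_true")))
    }
  }
  cells
}
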