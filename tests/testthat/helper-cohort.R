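# Shared fixtures, built in code. The cohort simulation is the expensive
# step, so one reduced cohort (3 cells per genotype x age group plus the
# non-firing cells) is built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

test_cohort_spec <- function(n = 3L, nonfiring = TRUE) {
  spec <- table1_cohort_spec(include_nonfiring = nonfiring)
  for (i in seq_along(spec))
    spec[[i]]$n <- if (spec[[i]]$nonfiring) 2L else n
  spec
}

test_cohort <- function() {
  if (is.null(.fixtures$cells))
    .fixtures$cells <- sample_cohort(test_cohort_spec(), seed = 20260901)
  .fixtures$cells
}

test_feature_table <- function() {
  if (is.null(.fixtures$table)) {
    qc <- qc_filter(test_cohort())
    .fixtures$table <- suppressMessages(build_feature_table(qc$kept))
  }
  .fixtures$table
}

# A quiet default cell for VC-chain tests: instantaneous noiseless PIC.
quiet_cell_params <- function(...) {
  sim_cell_params(tau_pic = 0, noise_sd = 0, ...)
}

# Minimal cell whose CC ramp baseline sits at a chosen potential; enough
# structure for the QC path without a full simulation.
qc_cell <- function(id, rmp, drift = 0, age = 45) {
  fs <- 1000; n <- 3000
  tt <- seq(0, by = 1 / fs, length.out = n)
  base_n <- 1000
  v <- c(rmp + seq(-drift / 2, drift / 2, length.out = base_n),
         rep(rmp, n - base_n))
  cmd <- c(rep(0, base_n), seq(0, 5, length.out = 1000),
           seq(5, 0, length.out = 1000))
  cc <- trace_sweep(tt, cmd, v, "CC", fs, ramp_spec(0, 5, 5, 1))
  cell_record(id, "a1", "WT", age, list(cc))
}

# Moment-matched normal feature table for the estimation-statistics layer.
normal_feature_table <- function(n_wt, n_ms, moments, seed = 1) {
  # moments: named list feature -> c(mean_wt, sd_wt, mean_ms, sd_ms)
  set.seed(seed)
  n <- n_wt + n_ms
  tab <- data.frame(cell_id = sprintf("c%04d", seq_len(n)),
                    animal_id = "a01",
                    genotype = rep(c("WT", "mSOD1"), c(n_wt, n_ms)),
                    age_days = 45L, age_group = "P30-P60",
                    firing_class = "repetitive",
                    stringsAsFactors = FALSE)
  for (f in canonical_features()) {
    if (!is.null(moments[[f]])) {
      m <- moments[[f]]
      tab[[f]] <- c(stats::rnorm(n_wt, m[1], m[2]), stats::rnorm(n_ms, m[3], m[4]))
    } else tab[[f]] <- stats::rnorm(n)
  }
  class(tab) <- c("feature_table", "data.frame")
  tab
}
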