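# Cohort pipeline: QC, age grouping, assembly of the 21-feature per-cell
# table, group comparisons, non-firing comparisons, ascending/descending
# concordance, and the end-to-end report.

#' Canonical feature names of the per-cell table
#'
#' The 21 electrophysiological features, in the order of the published
#' summary table.
#'
#' @return character vector of length 21.
#' @export
canonical_features <- function() {
  c("input_conductance", "pic_amplitude_asc", "pic_amplitude_desc",
    "current_transition_spr_pr", "recruitment_current",
    "derecruitment_current", "freq_transition_spr_pr",
    "normalized_pic_desc", "delta_i", "vthreshold_rel_rmp", "delta_f",
    "pic_peak_voltage_rel_rmp", "fi_gain_desc", "fi_gain_asc",
    "pic_onset_voltage_rel_rmp", "rmp", "vthreshold", "pic_peak_voltage",
    "pic_onset_voltage", "pic_end_voltage", "pic_peak_voltage_desc")
}

#' Assign the age group of a recording
#'
#' Half-open bins: < 60 d is P30-P60, 60-89 d is P60-P90, >= 90 d is
#' P90-P120.
#'
#' @param age_days integer vector of ages (>= 1).
#' @return character vector of group labels.
#' @export
assign_age_group <- function(age_days) {
  stopifnot(all(age_days >= 1))
  ifelse(age_days < 60, "P30-P60",
         ifelse(age_days < 90, "P60-P90", "P90-P120"))
}

#' Quality-control filter
#'
#' Excludes cells whose RMP is more depolarized than -50 mV (a cell at
#' exactly -50.0 mV is kept) and cells with an unstable baseline (drift
#' beyond `max_drift` mV). RMP and drift are measured from the CC ramp
#' baseline when not already present on the record.
#'
#' @param cells list of [cell_record()]s.
#' @param max_drift baseline drift bound (mV).
#' @return list with `kept` (cell_records, with `rmp` filled in) and
#'   `excluded` (data.frame of `cell_id`, `reason`).
#' @export
qc_filter <- function(cells, max_drift = 2) {
  kept <- list(); exc_id <- character(0); exc_reason <- character(0)
  for (cell in cells) {
    cc <- get_sweep(cell, "CC", "ramp_spec")
    meas <- if (!is.null(cc)) measure_rmp(cc) else list(rmp = cell$rmp, drift = 0)
    rmp <- if (is.na(cell$rmp)) meas$rmp else cell$rmp
    drift <- if (is.null(meas$drift)) NA_real_ else meas$drift
    if (is.na(rmp)) {
      exc_id <- c(exc_id, cell$cell_id)
      exc_reason <- c(exc_reason, "no RMP measurable")
    } else if (rmp > -50) {
      exc_id <- c(exc_id, cell$cell_id)
      exc_reason <- c(exc_reason, "depolarized RMP")
    } else if (!is.na(drift) && abs(drift) > max_drift) {
      exc_id <- c(exc_id, cell$cell_id)
      exc_reason <- c(exc_reason, "unstable RMP")
    } else {
      cell$rmp <- rmp
      kept <- c(kept, list(cell))
    }
  }
  list(kept = kept,
       excluded = data.frame(cell_id = exc_id, reason = exc_reason,
                             stringsAsFactors = FALSE))
}

#' Extract every feature of one cell
#'
#' Runs the voltage-clamp and current-clamp chains and assembles the named
#' feature vector (derived features included).
#'
#' @param cell a [cell_record()] that passed QC (rmp filled in).
#' @param ... forwarded to [extract_vclamp()].
#' @return named list: 21 features plus `firing_class`.
#' @export
extract_cell_features <- function(cell, ...) {
  vc <- get_sweep(cell, "VC", "ramp_spec")
  cc <- get_sweep(cell, "CC", "ramp_spec")
  st <- get_sweep(cell, "CC", "step_spec")
  if (is.null(vc) || is.null(cc))
    pq_stop(sprintf("cell %s lacks a VC and/or CC ramp sweep", cell$cell_id),
            "picquant_format_error")
  v <- extract_vclamp(vc, ...)
  f <- extract_cclamp(cc, st)
  rmp <- if (!is.na(cell$rmp)) cell$rmp else f$rmp
  rel <- function(x) if (is.na(x) || is.na(rmp)) NA_real_ else x - rmp
  list(input_conductance = v$leak_fit$slope,
       pic_amplitude_asc = v$pic$amplitude_asc,
       pic_amplitude_desc = v$pic$amplitude_desc,
       current_transition_spr_pr = f$spr_pr_transition_current,
       recruitment_current = f$recruitment_current,
       derecruitment_current = f$derecruitment_current,
       freq_transition_spr_pr = f$spr_pr_transition_frequency,
       normalized_pic_desc = if (is.finite(v$leak_fit$slope) && v$leak_fit$slope > 0)
         v$pic$amplitude_desc / v$leak_fit$slope else NA_real_,
       delta_i = f$delta_i,
       vthreshold_rel_rmp = rel(f$v_threshold),
       delta_f = f$delta_f,
       pic_peak_voltage_rel_rmp = rel(v$pic$peak_voltage_asc),
       fi_gain_desc = f$gain_desc,
       fi_gain_asc = f$gain_asc,
       pic_onset_voltage_rel_rmp = rel(v$pic$onset_voltage),
       rmp = rmp,
       vthreshold = f$v_threshold,
       pic_peak_voltage = v$pic$peak_voltage_asc,
       pic_onset_voltage = v$pic$onset_voltage,
       pic_end_voltage = v$pic$end_voltage,
       pic_peak_voltage_desc = v$pic$peak_voltage_desc,
       firing_class = f$firing_class)
}

#' Build the 21-feature per-cell table
#'
#' One row per QC-passed cell: metadata (`cell_id`, `animal_id`,
#' `genotype`, `age_days`, `age_group`), the 21 canonical features, and
#' `firing_class`. Missing features propagate as `NA`.
#'
#' @param cells QC-passed [cell_record()]s.
#' @param ... forwarded to [extract_cell_features()].
#' @return data.frame (class `feature_table`).
#' @export
build_feature_table <- function(cells, ...) {
  ids <- vapply(cells, `[[`, "", "cell_id")
  if (anyDuplicated(ids))
    pq_stop(paste("duplicate cell_id:", ids[duplicated(ids)][1]),
            "picquant_integrity_error")
  rows <- lapply(cells, function(cell) {
    pq_log("extracting features", cell$cell_id, "extract")
    feats <- extract_cell_features(cell, ...)
    c(list(cell_id = cell$cell_id, animal_id = cell$animal_id,
           genotype = cell$genotype, age_days = cell$age_days,
           age_group = assign_age_group(cell$age_days)),
      feats)
  })
  tab <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  class(tab) <- c("feature_table", "data.frame")
  tab
}

#' Genotype comparisons per feature and age group
#'
#' For each of the 21 features and each age group present with at least
#' `min_n` cells per genotype, computes Hedges' g of mSOD1 versus WT
#' (positive g = larger in mSOD1) with the BCa bootstrap interval.
#'
#' @param table a feature table.
#' @param n_boot bootstrap resamples per comparison.
#' @param seed master seed (a sub-seed is derived per comparison).
#' @param min_n minimum cells per genotype in a group.
#' @return data.frame with one row per feature x age group, sorted within
#'   each group by descending g in the P30-P60 group ordering; columns
#'   include `g`, `ci_low`, `ci_high`, `welch_t`, `df_pooled`, `p`,
#'   `n_wt`, `n_msod1`.
#' @export
compare_groups <- function(table, n_boot = 5000, seed = 1L, min_n = 2L) {
  groups <- sort(unique(table$age_group))
  out <- list(); k <- 0L
  for (feat in canonical_features()) {
    for (grp in groups) {
      sub <- table[table$age_group == grp, ]
      wt <- sub[[feat]][sub$genotype == "WT"]
      ms <- sub[[feat]][sub$genotype == "mSOD1"]
      wt <- wt[is.finite(wt)]; ms <- ms[is.finite(ms)]
      if (length(wt) < min_n || length(ms) < min_n) {
        warning(sprintf("skipping %s in %s: fewer than %d cells per genotype",
                        feat, grp, min_n), call. = FALSE)
        next
      }
      k <- k + 1L
      es <- hedges_g(wt, ms, n_boot = n_boot, seed = derive_seed(seed, k))
      out[[k]] <- data.frame(feature = feat, age_group = grp,
                             g = es$g, ci_low = es$ci_low, ci_high = es$ci_high,
                             mean_wt = es$mean1, mean_msod1 = es$mean2,
                             sd_wt = es$sd1, sd_msod1 = es$sd2,
                             n_wt = es$n1, n_msod1 = es$n2,
                             welch_t = es$welch_t, welch_df = es$welch_df,
                             df_pooled = es$df_pooled, p = es$p,
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  # order features by descending effect size in the youngest group
  g30 <- res$g[match(paste(res$feature, "P30-P60"),
                     paste(res$feature, res$age_group))]
  res[order(-g30, res$feature, res$age_group), ]
}

#' Firing versus non-firing comparisons
#'
#' Within one genotype (default mSOD1), compares input conductance and
#' ascending PIC amplitude between repetitively-firing and non-firing
#' cells (g signed firing -> non-firing), and compares the age at
#' recording of non-firing cells across genotypes.
#'
#' @param table a feature table with a `firing_class` column.
#' @param genotype genotype for the within-genotype comparisons.
#' @param n_boot,seed bootstrap controls.
#' @param min_n minimum cells per class.
#' @return list with `input_conductance`, `pic_amplitude` and
#'   `age_nonfiring` (`effect_size` objects or `NULL` when a class is
#'   missing).
#' @export
nonfiring_comparison <- function(table, genotype = "mSOD1", n_boot = 5000,
                                 seed = 1L, min_n = 2L) {
  sub <- table[table$genotype == genotype, ]
  fire <- sub[sub$firing_class == "repetitive", ]
  nf <- sub[sub$firing_class == "non_firing", ]
  cmp <- function(col, s) {
    a <- fire[[col]][is.finite(fire[[col]])]
    b <- nf[[col]][is.finite(nf[[col]])]
    if (length(a) < min_n || length(b) < min_n) return(NULL)
    hedges_g(a, b, n_boot = n_boot, seed = derive_seed(seed, s))
  }
  nf_wt <- table[table$genotype == "WT" & table$firing_class == "non_firing", ]
  age_cmp <- if (nrow(nf_wt) >= min_n && nrow(nf) >= min_n)
    hedges_g(nf_wt$age_days, nf$age_days, n_boot = n_boot,
             seed = derive_seed(seed, 3L))
  else NULL
  list(input_conductance = cmp("input_conductance", 1L),
       pic_amplitude = cmp("pic_amplitude_asc", 2L),
       age_nonfiring = age_cmp)
}

#' Ascending/descending concordance
#'
#' Squared Pearson correlations for the four paired measures: PIC
#' amplitude (asc vs desc), PIC onset vs end voltage, PIC peak voltage
#' (asc vs desc), and recruitment vs de-recruitment current.
#'
#' @param table a feature table.
#' @param min_n minimum complete pairs.
#' @return named numeric vector of r-squared values (`NA` where variance
#'   is degenerate or pairs are too few).
#' @export
asc_desc_concordance <- function(table, min_n = 3L) {
  pairs <- list(
    pic_amplitude = c("pic_amplitude_asc", "pic_amplitude_desc"),
    pic_onset_voltage = c("pic_onset_voltage", "pic_end_voltage"),
    pic_peak_voltage = c("pic_peak_voltage", "pic_peak_voltage_desc"),
    recruitment_current = c("recruitment_current", "derecruitment_current"))
  vapply(pairs, function(p) {
    x <- table[[p[1]]]; y <- table[[p[2]]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < min_n || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(NA_real_)
    stats::cor(x[ok], y[ok])^2
  }, numeric(1))
}

#' End-to-end report on a cohort
#'
#' Runs QC, feature extraction, genotype comparisons, age regressions of
#' the headline features, the ANCOVA per age group, the non-firing
#' comparisons, concordance, and PCA; optionally writes the feature table
#' (CSV) and the statistics (JSON) to `out_dir`. Deterministic under a
#' fixed seed.
#'
#' @param cells list of [cell_record()]s (e.g. from [sample_cohort()]).
#' @param out_dir optional output directory.
#' @param n_boot bootstrap resamples.
#' @param seed seed for all resampling.
#' @return list with `table`, `excluded`, `effects`, `regressions`,
#'   `ancova`, `nonfiring`, `concordance`, `pca` (and `paths` when
#'   written).
#' @export
run_report <- function(cells, out_dir = NULL, n_boot = 5000, seed = 1L) {
  if (length(cells) == 0)
    pq_stop("empty cohort: expected a list of cell_record objects, each with one VC ramp and one CC ramp sweep",
            "picquant_format_error")
  qc <- qc_filter(cells)
  table <- build_feature_table(qc$kept)
  effects <- compare_groups(table, n_boot = n_boot, seed = seed)
  wk <- age_weeks(table$age_days)
  regr <- lapply(c(pic_amplitude_asc = "pic_amplitude_asc",
                   input_conductance = "input_conductance",
                   rmp = "rmp"), function(col) {
    lapply(c(WT = "WT", mSOD1 = "mSOD1"), function(gt) {
      i <- table$genotype == gt & is.finite(table[[col]])
      if (sum(i) < 3) return(NULL)
      unclass(regress_with_ci(wk[i], table[[col]][i]))
    })
  })
  anc <- lapply(split(table, table$age_group), function(sub) {
    tryCatch(ancova_pic_conductance(sub), picquant_error = function(e) NULL)
  })
  nonf <- nonfiring_comparison(table, n_boot = n_boot, seed = derive_seed(seed, 1000L))
  conc <- asc_desc_concordance(table)
  pca <- tryCatch(pca_features(table), picquant_error = function(e) NULL)
  rep <- list(table = table, excluded = qc$excluded, effects = effects,
              regressions = regr, ancova = anc, nonfiring = nonf,
              concordance = conc, pca = pca)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tab_path <- file.path(out_dir, "feature_table.csv")
    write_feature_table(table, tab_path)
    stats_path <- file.path(out_dir, "stats.json")
    strip <- function(x) {
      if (inherits(x, "effect_size")) x$boot_g <- NULL
      if (is.list(x)) x <- lapply(x, strip)
      x
    }
    json <- list(
      excluded = qc$excluded, effects = effects,
      regressions = regr, ancova = anc,
      nonfiring = strip(nonf), concordance = as.list(conc),
      pca = if (!is.null(pca)) list(
        explained_variance_ratio = pca$explained_variance_ratio,
        n_cells = pca$n_cells, n_dropped = pca$n_dropped))
    jsonlite::write_json(json, stats_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    rep$paths <- c(feature_table = tab_path, stats = stats_path)
  }
  rep
}
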