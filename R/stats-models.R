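# Model-based statistics: regressions against age, the ANCOVA of PIC
# amplitude on input conductance by genotype, and PCA of the standardized
# feature table.

#' Ordinary least-squares regression with a slope confidence interval
#'
#' @param x predictor (e.g. age in weeks).
#' @param y response.
#' @param conf confidence level for the slope interval (t distribution,
#'   n - 2 df).
#' @return object of class `regression_result`: `slope`, `intercept`,
#'   `ci_low`, `ci_high`, `r2`, `p` (slope test), `n`.
#' @export
regress_with_ci <- function(x, y, conf = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) pq_stop("need n >= 3 complete pairs", "picquant_degenerate_error")
  if (stats::sd(x) == 0)
    pq_stop("constant predictor: rank-deficient design", "picquant_rank_error")
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))   # quiet on exact fits
  ci <- suppressWarnings(stats::confint(fit, "x", level = conf))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 ci_low = ci[1], ci_high = ci[2],
                 r2 = sm$r.squared,
                 p = sm$coefficients[2, 4], n = n),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression> slope = %.3g 95%%CI[%.3g, %.3g], r2 = %.3f, p = %.3g (n = %d)\n",
              x$slope, x$ci_low, x$ci_high, x$r2, x$p, x$n))
  invisible(x)
}

#' Convert age in days to weeks
#' @param age_days numeric days.
#' @return weeks (days / 7).
#' @export
age_weeks <- function(age_days) age_days / 7

#' ANCOVA of PIC amplitude on input conductance by genotype
#'
#' Fits `pic_amplitude_asc ~ input_conductance * genotype`; when the
#' interaction is not significant (p >= `alpha`) the model is refit
#' without it and the additive genotype effect is reported with its
#' confidence interval.
#'
#' @param table a feature table (see [build_feature_table()]) with both
#'   genotypes, the `input_conductance` and `pic_amplitude_asc` columns.
#' @param alpha interaction screen threshold (default 0.05).
#' @param conf confidence level.
#' @return list with `interaction` (`t`, `df`, `p`), `model`
#'   (`"additive"` or `"interaction"`), and `genotype_effect`
#'   (`estimate`, `ci_low`, `ci_high`, `t`, `df`, `p`).
#' @export
ancova_pic_conductance <- function(table, alpha = 0.05, conf = 0.95) {
  d <- table[is.finite(table$input_conductance) &
               is.finite(table$pic_amplitude_asc), ]
  if (length(unique(d$genotype)) < 2 || any(table(d$genotype) < 3))
    pq_stop("both genotypes with >= 3 cells required", "picquant_design_error")
  d$genotype <- factor(d$genotype, levels = c("WT", "mSOD1"))
  # center the covariate so the genotype coefficient is the effect at the
  # mean conductance (identical in the additive model, and the meaningful
  # contrast when the interaction is retained)
  d$input_conductance <- d$input_conductance - mean(d$input_conductance)
  full <- stats::lm(pic_amplitude_asc ~ input_conductance * genotype, data = d)
  cf <- summary(full)$coefficients
  irow <- grep(":", rownames(cf))
  inter <- list(t = cf[irow, "t value"], df = full$df.residual,
                p = cf[irow, "Pr(>|t|)"])
  use_additive <- inter$p >= alpha
  fit <- if (use_additive)
    stats::lm(pic_amplitude_asc ~ input_conductance + genotype, data = d)
  else full
  cf2 <- summary(fit)$coefficients
  grow <- grep("^genotype", rownames(cf2))[1]
  ci <- stats::confint(fit, rownames(cf2)[grow], level = conf)
  list(interaction = inter,
       model = if (use_additive) "additive" else "interaction",
       genotype_effect = list(estimate = cf2[grow, "Estimate"],
                              ci_low = ci[1], ci_high = ci[2],
                              t = cf2[grow, "t value"],
                              df = fit$df.residual,
                              p = cf2[grow, "Pr(>|t|)"]),
       n = nrow(d))
}

#' PCA of the standardized 21-feature table
#'
#' Complete-case cells are z-scored per feature (SD with n-1 denominator)
#' and projected; `n_components` components are retained and the
#' feature-by-component correlation matrix (the loadings heatmap analogue)
#' is computed.
#'
#' @param table a feature table.
#' @param n_components components to retain (default 5).
#' @return object of class `pca_result`: `explained_variance_ratio` (all
#'   components), `loadings` (feature x retained-component correlations),
#'   `scores` (cell x retained components, with cell_id rownames),
#'   `n_components`, `n_cells`, `n_dropped`.
#' @export
pca_features <- function(table, n_components = 5) {
  feats <- canonical_features()
  missing_cols <- setdiff(feats, names(table))
  if (length(missing_cols))
    pq_stop(paste("feature columns missing:", paste(missing_cols, collapse = ", ")),
            "picquant_schema_error")
  m <- as.matrix(table[, feats])
  complete <- stats::complete.cases(m)
  n_dropped <- sum(!complete)
  if (n_dropped)
    pq_log(sprintf("%d cell(s) dropped (incomplete features)", n_dropped),
           stage = "pca")
  m <- m[complete, , drop = FALSE]
  if (nrow(m) < 6) pq_stop("need >= 6 complete-case cells", "picquant_degenerate_error")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    pq_stop(paste("zero-variance feature:",
                  paste(feats[sds == 0], collapse = ", ")),
            "picquant_scaling_error")
  z <- scale(m)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  ratio <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rownames(scores) <- table$cell_id[complete]
  loadings <- stats::cor(z, scores)
  structure(list(explained_variance_ratio = ratio,
                 loadings = loadings, scores = scores,
                 n_components = k, n_cells = nrow(m),
                 n_dropped = n_dropped),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d cells (%d dropped), first %d ratios: %s\n",
              x$n_cells, x$n_dropped, min(3, x$n_components),
              paste(sprintf("%.1f%%", 100 * x$explained_variance_ratio[1:min(3, x$n_components)]),
                    collapse = ", ")))
  invisible(x)
}
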