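test_that("summary-based Hedges' g has the standard algebraic properties", {
  g <- hedges_g_from_summary(10, 2, 12, 13, 2.5, 9)
  # antisymmetry and location/scale invariance
  expect_equal(as.numeric(hedges_g_from_summary(13, 2.5, 9, 10, 2, 12)),
               -as.numeric(g), tolerance = 1e-12)
  expect_equal(as.numeric(hedges_g_from_summary(3 * 10 + 1, 3 * 2, 12,
                                                3 * 13 + 1, 3 * 2.5, 9)),
               as.numeric(g), tolerance = 1e-12)
  expect_equal(as.numeric(hedges_g_from_summary(5, 1, 10, 5, 1, 10)), 0)
  expect_error(hedges_g_from_summary(1, 0, 5, 2, 0, 5),
               class = "picquant_degenerate_error")
})

test_that("exact and approximate small-sample corrections agree for df >= 10", {
  for (df in seq(10, 80, by = 2)) {
    j_exact <- exp(lgamma(df / 2) - log(sqrt(df / 2)) - lgamma((df - 1) / 2))
    j_approx <- 1 - 3 / (4 * df - 1)
    expect_lt(abs(j_exact - j_approx), 5e-4)
  }
  g <- hedges_g_from_summary(0, 1, 10, 1, 1, 10)
  expect_equal(as.numeric(g), attr(g, "g_approx"), tolerance = 1e-3)
})

test_that("sample-based g agrees with an independent bootstrap implementation", {
  skip_if_not_installed("boot")
  set.seed(11)
  x <- rnorm(19); y <- rnorm(15) + 0.8
  es <- hedges_g(x, y, n_boot = 4000, seed = 2)
  # point estimate equals the summary form on the sample moments
  expect_equal(es$g, as.numeric(hedges_g_from_summary(
    mean(x), sd(x), 19, mean(y), sd(y), 15)))
  # BCa interval against boot::boot.ci with stratified resampling
  dat <- data.frame(v = c(x, y), grp = rep(1:2, c(19, 15)))
  stat <- function(d, i) {
    di <- d[i, ]
    as.numeric(hedges_g_from_summary(
      mean(di$v[di$grp == 1]), sd(di$v[di$grp == 1]), sum(di$grp == 1),
      mean(di$v[di$grp == 2]), sd(di$v[di$grp == 2]), sum(di$grp == 2)))
  }
  set.seed(7)
  b <- boot::boot(dat, stat, R = 4000, strata = dat$grp)
  ci <- boot::boot.ci(b, type = "bca")$bca[4:5]
  expect_lt(abs(es$ci_low - ci[1]), 0.15)
  expect_lt(abs(es$ci_high - ci[2]), 0.15)
  # Welch attachment matches t.test
  tt <- t.test(x, y)
  expect_equal(es$welch_t, unname(tt$statistic))
  expect_equal(es$welch_df, unname(tt$parameter))
})

test_that("degenerate samples give a degenerate interval, not an error", {
  es <- hedges_g(rep(2, 5), rep(2, 7), n_boot = 100, seed = 1)
  expect_equal(es$g, 0)
  expect_equal(c(es$ci_low, es$ci_high), c(0, 0))
  expect_error(hedges_g(c(1), c(1, 2)), class = "picquant_degenerate_error")
})

test_that("the BCa interval reduces to the percentile interval without bias", {
  set.seed(3)
  x <- rnorm(60); y <- rnorm(60)   # symmetric null: bias and acceleration ~ 0
  bca <- hedges_g(x, y, n_boot = 4000, seed = 5)
  pct <- hedges_g(x, y, n_boot = 4000, seed = 5, ci_type = "percentile")
  expect_lt(abs(bca$ci_low - pct$ci_low), 0.05)
  expect_lt(abs(bca$ci_high - pct$ci_high), 0.05)
})

test_that("regression slope intervals equal the closed-form OLS result", {
  r <- regress_with_ci(1:10, 2 * (1:10))
  expect_equal(r$slope, 2)
  expect_equal(r$r2, 1)
  expect_lt(r$ci_high - r$ci_low, 1e-8)

  set.seed(8)
  x <- rnorm(40); y <- 3 - 0.45 * x + rnorm(40, 0, 0.7)
  r2 <- regress_with_ci(x, y)
  # closed form: slope +/- t_{n-2} * s / sqrt(Sxx)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  s <- sqrt(sum((y - a - b * x)^2) / 38)
  half <- qt(0.975, 38) * s / sqrt(sum((x - mean(x))^2))
  expect_equal(r2$slope, b, tolerance = 1e-10)
  expect_equal(r2$ci_low, b - half, tolerance = 1e-10)
  expect_equal(r2$ci_high, b + half, tolerance = 1e-10)
  expect_error(regress_with_ci(rep(1, 5), rnorm(5)), class = "picquant_rank_error")
})

test_that("the ANCOVA screens the interaction and recovers planted effects", {
  # mSOD1 shifted along the common conductance-PIC line: no genotype effect
  set.seed(5)
  n <- 30
  gcond <- c(runif(n, 0.3, 0.6), runif(n, 0.5, 0.9))
  tb <- data.frame(input_conductance = gcond,
                   pic_amplitude_asc = 7.7 * gcond + rnorm(2 * n, 0, 0.3),
                   genotype = rep(c("WT", "mSOD1"), each = n))
  a <- ancova_pic_conductance(tb)
  expect_identical(a$model, "additive")
  expect_lt(abs(a$genotype_effect$estimate), 0.3)
  expect_gt(a$genotype_effect$p, 0.05)

  # planted 2 nA offset at fixed conductance: CI covers it in >= 93% of runs
  hits <- 0L
  for (r in 1:300) {
    set.seed(r)
    gc2 <- runif(40, 0.3, 0.8)
    tb2 <- data.frame(
      input_conductance = gc2,
      pic_amplitude_asc = 7 * gc2 + rep(c(0, 2), each = 20) + rnorm(40, 0, 1),
      genotype = rep(c("WT", "mSOD1"), each = 20))
    a2 <- ancova_pic_conductance(tb2)
    if (a2$genotype_effect$ci_low <= 2 && 2 <= a2$genotype_effect$ci_high)
      hits <- hits + 1L
  }
  expect_gte(hits / 300, 0.93)

  expect_error(ancova_pic_conductance(
    data.frame(input_conductance = runif(8), pic_amplitude_asc = runif(8),
               genotype = "WT")), class = "picquant_design_error")
})

test_that("PCA standardizes, orders components and exposes block structure", {
  set.seed(6)
  n <- 40
  z <- rnorm(n)
  tab <- as.data.frame(matrix(rnorm(n * 21, sd = 0.4), n, 21))
  names(tab) <- canonical_features()
  cur_feats <- c("input_conductance", "pic_amplitude_asc", "recruitment_current")
  volt_feats <- c("rmp", "vthreshold", "pic_onset_voltage")
  for (f in cur_feats) tab[[f]] <- tab[[f]] + z
  for (f in volt_feats) tab[[f]] <- tab[[f]] - z   # anti-correlated block
  tab$cell_id <- sprintf("c%02d", 1:n)
  p <- pca_features(tab)
  expect_true(all(diff(p$explained_variance_ratio) <= 1e-12))
  expect_equal(sum(p$explained_variance_ratio), 1)
  expect_equal(p$n_components, 5)
  expect_lt(max(abs(colMeans(p$scores))), 1e-10)
  # PC1 carries the two blocks with opposite signs
  l1 <- p$loadings[, 1]
  expect_true(all(sign(l1[cur_feats]) == -sign(l1[volt_feats])))
  expect_gt(min(abs(l1[c(cur_feats, volt_feats)])), 0.5)

  tab$rmp <- 1  # zero variance must be reported by name
  err <- tryCatch(pca_features(tab), error = identity)
  expect_s3_class(err, "picquant_scaling_error")
  expect_match(conditionMessage(err), "rmp")
})
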