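make_table <- function() {
  grid <- seq(0, 24, by = 4)
  rows <- expand.grid(genotype = c("WT", "mutA"), gene = c("Per1", "Bmal1"),
                      CT = grid, replicate = 1:3,
                      stringsAsFactors = FALSE)
  rows$value <- 1 + 0.5 * cos(2 * pi * rows$CT / 24) +
    0.01 * rows$replicate
  timecourse_table(rows)
}

test_that("time-course tables are validated against their invariants", {
  tab <- make_table()
  expect_s3_class(tab, "timecourse_table")
  bad <- as.data.frame(tab); bad$CT[1] <- 3
  expect_error(timecourse_table(bad), "sampling grid")
  bad2 <- as.data.frame(tab); bad2$value[1] <- -1
  expect_error(timecourse_table(bad2), "non-negative")
  expect_error(timecourse_table(as.data.frame(tab)[, -5]), "missing column")
})

test_that("mean profiles reduce replicates correctly", {
  grid <- seq(0, 24, by = 4)
  d <- data.frame(genotype = "WT", gene = "Per1",
                  CT = rep(grid, each = 3), replicate = rep(1:3, 7),
                  value = rep(c(1, 2, 3), 7))
  tab <- timecourse_table(d)
  mp <- mean_profile(tab, "WT", "Per1")
  expect_equal(mp$mean, rep(2, 7))
  expect_equal(mp$sd, rep(1, 7))   # sample SD of (1, 2, 3)
  # single replicate: mean is the value, SD zero
  d1 <- d[d$replicate == 1, ]
  mp1 <- mean_profile(timecourse_table(d1), "WT", "Per1")
  expect_equal(mp1$mean, rep(1, 7))
  expect_equal(mp1$sd, rep(0, 7))
})

test_that("replicate noise has the configured magnitude", {
  # Monte-Carlo oracle: pooled empirical CV of n = 3 lognormal replicates
  # at CV 0.1 (sample CV is slightly biased low at n = 3)
  set.seed(11)
  cvs <- replicate(200, {
    x <- .lognorm_factors <- stats::rlnorm(3, -0.5 * log(1.01),
                                           sqrt(log(1.01)))
    stats::sd(x) / mean(x)
  })
  expect_gt(mean(cvs), 0.07)
  expect_lt(mean(cvs), 0.13)
})

test_that("relative amplitude implements the wild-type-relative formula", {
  grid <- seq(0, 24, by = 4)
  wt <- data.frame(CT = grid, mean = c(1.5, 1.2, 0.8, 0.5, 0.8, 1.2, 1.5))
  mut <- data.frame(CT = grid, mean = c(2.0, 1.5, 0.9, 0.5, 0.9, 1.5, 2.0))
  # direct arithmetic: (2.0 - 0.5) / (1.5 - 0.5)
  expect_equal(relative_amplitude(mut, wt), 1.5)
  # self-normalisation and linearity
  expect_equal(relative_amplitude(wt, wt), 1)
  mut2 <- wt; mut2$mean <- 2 * wt$mean
  expect_equal(relative_amplitude(mut2, wt), 2)
  # scale equivariance in the mutant, scale inversion in the reference
  expect_equal(relative_amplitude(mut, wt),
               relative_amplitude(transform(mut, mean = 3 * mean), wt) / 3)
  wts <- transform(wt, mean = 2 * mean)
  expect_equal(relative_amplitude(mut, wts),
               relative_amplitude(mut, wt) / 2)
  # flat reference is an error
  flat <- data.frame(CT = grid, mean = rep(1, 7))
  expect_error(relative_amplitude(mut, flat), "flat")
})

test_that("amplitude ratios propagate replicate errors to first order", {
  expect_equal(amplitude_ratio(1, 1)$ratio, 1)
  expect_equal(amplitude_ratio(1.5, 0.5)$ratio, 3)
  expect_error(amplitude_ratio(1, 0), "positive")
  # delta method against Monte Carlo
  set.seed(21)
  num <- stats::rnorm(20000, 2, 0.1); den <- stats::rnorm(20000, 1, 0.08)
  mc <- stats::sd(num / den)
  delta <- amplitude_ratio(2, 1, 0.1, 0.08)$sd
  expect_lt(abs(mc - delta) / mc, 0.05)
})

test_that("percent-of-max normalisation is idempotent and cancels in amplitudes", {
  tab <- make_table()
  n1 <- normalize_percent_max(tab)
  n2 <- normalize_percent_max(n1)
  expect_equal(n1$value, n2$value, tolerance = 1e-12)
  a_raw <- relative_amplitude(mean_profile(tab, "mutA", "Per1"),
                              mean_profile(tab, "WT", "Per1"))
  a_nrm <- relative_amplitude(mean_profile(n1, "mutA", "Per1"),
                              mean_profile(n1, "WT", "Per1"))
  expect_equal(a_raw, a_nrm, tolerance = 1e-12)
})

test_that("monotonicity test detects decreasing relations and respects the null", {
  d <- data.frame(genotype = letters[1:8],
                  ratio = seq(3, 0.3, length.out = 8),
                  period = seq(22, 27, length.out = 8))
  out <- monotonicity_test(d, exclusions = character(0), n_perm = 2000)
  expect_equal(out$rho, -1)
  expect_lt(out$p_value, 0.01)
  # independent pairs: the null median |rho| stays moderate at n = 10
  set.seed(42)
  rhos <- replicate(1000, abs(stats::cor(stats::runif(10), stats::runif(10),
                                         method = "spearman")))
  expect_lt(stats::median(rhos), 0.5)
  # degenerate all-tied input is refused
  tied <- data.frame(genotype = letters[1:6], ratio = 1, period = 1:6)
  expect_error(monotonicity_test(tied, exclusions = character(0)), "tied")
  expect_error(monotonicity_test(d[1:4, ], exclusions = character(0)),
               "fewer than 5")
})

test_that("the full pipeline on noiseless panels is an exact round trip", {
  pan <- generate_panel(panel_config(cv = 0, seed = 1))
  summ <- genotype_summaries(pan$table,
                             data.frame(genotype = pan$truth$genotype,
                                        period = pan$truth$period))
  m <- match(summ$genotype, pan$truth$genotype)
  expect_equal(summ$rel_amp_Per1, pan$truth$rel_amp_Per1[m], tolerance = 1e-12)
  expect_equal(summ$rel_amp_Bmal1, pan$truth$rel_amp_Bmal1[m],
               tolerance = 1e-12)
  expect_equal(summ$ratio, pan$truth$ratio[m], tolerance = 1e-12)
})
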