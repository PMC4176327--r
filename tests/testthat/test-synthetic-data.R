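test_that("generators are deterministic per seed", {
  a <- generate_panel(panel_config(seed = 7))
  b <- generate_panel(panel_config(seed = 7))
  expect_identical(a$table$value, b$table$value)
  c1 <- generate_trace(trace_config(seed = 4))
  c2 <- generate_trace(trace_config(seed = 4))
  expect_identical(c1$trace$value, c2$trace$value)
  d <- generate_panel(panel_config(seed = 8))
  expect_false(identical(a$table$value, d$table$value))
  expect_error(panel_config(), "seed")
  expect_error(trace_config(), "seed")
})

test_that("the noise-free limit reproduces the mean curves exactly", {
  pan <- generate_panel(panel_config(cv = 0, n_rep = 3, seed = 2))
  one <- pan$table[pan$table$genotype == "WT" & pan$table$gene == "Per1", ]
  v <- matrix(one$value, ncol = 3)
  expect_equal(v[, 1], v[, 2])
  expect_equal(v[, 1], v[, 3])
  expect_error(panel_config(cv = -0.1, seed = 1), "CV")
})

test_that("the default panel embeds the decreasing ratio-period relation", {
  truth <- default_panel_truth()
  keep <- truth$genotype != "Cry1-KO"
  rho <- stats::cor(truth$rel_amp_Per1[keep] / truth$rel_amp_Bmal1[keep],
                    truth$period[keep], method = "spearman")
  expect_lt(rho, -0.9)
  # seeded noisy panel analysed end to end
  pan <- generate_panel(panel_config(seed = 7))
  summ <- genotype_summaries(pan$table,
                             data.frame(genotype = pan$truth$genotype,
                                        period = pan$truth$period))
  mt <- monotonicity_test(summ)
  expect_lte(mt$rho, -0.7)
  expect_lt(mt$p_value, 0.05)
})

test_that("trace generation matches its closed form and is recoverable", {
  cfg <- trace_config(noise_sd = 0, drift = 0, curvature = 0, seed = 9)
  tr <- generate_trace(cfg)
  t <- tr$trace$time
  expected <- cfg$baseline + cfg$amplitude * exp(-cfg$damping * t) *
    sin(2 * pi * t / cfg$period)
  expect_equal(tr$trace$value, expected, tolerance = 1e-12)
  d <- detrend(t, tr$trace$value)
  f <- sine_fit_period(d$time, d$value)
  expect_lt(abs(f$period - cfg$period), 0.05)
  expect_error(trace_config(duration = 40, seed = 1), "three periods")
})

test_that("longer records tighten the period estimate", {
  err <- function(dur) {
    vapply(1:12, function(s) {
      tr <- generate_trace(trace_config(duration = dur, seed = s))
      d <- detrend(tr$trace$time, tr$trace$value)
      abs(sine_fit_period(d$time, d$value)$period - 24.5)
    }, numeric(1))
  }
  e1 <- err(120); e2 <- err(240)
  expect_lt(stats::sd(e2), stats::sd(e1))
})

test_that("model-derived panels bridge the simulator to the pipeline", {
  genos <- c("WT", "Fbxl3-KO", "Cry2-KO", "Per2-KO", "Cry1-KO", "hiPer2")
  pm <- panel_from_model(genos, cv = 0, seed = 3, t_end = 600, discard = 360)
  # noiseless values equal the trajectory samples (positive part)
  expect_true(all(pm$table$value >= 0))
  one <- pm$table[pm$table$genotype == "WT" & pm$table$gene == "Per1", ]
  v <- matrix(one$value, ncol = 3)
  expect_equal(v[, 1], v[, 2])
  # WT normalised to itself gives relative amplitude one
  summ <- genotype_summaries(pm$table,
                             data.frame(genotype = pm$truth$genotype,
                                        period = pm$truth$period))
  expect_equal(summ$rel_amp_Per1[summ$genotype == "WT"], 1)
  expect_equal(summ$rel_amp_Bmal1[summ$genotype == "WT"], 1)
  # periods carried through from the simulations
  expect_true(all(is.finite(summ$period[summ$genotype %in%
                                          pm$truth$genotype[pm$truth$is_rhythmic]])))
})

test_that("programmed effect sizes are recovered under replicate noise", {
  # reduced version of the parameter-recovery sweep (the acceptance test
  # runs the full 500 seeds)
  hits <- 0; tot <- 0
  for (s in 1:60) {
    pan <- generate_panel(panel_config(seed = s))
    summ <- genotype_summaries(pan$table,
                               data.frame(genotype = pan$truth$genotype,
                                          period = pan$truth$period))
    m <- match(summ$genotype, pan$truth$genotype)
    rel <- abs(c(summ$rel_amp_Per1 / pan$truth$rel_amp_Per1[m] - 1,
                 summ$rel_amp_Bmal1 / pan$truth$rel_amp_Bmal1[m] - 1))
    hits <- hits + sum(rel <= 0.25); tot <- tot + length(rel)
  }
  expect_gte(hits / tot, 0.9)
})
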