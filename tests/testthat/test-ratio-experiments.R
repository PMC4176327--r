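test_that("rotation angle is the arccotangent of the intensity ratio", {
  expect_equal(rotation_angle(1, 1), pi / 4)
  expect_equal(rotation_angle(4.2888, 1), atan(1 / 4.2888), tolerance = 1e-9)
  expect_equal(rotation_angle(4.2888, 1), 0.2291, tolerance = 1e-3)
  # vanishing auxiliary amplitude sends the angle to zero
  expect_lt(rotation_angle(1, 1e-9), 1e-8)
  expect_error(rotation_angle(0, 1), "positive")
  expect_error(rotation_angle(1, -0.1), "positive")
})

test_that("sweep records carry flags and the identity point reproduces the wild type", {
  rec <- sweep_surface(scales_P = c(0.6, 1), scales_A = c(0.5, 1), dt = 0.05)
  expect_equal(nrow(rec), 4)
  expect_true(all(c("scale_P", "scale_A", "amp_plbs", "amp_albs", "ratio",
                    "theta", "period", "is_rhythmic") %in% names(rec)))
  wtrow <- rec[rec$scale_P == 1 & rec$scale_A == 1, ]
  expect_true(wtrow$is_rhythmic)
  expect_equal(wtrow$period, 23.92, tolerance = 0.05)
  expect_equal(wtrow$ratio, 1.3764, tolerance = 0.02)
})

test_that("non-oscillatory sweep points are flagged, not dropped", {
  # very weak primary modulation cannot sustain the limit cycle
  rec <- sweep_surface(scales_P = c(0.2, 1), scales_A = 1, dt = 0.05)
  expect_equal(nrow(rec), 2)
  expect_false(rec$is_rhythmic[rec$scale_P == 0.2])
  expect_true(rec$is_rhythmic[rec$scale_P == 1])
})

test_that("ratio_period_curve reports monotonicity statistics", {
  # strictly decreasing synthetic pairs give rho exactly -1
  fake <- data.frame(scale_P = 1, scale_A = 1,
                     amp_plbs = seq(0.2, 1, length.out = 12),
                     amp_albs = seq(0.52, 0.48, length.out = 12),
                     period = seq(26, 22, length.out = 12),
                     is_rhythmic = TRUE)
  fake$ratio <- fake$amp_plbs / fake$amp_albs
  out <- ratio_period_curve(fake)
  expect_equal(out$rho_ratio, -1)
  expect_equal(out$curve$ratio, sort(fake$ratio))
  expect_error(ratio_period_curve(fake[1:5, ]), "fewer than")
})

test_that("transmission curves pass through the wild-type point", {
  tc <- transmission_curve(scales = c(0.9, 1, 1.1), dt = 0.05)
  wtrow <- tc$table[tc$table$scale == 1, ]
  expect_equal(wtrow$amp_plbs_rel, 1, tolerance = 1e-9)
  expect_equal(wtrow$amp_albs_rel, 1, tolerance = 1e-9)
})

test_that("the dual-perturbation grid is anchored at the wild type", {
  g <- dual_perturbation_grid(scales_primary = c(0.85, 1, 1.18),
                              scales_auxiliary = c(0.85, 1, 1.18), dt = 0.05)
  expect_equal(g$period_wt, 23.92, tolerance = 0.05)
  expect_true(all(is.finite(g$period)))
})

test_that("virtual genotypes edit parameters purely and validate names", {
  base <- comprehensive_params()
  panel <- genotype_panel()
  # Cry1 knockout zeroes only the Cry1 transcription terms
  ko <- virtual_genotype(base, panel[["Cry1-KO"]])
  expect_equal(ko$v_C1, 0)
  expect_equal(ko$v_C1r, 0)
  same <- setdiff(names(base), c("v_C1", "v_C1r"))
  expect_identical(ko[same], base[same])
  expect_equal(base$v_C1, 0.8)  # purity: input untouched
  # Rev-erba knockout pins the RORE at its derepressed maximum
  rko <- virtual_genotype(base, panel[["Rev-erba-KO"]])
  traj <- integrate_dde(rko, t_span = c(0, 300), dt = 0.05)
  late <- traj$time > 200
  expect_true(all(abs(traj$signals[late, "RORE"] - 1) < 1e-9))
  # unknown parameter is rejected
  bad <- genotype_spec("broken", list(list(param = "v_X", op = "set",
                                           value = 0)))
  expect_error(virtual_genotype(base, bad), "unknown parameter")
})

test_that("rescue routes normalise the wild type to (1, 1) with zero displacement", {
  rr <- rescue_route(c("WT"), t_end = 600, discard = 360)
  expect_equal(rr$rel_amp_Per1, 1, tolerance = 1e-9)
  expect_equal(rr$rel_amp_Bmal1, 1, tolerance = 1e-9)
  expect_equal(rr$dist_wt_ray, 0, tolerance = 1e-9)
})

test_that("known mutants move the period in the documented directions", {
  wt <- simulate_genotype("WT")
  fb <- simulate_genotype("Fbxl3-KO")
  cry1 <- simulate_genotype("Cry1-KO")
  expect_gt(fb$period, wt$period + 2)    # stabilised CRY: long period
  expect_lt(cry1$period, wt$period)      # Cry1 loss: short period
})
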