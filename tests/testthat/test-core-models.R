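test_that("binding-site activities follow the Hill repression identities", {
  p <- conceptual_params(v_P = 1, v_A = 0.4, K1 = 0.2, K2 = 0.3, h = 4)
  # no repressor: maximal activity
  expect_equal(plbs_activity(0, p), 1.0)
  expect_equal(albs_activity(0, p), 0.4)
  # half-saturation at the repression constant, for any Hill coefficient
  for (h in c(1, 2, 4, 7)) {
    ph <- conceptual_params(v_P = 1, v_A = 0.4, K1 = 0.2, K2 = 0.3, h = h)
    expect_equal(plbs_activity(0.2, ph), 0.5)
    expect_equal(albs_activity(0.3, ph), 0.2)
  }
  # direct evaluation of the Hill form: x = 2 K1, h = 4 -> 1/(1+16)
  p4 <- conceptual_params(v_P = 1, K1 = 0.2, h = 4)
  expect_equal(plbs_activity(0.4, p4), 1 / 17, tolerance = 1e-12)
  # strictly decreasing, bounded in (0, v_P]
  x <- seq(0, 5, by = 0.1)
  act <- plbs_activity(x, p)
  expect_true(all(diff(act) < 0))
  expect_true(all(act > 0 & act <= 1))
  # topology switch: disabled auxiliary loop nulls the ALBS for any input
  p0 <- conceptual_params(al_enabled = FALSE)
  expect_equal(albs_activity(c(0, 0.1, 10), p0), c(0, 0, 0))
  # negative repressor is a domain error
  expect_error(plbs_activity(-1, p), "non-negative")
})

test_that("conceptual right-hand side matches its definition", {
  p <- conceptual_params(v_P = 1, v_A = 0.4, c = 1, d1 = 0.3, d2 = 0.2)
  z <- c(R1 = 0, R2 = 0)
  d <- conceptual_rhs(z, z, z, p)
  expect_equal(unname(d["R1"]), 1.4)   # maximal drive at zero repressor
  expect_equal(unname(d["R2"]), 1.0)
  # degradation contribution is linear in the rate
  x <- c(R1 = 0.5, R2 = 0.8)
  d1 <- conceptual_rhs(x, x, x, p)
  p2 <- conceptual_params(v_P = 1, v_A = 0.4, c = 1, d1 = 0.6, d2 = 0.2)
  d2 <- conceptual_rhs(x, x, x, p2)
  expect_equal(unname(d1["R1"] - d2["R1"]), 0.3 * 0.5)
  # fixed point of the non-delayed system zeroes the rhs (root oracle)
  fp <- conceptual_fixed_point(p)
  expect_equal(max(abs(conceptual_rhs(fp, fp, fp, p))), 0, tolerance = 1e-9)
})

test_that("comprehensive wiring honours the cis-element architecture", {
  p <- comprehensive_params()
  hi <- c(Bmal1 = 5, Per1 = 0.1, Per2 = 0.1, Cry1 = 0.1, Cry2 = 0.1,
          Rev = 0.1)
  # derepressed RORE: zero delayed REV gives maximal Bmal1 drive
  z <- hi; z["Rev"] <- 0
  el <- cis_activities(z, z, z, p)
  expect_equal(unname(el["RORE"]), 1)
  d <- comprehensive_rhs(z, z, z, z, p)
  expect_equal(unname(d["Bmal1"]), p$v_B * 1 - p$d_B * z[["Bmal1"]])
  # addition-rule degenerate case: a_R = 0 reduces Cry1 to the
  # single-element (Per2-style) form up to the rate constants
  p0 <- comprehensive_params(a_R = 0, a_E = 1)
  d0 <- comprehensive_rhs(z, z, z, z, p0)
  expect_equal(unname(d0["Cry1"] + p0$d_C1 * z[["Cry1"]]),
               unname(p0$v_C1 / p0$v_P2 * (d0["Per2"] + p0$d_P2 * z[["Per2"]])))
  # knockout locality: zeroing Cry1 transcription leaves the other
  # equations unchanged at identical states
  pk <- comprehensive_params(v_C1 = 0, v_C1r = 0)
  dk <- comprehensive_rhs(z, z, z, z, pk)
  dfull <- comprehensive_rhs(z, z, z, z, p)
  expect_equal(dk[c("Bmal1", "Per1", "Per2", "Cry2", "Rev")],
               dfull[c("Bmal1", "Per1", "Per2", "Cry2", "Rev")])
  expect_equal(unname(dk["Cry1"]), -p$d_C1 * z[["Cry1"]])
})

test_that("parameter validation enforces the invariants", {
  expect_error(conceptual_params(h = 0.5), "'h'")
  expect_error(conceptual_params(v_P = -1), "'v_P'")
  expect_error(conceptual_params(tau_P = 0), "'tau_P'")
  expect_error(comprehensive_params(K_R = -2), "'K_R'")
  expect_error(comprehensive_params(h_E = 0), "'h_E'")
  # knockouts may zero maximal rates
  expect_s3_class(comprehensive_params(v_R = 0), "comprehensive_params")
})

test_that("trajectories from non-negative history stay non-negative and bounded", {
  # property over a fixed set of parameter draws
  set.seed(101)
  for (k in 1:5) {
    p <- conceptual_params(
      v_P = runif(1, 0.5, 1.5), v_A = runif(1, 0.1, 0.6),
      K1 = runif(1, 0.2, 0.8), K2 = runif(1, 2, 6),
      d1 = runif(1, 1, 2.5), d2 = runif(1, 0.1, 0.3))
    traj <- quick_conceptual(p, dt = 0.05)
    expect_true(all(traj$states >= 0))
    bound_R1 <- (p$v_P + p$v_A) / p$d1
    bound_R2 <- p$c * p$v_P / p$d2
    late <- traj$time > 100
    expect_true(all(traj$states[late, "R1"] <= bound_R1 * 1.001))
    expect_true(all(traj$states[late, "R2"] <= bound_R2 * 1.001))
  }
})

test_that("wild-type comprehensive rhythm has Per1 and Bmal1 in antiphase", {
  traj <- quick_comprehensive()
  s1 <- osc_stats(traj, "Per1", discard = 420)
  sB <- osc_stats(traj, "Bmal1", discard = 420)
  expect_true(s1$is_rhythmic && sB$is_rhythmic)
  off <- (sB$peak_phase - s1$peak_phase) %% s1$period
  off <- min(off, s1$period - off)
  expect_gt(off, 9)
  expect_lt(off, 15)
})

test_that("primary-only protein trough-to-peak approximates tau_P", {
  p <- conceptual_params(al_enabled = FALSE)
  traj <- quick_conceptual(p)
  ex <- extrema(traj, "R1")
  pk <- ex$time[ex$type == "peak"]; tr <- ex$time[ex$type == "trough"]
  t2p <- mean(vapply(tr[1:4], function(tt) min(pk[pk > tt] - tt), numeric(1)))
  expect_lt(abs(t2p - p$tau_P) / p$tau_P, 0.15)
})
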