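test_that("monoexponential fit recovers exact-exponential parameters", {
  t <- seq(0, 0.5, length.out = 200)
  tr <- volume_trace(t, 3e-15 + 2e-15 * exp(-t / 0.05))
  fit <- fit_monoexponential(tr)
  expect_lt(abs(fit$tau - 0.05) / 0.05, 1e-6)
  expect_equal(fit$y_inf, 3e-15, tolerance = 1e-6)
  expect_equal(fit$amp, 2e-15, tolerance = 1e-6)
})

test_that("tau of a small-gradient deflation matches the linearized closed form", {
  sp <- small_gradient_spec()
  tg <- seq(0, 0.5, length.out = 500)
  tr <- volume_trace(tg, deflate_analytic(sp, tg))
  fit <- fit_monoexponential(tr)
  tau_lin <- sp$r0 * sp$c_in0 / (3 * sp$P_f * sp$V_w_molar * sp$c_out^2)
  expect_equal(tau_lin, 0.059671, tolerance = 1e-4)
  expect_lt(abs(fit$tau - tau_lin) / tau_lin, 0.02)
})

test_that("degenerate traces are rejected", {
  expect_error(fit_monoexponential(volume_trace(seq(0, 1, 0.01),
                                                rep(1e-15, 101))),
               "constant signal")
  expect_error(fit_monoexponential(volume_trace(c(0, 1, 2), c(3, 2, 1))),
               "at least 4 points")
})

test_that("tau-to-P_f conversion variants reproduce hand arithmetic", {
  tau <- 0.059671   # linearized tau of the small-gradient scenario
  r0 <- 1e-5
  c_in0 <- mM_to_molcm3(290)
  c_out <- mM_to_molcm3(300)
  expect_equal(pf_from_tau(tau, r0, c_in0, c_out, "improved"),
               0.010172, tolerance = 1e-4)
  expect_equal(pf_from_tau(tau, r0, c_in0, c_out, "b"),
               0.310345, tolerance = 1e-4)
  expect_equal(pf_from_tau(tau, r0, c_in0, c_out, "c"),
               0.010000, tolerance = 1e-4)
  expect_equal(pf_from_tau(tau, r0, c_in0, c_out, "a"),
               0.010345, tolerance = 1e-4)
  expect_error(pf_from_tau(tau, r0, c_out, c_out, "b"), "zero")
})

test_that("nominal-gradient conversion (variant b) has the closed-form bias", {
  sp <- small_gradient_spec()
  tg <- seq(0, 0.5, length.out = 500)
  tau <- fit_monoexponential(volume_trace(tg, deflate_analytic(sp, tg)))$tau
  est_b <- pf_from_tau(tau, sp$r0, sp$c_in0, sp$c_out, "b")
  bias_expected <- sp$c_out^2 / (sp$c_in0 * (sp$c_out - sp$c_in0))  # 31.03
  expect_equal(est_b / sp$P_f, bias_expected, tolerance = 0.02)
})

test_that("the averaged-gradient conversion beats variants a and b", {
  # several small-gradient scenarios: |improved - truth| < |a|, |b| errors
  for (c_out_mM in c(295, 300, 310, 320)) {
    sp <- vesicle_spec(nm_to_cm(100), mM_to_molcm3(290),
                       mM_to_molcm3(c_out_mM), 0.01)
    tg <- seq(0, 10 * deflation_tau(sp), length.out = 400)
    tau <- fit_monoexponential(volume_trace(tg, deflate_analytic(sp, tg)))$tau
    err <- function(v) abs(pf_from_tau(tau, sp$r0, sp$c_in0, sp$c_out, v) - 0.01)
    expect_lt(err("improved"), err("a"))
    expect_lt(err("improved"), err("b"))
  }
})

test_that("analytic full-curve fit is exact on noiseless data", {
  sp <- challenge_spec()
  tg <- seq(0, 0.1, length.out = 300)
  tr <- volume_trace(tg, deflate_analytic(sp, tg))
  fit <- fit_deflation(tr, sp$r0, sp$c_in0, sp$c_out)
  expect_lt(abs(fit$P_f - sp$P_f) / sp$P_f, 1e-6)
})

test_that("grid strategy lands within one grid step of the analytic fit", {
  sp <- small_gradient_spec()
  tg <- seq(0, 0.5, length.out = 200)
  tr <- volume_trace(tg, deflate_analytic(sp, tg))
  grid <- exp(seq(log(0.001), log(0.1), length.out = 200))
  fa <- fit_deflation(tr, sp$r0, sp$c_in0, sp$c_out, strategy = "analytic")
  fg <- fit_deflation(tr, sp$r0, sp$c_in0, sp$c_out, strategy = "grid",
                      grid = grid)
  step <- diff(log(grid))[1]
  expect_lt(abs(log(fg$P_f) - log(fa$P_f)), 1.5 * step)
})

test_that("grid strategy demands a grid wide enough to bracket tau", {
  sp <- small_gradient_spec()
  tg <- seq(0, 0.5, length.out = 100)
  tr <- volume_trace(tg, deflate_analytic(sp, tg))
  expect_error(fit_deflation(tr, sp$r0, sp$c_in0, sp$c_out, strategy = "grid",
                             grid = c(1e-4, 2e-4, 3e-4)),
               "extend the P_f grid")
})

test_that("P_f estimates do not depend on the generating osmotic gradient", {
  # same membrane, different osmotic challenges -> same fitted P_f
  ests <- vapply(c(320, 400, 590), function(c_out_mM) {
    sp <- vesicle_spec(nm_to_cm(100), mM_to_molcm3(290),
                       mM_to_molcm3(c_out_mM), 0.01)
    tg <- seq(0, 8 * deflation_tau(sp), length.out = 300)
    tr <- volume_trace(tg, deflate_analytic(sp, tg))
    fit_deflation(tr, sp$r0, sp$c_in0, sp$c_out)$P_f
  }, numeric(1))
  expect_lt(max(abs(ests - 0.01) / 0.01), 1e-6)
})

test_that("noisy recovery: analytic fit finds P_f within 5% per seed", {
  sp <- challenge_spec()
  tg <- seq(0, 0.1, length.out = 500)
  errs <- vapply(1:30, function(s) {
    tr <- gen_deflation(sp, tg, noise = noise_spec(sigma = 0.01, seed = s))
    abs(fit_deflation(tr, sp$r0, sp$c_in0, sp$c_out)$P_f - sp$P_f) / sp$P_f
  }, numeric(1))
  expect_lt(max(errs), 0.05)
})

test_that("bootstrap CI is seeded, reproducible, and covers the estimate", {
  sp <- challenge_spec()
  tg <- seq(0, 0.1, length.out = 200)
  tr <- gen_deflation(sp, tg, noise = noise_spec(sigma = 0.01, seed = 4))
  expect_error(fit_deflation(tr, sp$r0, sp$c_in0, sp$c_out, n_boot = 10),
               "seed")
  f1 <- fit_deflation(tr, sp$r0, sp$c_in0, sp$c_out, n_boot = 50, seed = 9)
  f2 <- fit_deflation(tr, sp$r0, sp$c_in0, sp$c_out, n_boot = 50, seed = 9)
  expect_identical(f1$ci, f2$ci)
  expect_true(f1$ci[1] <= f1$P_f && f1$P_f <= f1$ci[2])
})
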