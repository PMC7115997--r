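test_that("forward scattering model is the stated quadratic", {
  expect_equal(intensity_from_volume(1, scatter_calibration(0, 1, 0)), 1)
  expect_equal(intensity_from_volume(1, scatter_calibration(0.1, 2, 0)), 2.1)
  expect_equal(intensity_from_volume(2, scatter_calibration(1, 0.5, 0.25)),
               1 + 1 + 1)
})

test_that("linear calibrations invert exactly", {
  calib <- scatter_calibration(0.1, 2, 0)
  V <- c(0.3, 0.7, 1.1)
  I <- intensity_from_volume(V, calib)
  expect_equal(volume_from_intensity(I, calib, c(0, 2)), V)
})

test_that("quadratic calibrations round-trip within bounds", {
  sp <- small_gradient_spec()
  calib <- scatter_calibration(a = 0.2, b = -2e14, d = 3e28)
  V <- seq(equilibrium_volume(sp), sp$V0, length.out = 20)
  I <- intensity_from_volume(V, calib)
  V_back <- volume_from_intensity(I, calib, c(equilibrium_volume(sp), sp$V0))
  expect_lt(max(abs(V_back - V) / V), 1e-12)
})

test_that("ambiguous inversion (both roots in bounds) is an error naming roots", {
  # parabola with vertex inside the bounds: two admissible roots
  calib <- scatter_calibration(a = 0, b = -2, d = 1)  # I = V^2 - 2V, vertex V=1
  expect_error(volume_from_intensity(-0.75, calib, c(0, 2)),
               "roots .* inside bounds")
  expect_error(volume_from_intensity(0, scatter_calibration(0, 0, 0), c(0, 1)),
               "degenerate")
})

test_that("trace_to_volume checks monotonicity and converts", {
  sp <- small_gradient_spec()
  tg <- seq(0, 0.3, length.out = 50)
  V <- deflate_analytic(sp, tg)
  calib <- scatter_calibration(1, -1e14, 0)
  itr <- intensity_trace(tg, intensity_from_volume(V, calib))
  vtr <- trace_to_volume(itr, calib, c(equilibrium_volume(sp), sp$V0))
  expect_s3_class(vtr, "volume_trace")
  expect_equal(vtr$y, V, tolerance = 1e-10)
  # non-monotone calibration over the range is refused
  bad <- scatter_calibration(0, -2 * 3e-15, 1)
  expect_error(trace_to_volume(itr, bad, c(0, 6e-15)), "monotone")
})

test_that("fit_calibration recovers quadratic coefficients from paired data", {
  V <- seq(0.5, 1, length.out = 10)
  I <- 0.3 + 1.2 * V - 0.4 * V^2
  cal <- fit_calibration(V, I)
  expect_equal(cal$a, 0.3, tolerance = 1e-8)
  expect_equal(cal$b, 1.2, tolerance = 1e-8)
  expect_equal(cal$d, -0.4, tolerance = 1e-8)
})

test_that("mixture with one population reduces to the plain pipeline", {
  sp <- small_gradient_spec()
  calib <- scatter_calibration(0, 1e14, 0)
  tg <- seq(0, 0.3, length.out = 100)
  mix <- mixture_spec(list(sp), 1)
  m <- mixture_trace(mix, calib, tg)
  plain <- intensity_from_volume(deflate_analytic(sp, tg), calib)
  expect_equal(m$y, plain)
  # 50:50 of identical specs is the same signal
  mix2 <- mixture_spec(list(sp, sp), c(0.5, 0.5))
  expect_equal(mixture_trace(mix2, calib, tg)$y, plain)
})

test_that("bare-vesicle + proteoliposome mixtures are not monoexponential", {
  bare <- vesicle_spec(nm_to_cm(100), mM_to_molcm3(290), mM_to_molcm3(590), 0.001)
  pl   <- vesicle_spec(nm_to_cm(100), mM_to_molcm3(290), mM_to_molcm3(590), 0.02)
  calib <- scatter_calibration(0, 1e14, 0)
  tg <- seq(0, 0.6, length.out = 400)
  mix <- mixture_trace(mixture_spec(list(bare, pl), c(0.5, 0.5)), calib, tg)
  mono <- fit_monoexponential(mix)
  # two-component oracle fitted directly in the test
  t <- tg; y <- mix$y / max(mix$y)
  two <- minpack.lm::nlsLM(
    y ~ y_inf + a1 * exp(-t / t1) + a2 * exp(-t / t2),
    start = list(y_inf = min(y), a1 = 0.3, t1 = 0.01, a2 = 0.3, t2 = 0.3),
    lower = c(-Inf, 0, 1e-6, 0, 1e-6))
  rss_two <- sum(resid(two)^2) * max(mix$y)^2
  expect_lt(rss_two, mono$rss * 0.5)
})

test_that("mixture weights are validated", {
  sp <- small_gradient_spec()
  expect_error(mixture_spec(list(sp, sp), c(0.6, 0.6)), "sum to 1")
  expect_error(mixture_spec(list(sp), 0), "sum to 1|in \\(0")
})
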