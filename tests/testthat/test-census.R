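test_that("electrical channel counting is G/g with guards", {
  expect_equal(channels_from_conductance(2e-9, 2e-12), 1000)
  expect_equal(channels_from_conductance(0, 2e-12), 0)
  expect_equal(channels_from_conductance(1.5e-10, 2e-12), 75)
  expect_error(channels_from_conductance(1e-9, 0), "g must be")
})

test_that("conductance-slope census converts slope to unitary permeability", {
  # exact synthetic line: P_f = slope * G, slope = 5e3 cm/s per S
  G <- c(1e-10, 5e-10, 1e-9, 2e-9)
  cs <- slope_census(G, 5e3 * G + 1e-4, kind = "conductance")
  fit <- pf_from_conductance_slope(cs, A = 1e-2, g = 2e-12)
  expect_equal(fit$p_f, 1e-10, tolerance = 1e-9)
  expect_equal(fit$lipid_background, 1e-4, tolerance = 1e-6)
  expect_true(fit$slope_significant)
})

test_that("a flat permeability-conductance relation is flagged", {
  cs <- slope_census(c(1e-10, 5e-10, 1e-9, 2e-9), rep(1e-4, 4),
                     kind = "conductance")
  expect_warning(fit <- pf_from_conductance_slope(cs, A = 1e-2, g = 2e-12),
                 "spans zero")
  expect_equal(fit$p_f, 0, tolerance = 1e-16)
  expect_false(fit$slope_significant)
})

test_that("noisy conductance census recovers p_f within its CI", {
  truth <- attr(cs <- gen_slope_census(
    p_f = 1e-13, densities = seq(2e7, 2e8, length.out = 8),
    lipid_Pf = 2e-4, kind = "conductance", A = 1e-2, g = 2e-12,
    noise = noise_spec(sigma = 0.01, seed = 31)), "truth")
  fit <- pf_from_conductance_slope(cs, A = truth$A, g = truth$g)
  expect_true(fit$p_f_ci[1] <= truth$p_f && truth$p_f <= fit$p_f_ci[2])
})

test_that("electrically silent channels inflate the naive estimate by 1/(1-s)", {
  s <- 0.9   # inactivated fraction still conducting water
  n <- seq(500, 5000, length.out = 6)
  cs <- gen_slope_census(p_f = 1e-13, densities = n, kind = "conductance",
                         A = 1e-2, g = 2e-12, silent_fraction = s)
  naive <- pf_from_conductance_slope(cs, A = 1e-2, g = 2e-12)
  expect_equal(naive$p_f, 1e-13 / (1 - s), tolerance = 1e-9)
  corrected <- pf_from_conductance_slope(cs, A = 1e-2, g = 2e-12,
                                         silent_fraction = s)
  expect_equal(corrected$p_f, 1e-13, tolerance = 1e-9)
})

test_that("FCS two-step counting converts count ratios to channels", {
  # 8 micelles per vesicle, every protomer labeled, tetramer
  cv <- channels_per_vesicle(fcs_census(100, 800, protomers_per_oligomer = 4))
  expect_equal(cv$oligomers_per_vesicle, 2)
  # imperfect labeling: 8/0.8 = 10 protomers -> 2.5 tetramers
  cv2 <- channels_per_vesicle(fcs_census(100, 800, 4, labeling_efficiency = 0.8))
  expect_equal(cv2$protomers_per_vesicle, 10)
  expect_equal(cv2$oligomers_per_vesicle, 2.5)
  # bare vesicles dilute the per-proteoliposome count
  cv3 <- channels_per_vesicle(fcs_census(100, 800, 4, bare_fraction = 0.5))
  expect_equal(cv3$oligomers_per_proteoliposome, 4)
  # no reconstitution
  cv0 <- channels_per_vesicle(fcs_census(100, 0, 4))
  expect_false(cv0$reconstituted)
  expect_equal(cv0$oligomers_per_vesicle, 0)
})

test_that("low labeling efficiency triggers the reliability warning", {
  expect_warning(channels_per_vesicle(fcs_census(100, 400, 4,
                                                 labeling_efficiency = 0.5)),
                 "labeling efficiency")
  expect_error(fcs_census(100, 400, 4, labeling_efficiency = 0), "efficiency")
  expect_error(fcs_census(0, 400, 4), "vesicle_count")
})

test_that("density-slope census: slope is p_f, intercept the lipid background", {
  dens <- seq(1e3, 1e4, length.out = 5)
  cs <- slope_census(dens, 1e-13 * dens + 3e-4, kind = "density")
  fit <- pf_from_density_slope(cs)
  expect_equal(fit$p_f, 1e-13, tolerance = 1e-10)
  expect_equal(fit$lipid_background, 3e-4, tolerance = 1e-8)
})

test_that("end-to-end census pipeline recovers p_f within 5% at 1% noise", {
  # proteoliposome series at increasing protein:lipid ratio
  r0 <- nm_to_cm(100)
  oligomer_counts <- c(2, 5, 10, 20, 40)
  censuses <- lapply(oligomer_counts, function(n) {
    fcs_census(1000, 1000 * n * 4 * 0.9, protomers_per_oligomer = 4,
               labeling_efficiency = 0.9)
  })
  olig <- vapply(censuses, function(cs) {
    channels_per_vesicle(cs)$oligomers_per_vesicle
  }, numeric(1))
  expect_equal(olig, oligomer_counts)
  dens <- channel_density(olig, r0)
  cs <- gen_slope_census(p_f = 2e-13, densities = dens, lipid_Pf = 2e-4,
                         kind = "density",
                         noise = noise_spec(sigma = 0.01, seed = 17))
  fit <- pf_from_density_slope(cs)
  expect_lt(abs(fit$p_f - 2e-13) / 2e-13, 0.05)
  # the intercept is noisier than the slope; check it through its CI
  expect_true(fit$intercept_ci[1] <= 2e-4 && 2e-4 <= fit$intercept_ci[2])
})
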