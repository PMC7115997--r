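test_that("osmotic work is v_w * N * delta_Pi with sane domain checks", {
  expect_equal(osmotic_work(0, 1e6), 0)
  # 8 waters against a 100 mM ideal gradient at 298 K
  dPi <- osmotic_pressure(mM_to_molcm3(100), 298)
  expect_equal(dPi, 2.477709e6, tolerance = 1e-5)
  expect_equal(osmotic_work(8, dPi), 5.9465e-16, tolerance = 1e-4)
  # linear in the gradient
  expect_equal(osmotic_work(1, 2 * dPi), 2 * osmotic_work(1, dPi))
  expect_error(osmotic_work(-1, dPi), "N must be")
  expect_error(osmotic_work(1, dPi, v_w = 0), "v_w")
})

test_that("channel_geometry derives and validates N, L, z", {
  g <- channel_geometry(N = 8)
  expect_equal(g$L, 8 * 2.8e-8)
  expect_match(g$defaults_used, "water diameter")
  g2 <- channel_geometry(L = 2.24e-7, z = 2.8e-8)
  expect_equal(g2$N, 8)
  expect_error(channel_geometry(N = 8, L = 1e-7, z = 2.8e-8), "inconsistent")
  expect_error(channel_geometry(N = 0.5), "N must be >= 1")
  expect_error(channel_geometry(N = 5, N_H = -1), "N_H")
})

test_that("pore-geometry permeability matches hand arithmetic and scaling laws", {
  expect_equal(pf_finkelstein(D_1 = 1e-5, z = 2.8e-8, L = 2.24e-7),
               4.78316e-14, tolerance = 1e-5)
  # halving L doubles p_f
  expect_equal(pf_finkelstein(D_1 = 1e-5, z = 2.8e-8, L = 1.12e-7),
               2 * pf_finkelstein(D_1 = 1e-5, z = 2.8e-8, L = 2.24e-7))
  expect_error(pf_finkelstein(D_1 = 1e-5, z = 2.8e-8, L = 0), "L")
})

test_that("mobility-based permeability reproduces the bulk and slow extremes", {
  # bulk-like mobility (fastest single-file channel)
  expect_equal(pf_from_mobility(5e-5), 1.91326e-12, tolerance = 1e-5)
  # four orders below bulk (slowest)
  expect_equal(pf_from_mobility(4e-9), 1.53061e-16, tolerance = 1e-5)
  expect_equal(pf_from_mobility(0), 0)
  expect_error(pf_from_mobility(5e-5, z = 0), "z")
  # inverse pair
  expect_equal(mobility_from_pf(pf_from_mobility(3.7e-6)), 3.7e-6)
})

test_that("geometry and mobility formulations agree under D_w = D_1/N, L = N z", {
  for (i in 1:50) {
    N <- sample(4:8, 1)
    z <- runif(1, 2.5e-8, 3.1e-8)
    D_1 <- 10^runif(1, -9, -4)
    a <- pf_finkelstein(D_1 = D_1, z = z, L = N * z)
    b <- pf_from_mobility(D_w = D_1 / N, z = z)
    expect_lt(abs(a - b) / a, 1e-12)
  }
})

test_that("the derivation chain is self-consistent and balances forces", {
  g <- channel_geometry(N = 7)
  dPi <- osmotic_pressure(mM_to_molcm3(200), 298)
  # zero gradient: no flow
  d0 <- finkelstein_chain(g, 0, D_1 = 1e-5)
  expect_equal(d0$v, 0)
  expect_equal(d0$Phi, 0)
  expect_equal(d0$W, 0)
  # doubling L at fixed gradient halves the column velocity
  gL <- channel_geometry(N = 14, z = g$z)
  expect_equal(finkelstein_chain(gL, dPi, D_1 = 1e-5)$v,
               finkelstein_chain(g, dPi, D_1 = 1e-5)$v / 2)
  # flux per osmolyte-density difference equals the closed-form p_f
  set.seed(42)
  for (i in 1:100) {
    N <- sample(4:9, 1)
    z <- runif(1, 2.5e-8, 3.1e-8)
    D_1 <- 10^runif(1, -9, -4)
    dPi_i <- osmotic_pressure(mM_to_molcm3(runif(1, 10, 500)), 298)
    gg <- channel_geometry(N = N, z = z)
    d <- finkelstein_chain(gg, dPi_i, D_1 = D_1)
    expect_equal(d$Phi / d$delta_n_s,
                 pf_finkelstein(D_1 = D_1, z = z, L = gg$L),
                 tolerance = 1e-12)
    # steady state: osmotic force balances friction
    expect_equal(d$F_Pi, d$F_gamma, tolerance = 1e-12)
  }
  expect_error(finkelstein_chain(list(N = 7), dPi, D_1 = 1e-5), "channel_geometry")
})

test_that("hard-sphere p_f is monotone in L and D_1", {
  Ls <- seq(1e-7, 5e-7, length.out = 10)
  pf_L <- vapply(Ls, function(L) pf_finkelstein(D_1 = 1e-5, z = 2.8e-8, L = L),
                 numeric(1))
  expect_true(all(diff(pf_L) < 0))
  Ds <- seq(1e-7, 1e-5, length.out = 10)
  pf_D <- vapply(Ds, function(D) pf_finkelstein(D_1 = D, z = 2.8e-8, L = 2e-7),
                 numeric(1))
  expect_true(all(diff(pf_D) > 0))
})

test_that("the p_f/p_d = N prediction is returned as-is (and is unconfirmed)", {
  expect_equal(pf_pd_ratio_prediction(7), 7)   # measured ratio is ~5 here
  expect_equal(pf_pd_ratio_prediction(1), 1)
  expect_equal(pf_pd_ratio_prediction(8), 8)   # measured ratio is ~13 here
  expect_error(pf_pd_ratio_prediction(0.5), "N must be >= 1")
})
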