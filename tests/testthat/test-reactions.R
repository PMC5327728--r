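p_mock <- mock_params()

test_that("Wnt switch is the stated sigmoid with exact complement", {
  expect_equal(wnt_switch(5, p_mock)$chi_W, 0.5)
  expect_equal(wnt_switch(6, p_mock)$chi_W, 0.5 * (1 + tanh(1)))
  expect_equal(wnt_switch(6, p_mock)$chi_W, 0.8808, tolerance = 1e-4)
  expect_equal(wnt_switch(1e6, p_mock)$chi_W, 1)
  expect_equal(wnt_switch(1e6, p_mock)$chi_W_star, 0)
  # complement identity and monotonicity on a grid
  W <- seq(0, 20, by = 0.1)
  sw <- wnt_switch(W, p_mock)
  expect_equal(sw$chi_W + sw$chi_W_star, rep(1, length(W)))
  expect_true(all(diff(sw$chi_W) >= 0))
  expect_error(wnt_switch(-1, p_mock), "nonnegative")
})

test_that("nutrient gates sit at their thresholds and are step-like", {
  ng <- nutrient_gates(0.07, p_mock)
  expect_equal(ng$chi_N, 0.5)
  expect_equal(nutrient_gates(0.1, p_mock)$chi_N_star, 0.5)
  hi <- nutrient_gates(1, p_mock)
  expect_equal(hi$chi_N, 1, tolerance = 1e-6)
  expect_equal(hi$chi_N_star, 1, tolerance = 1e-6)
  # at steepness 100, within 1e-6 of a step 0.15 away from the threshold
  expect_lt(nutrient_gates(0, p_mock)$chi_N, 1e-6)
  expect_gt(nutrient_gates(0.07 + 0.15, p_mock)$chi_N, 1 - 1e-6)
  expect_lt(nutrient_gates(0, p_mock)$chi_N_star, 1e-6)
  N <- seq(0, 1, by = 0.005)
  g <- nutrient_gates(N, p_mock)
  expect_true(all(diff(g$chi_N) >= 0) && all(diff(g$chi_N_star) >= 0))
  expect_error(nutrient_gates(-0.1, p_mock), "nonnegative")
})

test_that("nutrient source is affine with the printed endpoint identities", {
  V <- 144
  expect_equal(nutrient_source(0, p_mock), 2 * 0.025)      # N_s * alpha_N
  expect_equal(nutrient_source(V, p_mock), 2)              # amplitude
  # affinity: midpoint identity for arbitrary admissible arguments
  for (x in c(10, 60, 131)) {
    expect_equal(nutrient_source(x / 2, p_mock),
                 (nutrient_source(0, p_mock) + nutrient_source(x, p_mock)) / 2)
  }
  expect_error(nutrient_source(-1, p_mock), "integral_Pg")
  expect_error(nutrient_source(145, p_mock), "integral_Pg")
  # boundary value is the source rescaled into [alpha_N, 1]
  expect_equal(nutrient_boundary(0, p_mock), 0.025)
  expect_equal(nutrient_boundary(V, p_mock), 1)
  # glycolytic-share closure agrees at full occupancy
  expect_equal(nutrient_source(V, p_mock, integral_live = V),
               nutrient_source(V, p_mock))
})

test_that("reaction terms vanish on the empty domain without Wnt input", {
  p0 <- model_params(S_W = 0)
  st <- list(P_o = 0, P_g = 0, P_d = 0, W = 0, W_I = 0, N = 0)
  r <- reaction_rhs(st, 0, p0, integral_live = 0)
  # all derivatives zero except the constitutive source-free nutrient term
  expect_equal(r$dP_o, 0); expect_equal(r$dP_g, 0); expect_equal(r$dP_d, 0)
  expect_equal(r$dW, 0); expect_equal(r$dW_I, 0)
  expect_equal(r$dN, nutrient_source(0, p0, integral_live = 0))
})

test_that("switching fluxes cancel between the two live populations", {
  # with proliferation, dead-cell decay and death disabled, the
  # P_o <-> P_g exchange must conserve live mass pointwise
  p <- unclass(p_mock)
  p$tau_o <- p$tau_g <- 1e300          # no proliferation
  p$mu_o <- p$mu_g <- 1e-300           # no death
  p$mu_d <- 1e-300
  class(p) <- "model_params"
  for (s in 1:100) {
    st <- random_state(s)
    r <- reaction_rhs(st, st$P_g * 144, p, integral_live = (st$P_o + st$P_g) * 144)
    expect_equal(r$dP_o + r$dP_g + r$dP_d, 0, tolerance = 1e-14)
  }
})

test_that("death transfers mass exactly into the dead pool", {
  p <- unclass(p_mock)
  p$tau_o <- p$tau_g <- 1e300
  p$mu_d <- 1e-300
  class(p) <- "model_params"
  for (s in 1:20) {
    st <- random_state(s)
    st$N <- runif(1, 0, 0.1)   # straddle the death threshold
    r <- reaction_rhs(st, st$P_g * 144, p, integral_live = (st$P_o + st$P_g) * 144)
    expect_equal(r$dP_o + r$dP_g + r$dP_d, 0, tolerance = 1e-13)
  }
})

test_that("cell mass is conserved under explicit-Euler reaction integration", {
  # proliferation and dead-cell decay off; switching and death on
  p <- unclass(p_mock)
  p$tau_o <- p$tau_g <- 1e300
  p$mu_d <- 1e-300
  class(p) <- "model_params"
  st <- list(P_o = 0.3, P_g = 0.4, P_d = 0.05, W = 4, W_I = 2, N = 0.5)
  total0 <- st$P_o + st$P_g + st$P_d
  dt <- 1e-3
  for (i in 1:1000) {
    r <- reaction_rhs(st, st$P_g * 144, p, integral_live = (st$P_o + st$P_g) * 144)
    st$P_o <- st$P_o + dt * r$dP_o
    st$P_g <- st$P_g + dt * r$dP_g
    st$P_d <- st$P_d + dt * r$dP_d
    st$W <- max(st$W + dt * r$dW, 0)
    st$W_I <- max(st$W_I + dt * r$dW_I, 0)
    st$N <- max(st$N + dt * r$dN, 0)
  }
  expect_lt(abs(st$P_o + st$P_g + st$P_d - total0), 1e-8)
})

test_that("invalid states are rejected naming the offending field", {
  st <- list(P_o = 0.1, P_g = 0.1, P_d = 0, W = 1, W_I = 1, N = 0.5)
  bad <- st; bad$W_I <- -0.2
  expect_error(reaction_rhs(bad, 10, p_mock), "W_I")
  nan <- st; nan$N <- NaN
  expect_error(reaction_rhs(nan, 10, p_mock), "'N'")
})
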