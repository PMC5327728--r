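test_that("the empty state is a root when constitutive Wnt production stops", {
  p <- model_params(S_W = 0)
  hs <- homogeneous_steady_state(p, n_multistart = 8)
  expect_false(is.null(hs$roots))
  zero_root <- apply(hs$roots[, 1:5], 1, function(r) all(abs(r) < 1e-8))
  expect_true(any(zero_root))
})

test_that("the mock parameters admit a strictly positive steady state", {
  hs <- fixture("mock_hss", homogeneous_steady_state(mock_params()))
  expect_false(is.null(hs$best))
  expect_true(all(unlist(hs$best[c("P_o", "P_g", "W", "W_I", "N")]) > 0))
  # residual check straight from the definition
  V <- 144
  r <- reaction_rhs(hs$best, hs$best$P_g * V, mock_params(),
                    integral_live = (hs$best$P_o + hs$best$P_g) * V)
  expect_lt(max(abs(unlist(r))), 1e-10)
})

test_that("k = 0 growth equals the reaction-only spectrum and decays at large k", {
  p <- mock_params()
  hs <- fixture("mock_hss", homogeneous_steady_state(p))
  disp <- dispersion(p, hs$best)
  J0 <- reaction_jacobian(hs$best, p, include_global = TRUE)
  expect_equal(disp$growth0, max(Re(eigen(J0)$values)), tolerance = 1e-10)
  # diffusive damping dominates at short wavelengths: the least-damped
  # direction decays at least like the smallest diffusivity
  n <- length(disp$k)
  Dmin <- min(p$D_o, p$D_g, p$D_d, p$D_W, p$D_WI, p$D_N)
  expect_lt(disp$growth[n], -disp$k[n]^2 * Dmin * 0.5)
  expect_true(all(diff(disp$growth[disp$k > 20]) < 0))
})

test_that("equal diffusivities cannot destabilise a reaction-stable state", {
  # a classical result: with D identical for every species the spectrum
  # is shifted by -k^2 D, so no k > 0 can grow if k = 0 does not
  p <- unclass(mock_params())
  for (f in c("D_o", "D_g", "D_d", "D_W", "D_N")) p[[f]] <- 1
  p$D_WI <- 1 + 1e-9          # keep the inhibitor-range invariant
  class(p) <- "model_params"
  st <- list(P_o = 0.2, P_g = 0.4, P_d = 0.05, W = 3, W_I = 4, N = 0.5)
  J <- reaction_jacobian(st, p, include_global = FALSE)
  growth0 <- max(Re(eigen(J)$values))
  disp <- dispersion(p, st)
  if (growth0 <= 0) {
    expect_true(is.null(disp$unstable_band))
  } else {
    # if the reaction part is unstable the flag must say non-Turing
    expect_true(disp$non_turing_instability)
  }
  # either way, growth at every k is below the k = 0 reaction growth
  expect_true(all(disp$growth <= growth0 + 1e-12))
})

test_that("the baseline glycolytic state is stable; stronger autocatalysis crosses the Turing onset", {
  p <- mock_params()
  hs <- fixture("mock_hss", homogeneous_steady_state(p))
  disp <- fixture("mock_disp", dispersion(p, hs$best))
  # at the published parameters the spotted pattern is a large-amplitude
  # (subcritical) spike state: the uniform glycolytic state itself is
  # linearly stable at every wavenumber
  expect_lte(disp$growth0, 0)
  expect_true(is.null(disp$unstable_band))
  # raising the nonlinear Wnt production rate crosses the onset and
  # selects a finite wavelength close to the observed spot spacing scale
  p2 <- mock_params(); p2$kappa_W <- 20
  hs2 <- homogeneous_steady_state(p2)
  d2 <- fixture("kw20_disp", dispersion(p2, hs2$best))
  expect_true(d2$turing)
  expect_gt(d2$k_max, 0)
  expect_true(is.finite(d2$wavelength_um))
  expect_gt(d2$wavelength_um, 10)
  expect_lt(d2$wavelength_um, 160)
  # dispersion curve is continuous over the long-wavelength range (at
  # large k the log-spaced grid makes -k^2 D steps large by itself)
  expect_lt(max(abs(diff(disp$growth[disp$k < 10]))), 1)
})
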