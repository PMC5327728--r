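test_that("Bliss combination index follows its closed form and conventions", {
  # no single-agent effect, combination works: CI = 0 by convention
  b0 <- bliss_ci(0, 0, 0.8)
  expect_equal(b0$CI, 0)
  expect_true(b0$synergy)
  # exact independence: CI = 1
  e <- 0.3 + 0.4 - 0.3 * 0.4
  b1 <- bliss_ci(0.3, 0.4, e)
  expect_equal(b1$CI, 1)
  expect_false(b1$synergy)
  # direct evaluation
  b2 <- bliss_ci(0.2, 0.3, 0.9)
  expect_equal(b2$CI, (0.2 + 0.3 - 0.06) / 0.9)
  expect_equal(b2$CI, 0.4889, tolerance = 1e-4)
  expect_true(b2$synergy)
  # E_AB = 0 with nonzero single effects: undefined
  b3 <- bliss_ci(0.5, 0, 0)
  expect_false(b3$defined)
  expect_true(is.na(b3$CI))
  # E_AB = 0 with no effects at all: CI = 0
  expect_equal(bliss_ci(0, 0, 0)$CI, 0)
  expect_error(bliss_ci(-0.1, 0, 0.5), "effects")
  expect_error(bliss_ci(0.2, 1.4, 0.5), "effects")
})

test_that("combo_params reproduces the dnLEF column at the matching dose", {
  p <- mock_params()
  # identity at no treatment
  expect_identical(unclass(combo_params(p, 1, NULL)), unclass(p))
  # the calibration point: xav_factor = 6.5/7.5 with diffusion scaling
  q <- combo_params(p, 6.5 / 7.5, dca_rate = NULL, diffusion_scaling = TRUE)
  expect_equal(q$S_W, 6.5)
  expect_equal(q$D_W, 0.008)
  expect_equal(q$D_WI, 1.5)
  # affine in (1 - xav_factor): midpoint of the calibration segment
  h <- combo_params(p, (1 + 6.5 / 7.5) / 2)
  expect_equal(h$D_W, (0.004 + 0.008) / 2)
  expect_equal(h$D_WI, (1 + 1.5) / 2)
  # without scaling the diffusivities stay at baseline
  q2 <- combo_params(p, 0.8, diffusion_scaling = FALSE)
  expect_equal(q2$D_W, p$D_W)
  expect_equal(q2$D_WI, p$D_WI)
  expect_equal(q2$S_W, 0.8 * 7.5)
  # DCA raises the switch rate
  q3 <- combo_params(p, 1, dca_rate = 12)
  expect_equal(1 / q3$tau_go, 12)
  expect_error(combo_params(p, 0), "xav_factor")
  expect_error(combo_params(p, 1.2), "xav_factor")
  expect_error(combo_params(p, 1, dca_rate = 0.5), "below the untreated")
})

test_that("therapy plans validate and route doses to the right population", {
  pl <- therapy_plan("P_g", dose = 0.5, duration = 2.5, recovery = 10)
  expect_equal(pl$mu_Pg, 0.5)
  expect_equal(pl$mu_Po, 0)
  pl2 <- therapy_plan("both", dose = 0.3)
  expect_equal(c(pl2$mu_Po, pl2$mu_Pg), c(0.3, 0.3))
  expect_error(therapy_plan("P_g", dose = -1))
  expect_error(therapy_plan("P_g", xav_factor = 0))
})

test_that("a no-op plan leaves a steady tumour unchanged", {
  st <- patterned_state()
  out <- apply_therapy(st, mock_params(),
                       therapy_plan("none", duration = 2, recovery = 2),
                       dt = 2e-3)
  expect_equal(out$relative_size, 1, tolerance = 1e-3)
  expect_false(out$eradicated)
  expect_equal(out$series$rel_total[1], 1)
  # relative size stays within the logistic cap
  expect_true(all(out$series$rel_total <= 1.05))
})

test_that("sub-eradicating killing is followed by recovery", {
  st <- patterned_state()
  out <- apply_therapy(st, mock_params(),
                       therapy_plan("P_o", dose = 0.25, duration = 2.5,
                                    recovery = 25),
                       dt = 2e-3)
  # transient suppression...
  expect_lt(min(out$series$rel_total), 0.99)
  # ...then recovery to at least 95% of baseline
  expect_gte(out$relative_size, 0.95)
})
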