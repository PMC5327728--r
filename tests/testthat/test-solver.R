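test_that("the seeded initial condition honours its contract", {
  g <- sim_grid(48)
  p <- mock_params()
  s1 <- initial_state(g, p, seed = 7)
  s2 <- initial_state(g, p, seed = 7)
  expect_identical(s1[field_names()], s2[field_names()])
  s3 <- initial_state(g, p, seed = 8)
  expect_false(identical(s1$P_g, s3$P_g))
  # interior exactly empty, boundary shell seeded
  d <- wntpattern:::grid_boundary_distance(g)
  expect_true(all(s1$P_g[d >= 1.2] == 0))
  expect_true(any(s1$P_g[d < 1.2] > 0))
  expect_true(all(s1$P_g >= 0 & s1$P_g <= 0.5))
  expect_true(all(s1$W <= 0.1) && all(s1$W_I <= 0.1))
  # no oxidative or dead cells initially; nutrient uniformly high
  expect_true(all(s1$P_o == 0) && all(s1$P_d == 0))
  expect_true(all(s1$N == 1))
})

test_that("implicit diffusion conserves mass exactly under no-flux walls", {
  g <- sim_grid(32)
  p <- zero_rate_params(D = 0.5)
  set.seed(3)
  st <- initial_state(g, mock_params(), seed = 3)
  st$P_o <- matrix(runif(prod(g$n)), g$n[1], g$n[2])
  st$W <- matrix(runif(prod(g$n)), g$n[1], g$n[2])
  m0_po <- sum(st$P_o); m0_w <- sum(st$W)
  cur <- st
  for (i in 1:50) cur <- step_state(cur, p, dt = 0.01, Nb_override = 0)
  expect_equal(sum(cur$P_o), m0_po, tolerance = 1e-10)
  expect_equal(sum(cur$W), m0_w, tolerance = 1e-10)
  # and the field genuinely diffused
  expect_lt(max(cur$P_o) - min(cur$P_o), max(st$P_o) - min(st$P_o))
})

test_that("a uniform state is a fixed point of the transport step", {
  g <- sim_grid(24)
  p <- zero_rate_params()
  st <- make_field_fixture("uniform", g, value = 0.37)
  st$N <- st$N * 0 + 0.37
  out <- step_state(st, p, dt = 1e-3, Nb_override = 0.37)
  for (f in field_names())
    expect_equal(out[[f]], st[[f]], tolerance = 1e-14)
})

test_that("semi-implicit steps agree with a fine explicit reference", {
  g <- sim_grid(8)
  p <- mock_params()
  # smooth, well-conditioned state (the Wnt term is stiff where W_I is
  # near zero, which would test trajectory sensitivity, not correctness)
  st <- smooth_reference_state(g)
  semi <- st
  for (i in 1:50) semi <- step_state(semi, p, dt = 1e-4)
  ref <- explicit_reference(st, p, dt = 1e-6, nsteps = 5000)
  for (f in field_names()) {
    sc <- max(abs(ref[[f]]), 1)
    expect_lt(max(abs(semi[[f]] - ref[[f]])) / sc, 1e-4)
  }
})

test_that("the nutrient Dirichlet frame is enforced after every step", {
  g <- sim_grid(24)
  p <- mock_params()
  st <- initial_state(g, p, seed = 1)
  out <- step_state(st, p, dt = 1e-3, Nb_override = 0.3)
  expect_equal(unique(c(out$N[c(1, 24), ], out$N[, c(1, 24)])), 0.3)
})

test_that("divergence aborts with the offending field named", {
  g <- sim_grid(16)
  p <- mock_params()
  st <- initial_state(g, p, seed = 1)
  st$W <- st$W + 1e5   # primed for explosion under quadratic autocatalysis
  expect_error(
    simulate_model(p, grid = g, t_end = 1, dt = 0.05, state = st,
                   conv_tol = 0),
    "diverged")
})

test_that("time steps above the reaction stability bound trigger a warning", {
  g <- sim_grid(16)
  p <- mock_params()
  st <- initial_state(g, p, seed = 1)
  expect_warning(step_state(st, p, dt = 0.5), "stability")
})

test_that("simulation diagnostics are monotone in time and converge flags", {
  res <- fixture("small_sim", {
    simulate_model(mock_params(), grid = sim_grid(32), t_end = 5, dt = 2e-3,
                   seed = 1, conv_tol = 0)
  })
  d <- res$diagnostics
  expect_true(all(diff(d$time) > 0))
  expect_true(all(is.finite(unlist(d))))
  expect_identical(res$converged, FALSE)
  expect_s3_class(res, "sim_result")
})

test_that("snapshots are recorded at the requested cadence", {
  res <- simulate_model(mock_params(), grid = sim_grid(24), t_end = 2,
                        dt = 2e-3, seed = 1, snapshot_every = 0.5,
                        conv_tol = 0)
  expect_length(res$snapshots, 4)
  expect_equal(res$snapshots[[4]]$time, 2, tolerance = 1e-9)
})

test_that("central_slice extracts the documented mid-plane", {
  g3 <- sim_grid(10, ndim = 3)
  p <- mock_params()
  st <- initial_state(g3, p, seed = 1)
  sl <- central_slice(st)
  expect_equal(sl$grid$ndim, 2)
  expect_equal(dim(sl$P_g), c(10, 10))
  k <- floor(10 / 2) + 1     # fixed convention
  expect_identical(sl$P_g, st$P_g[, , k])
  # a field constant along z slices to any plane
  st$W <- array(rep(st$W[, , 1], 10), dim = c(10, 10, 10))
  expect_equal(central_slice(st)$W, st$W[, , 1])
  # 2D input: identity with a warning
  g2 <- sim_grid(8)
  st2 <- initial_state(g2, p, seed = 1)
  expect_warning(out <- central_slice(st2), "already 2D")
  expect_identical(out[field_names()], st2[field_names()])
})

test_that("2D and 3D stepping agree on z-uniform states", {
  p <- zero_rate_params(D = 0.2)
  g2 <- sim_grid(12)
  g3 <- sim_grid(12, ndim = 3)
  st2 <- initial_state(g2, mock_params(), seed = 5)
  st3 <- initial_state(g3, mock_params(), seed = 5)
  for (f in field_names())
    st3[[f]] <- array(rep(st2[[f]], 12), dim = c(12, 12, 12))
  out2 <- step_state(st2, p, dt = 0.01, Nb_override = 0.5)
  out3 <- step_state(st3, p, dt = 0.01, Nb_override = 0.5)
  sl <- central_slice(out3)
  for (f in c("P_o", "P_g", "W")) {
    expect_equal(sl[[f]], out2[[f]], tolerance = 1e-12)
  }
})
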