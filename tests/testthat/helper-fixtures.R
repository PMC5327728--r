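# Shared fixtures, memoised so expensive simulations run once per session.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# A parameter list with every reaction switched off (bypasses the
# constructor on purpose: zero rates are not physical, but they isolate
# the transport terms).
zero_rate_params <- function(D = 0.01) {
  p <- unclass(mock_params())
  for (k in c("S_W", "mu_Po", "mu_Pg")) p[[k]] <- 0
  for (k in c("kappa_W", "kappa_WI")) p[[k]] <- 0
  for (k in c("mu_o", "mu_g", "mu_d", "mu_W", "mu_WI", "mu_N")) p[[k]] <- 1e-300
  for (k in c("nu_NG", "nu_NO")) p[[k]] <- 1e-300
  p$tau_o <- p$tau_g <- 1e300
  p$tau_og <- p$tau_go <- 1e300
  p$N_s <- 1e-300
  for (k in c("D_o", "D_g", "D_d")) p[[k]] <- D
  p$D_W <- D; p$D_WI <- 2 * D; p$D_N <- D
  class(p) <- "model_params"
  p
}

random_state <- function(seed = 1) {
  set.seed(seed)
  list(P_o = runif(1, 0, 0.6), P_g = runif(1, 0, 0.6),
       P_d = runif(1, 0, 0.3), W = runif(1, 0, 8),
       W_I = runif(1, 0, 10), N = runif(1, 0.02, 1.2))
}

# Small patterned state shared by the therapy tests (coarse but spotted).
patterned_state <- function() {
  fixture("patterned64", {
    simulate_model(mock_params(), grid = sim_grid(64), t_end = 60,
                   dt = 2e-3, seed = 1, conv_tol = 1e-5)$state
  })
}

# Smooth, strictly interior state used by the fine-step oracle checks:
# all gates away from their thresholds, W_I bounded away from zero.
smooth_reference_state <- function(grid) {
  n <- grid$n
  x <- grid$coords[[1]] / grid$lengths[1]
  y <- grid$coords[[2]] / grid$lengths[2]
  bump <- outer(sin(pi * x), sin(pi * y))
  st <- initial_state(grid, mock_params(), seed = 1)
  st$P_o <- 0.2 + 0.1 * bump
  st$P_g <- 0.3 + 0.1 * bump
  st$P_d <- 0.05 + 0 * bump
  st$W <- 2 + bump
  st$W_I <- 1 + 0.5 * bump
  st$N <- 0.5 + 0.2 * bump
  st
}

# Independent reference: fully explicit Euler stepper with the same
# conservative Neumann stencil (and Dirichlet nutrient frame), written in
# plain R against reaction_rhs().
explicit_reference <- function(state, params, dt, nsteps, Nb_override = NULL) {
  g <- state$grid
  h <- g$h
  lap <- function(F, D) {
    up <- rbind(F[1, ], F[-nrow(F), ])
    dn <- rbind(F[-1, ], F[nrow(F), ])
    lf <- cbind(F[, 1], F[, -ncol(F)])
    rt <- cbind(F[, -1], F[, ncol(F)])
    D * ((up + dn - 2 * F) / h[1]^2 + (lf + rt - 2 * F) / h[2]^2)
  }
  cv <- grid_cell_volume(g)
  f <- state[field_names()]
  for (i in seq_len(nsteps)) {
    ipg <- sum(f$P_g) * cv
    ilive <- ipg + (sum(f$P_o) + sum(f$P_d)) * cv
    r <- reaction_rhs(f, min(ipg, prod(g$lengths)), params,
                      integral_live = ilive)
    Nb <- if (is.null(Nb_override))
      nutrient_boundary(min(ipg, prod(g$lengths)), params,
                        integral_live = ilive) else Nb_override
    f$N[c(1, nrow(f$N)), ] <- Nb; f$N[, c(1, ncol(f$N))] <- Nb
    new <- list(
      P_o = f$P_o + dt * (lap(f$P_o, params$D_o) + r$dP_o),
      P_g = f$P_g + dt * (lap(f$P_g, params$D_g) + r$dP_g),
      P_d = f$P_d + dt * (lap(f$P_d, params$D_d) + r$dP_d),
      W   = f$W + dt * (lap(f$W, params$D_W) + r$dW),
      W_I = f$W_I + dt * (lap(f$W_I, params$D_WI) + r$dW_I),
      N   = f$N + dt * (lap_dirichlet(f$N, params$D_N, h) + r$dN))
    new$N[c(1, nrow(new$N)), ] <- Nb; new$N[, c(1, ncol(new$N))] <- Nb
    f <- lapply(new, function(x) pmax(x, 0))
  }
  f
}

lap_dirichlet <- function(F, D, h) {
  up <- rbind(F[1, ], F[-nrow(F), ])
  dn <- rbind(F[-1, ], F[nrow(F), ])
  lf <- cbind(F[, 1], F[, -ncol(F)])
  rt <- cbind(F[, -1], F[, ncol(F)])
  L <- D * ((up + dn - 2 * F) / h[1]^2 + (lf + rt - 2 * F) / h[2]^2)
  L[c(1, nrow(F)), ] <- 0
  L[, c(1, ncol(F))] <- 0
  L
}

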