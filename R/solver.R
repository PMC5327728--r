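#' @useDynLib wntpattern, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Inverse implicit-diffusion operator (I - dt * D * L / h^2)^-1 along one
# axis.  The Neumann Laplacian uses the conservative (zero column sum)
# stencil, so row sums of the inverse are one and total mass is preserved
# exactly by each sweep.  For Dirichlet boundaries the boundary rows are
# identity rows: boundary values pass through the solve unchanged and the
# interior rows couple to them implicitly.
make_axis_op <- function(n, h, D, dt, bc = c("neumann", "dirichlet")) {
  bc <- match.arg(bc)
  L <- diag(-2, n)
  L[cbind(2:n, 1:(n - 1))] <- 1
  L[cbind(1:(n - 1), 2:n)] <- 1
  if (bc == "neumann") {
    L[1, 1] <- -1
    L[n, n] <- -1
  } else {
    L[1, ] <- 0
    L[n, ] <- 0
  }
  solve(diag(n) - (dt * D / h^2) * L)
}

# All per-field operators for one (grid, params, dt) combination.
build_ops <- function(grid, params, dt, extra_D = NULL) {
  Ds <- c(AO = params$D_o, AG = params$D_g, AD = params$D_d,
          AW = params$D_W, AI = params$D_WI, AN = params$D_N)
  if (!is.null(extra_D)) Ds <- c(Ds, AL = extra_D)
  axes <- c("x", "y", "z")[seq_len(grid$ndim)]
  ops <- list()
  cache <- list()
  for (nmf in names(Ds)) {
    D <- Ds[[nmf]]
    bc <- if (nmf == "AN") "dirichlet" else "neumann"
    for (d in seq_len(grid$ndim)) {
      key <- paste(D, bc, grid$n[d], grid$h[d], sep = "|")
      if (is.null(cache[[key]]))
        cache[[key]] <- make_axis_op(grid$n[d], grid$h[d], D, dt, bc)
      nm <- paste0("A", axes[d], sub("^A", "", nmf))
      ops[[nm]] <- cache[[key]]
    }
  }
  ops
}

# Heuristic explicit-reaction stability bound on dt.
reaction_dt_bound <- function(params) {
  lam <- max(params$gamma_N * max(params$mu_o, params$mu_g) / 2,
             1 / params$tau_og, params$gamma_N * params$N_s / 10,
             params$mu_Po, params$mu_Pg)
  2 / lam
}

#' Advance a field state by one semi-implicit time step
#'
#' One step of the operator-split scheme: explicit reaction update (with
#' the nutrient uptake and decay treated pointwise implicitly), then
#' implicit diffusion via dimensionally split solves.  All fields use
#' no-flux (homogeneous Neumann) boundaries except the nutrient, whose
#' Dirichlet boundary value is tied to the current total glycolytic
#' population (see [nutrient_boundary()]); small negative undershoots are
#' clipped to zero.
#'
#' @param state A `field_state` (see [initial_state()]).
#' @param params A [model_params()] object (validation is not repeated, so
#'   experimental parameter lists can be passed).
#' @param dt Time step; warned about if above the explicit reaction
#'   stability heuristic.
#' @param Nb_override Fixed nutrient boundary value, or `NULL` for the
#'   glycolysis-coupled default.
#' @return The advanced `field_state`.
#' @export
step_state <- function(state, params, dt, Nb_override = NULL) {
  res <- run_core(state, params, nsteps = 1L, dt = dt,
                  diag_every = 1L, conv_tol = 0, Nb_override = Nb_override,
                  warn_dt = TRUE)
  res$state
}

# Shared driver around the compiled core.
run_core <- function(state, params, nsteps, dt, diag_every, conv_tol,
                     Nb_override = NULL, warn_dt = FALSE, ops = NULL,
                     invitro = FALSE, invitro_pars = NULL) {
  grid <- state$grid
  if (warn_dt && dt > reaction_dt_bound(params))
    warning(sprintf("dt = %g exceeds the explicit reaction stability bound %g",
                    dt, reaction_dt_bound(params)))
  if (is.null(ops))
    ops <- build_ops(grid, params, dt,
                     extra_D = if (invitro) params$D_L else NULL)
  nb <- if (is.null(Nb_override)) -1 else Nb_override
  V <- prod(grid$lengths)
  cv <- grid_cell_volume(grid)
  if (grid$ndim == 2) {
    out <- rd_run_2d(state$P_o, state$P_g, state$P_d, state$W, state$W_I,
                     state$N, unclass(params), ops, as.integer(nsteps), dt,
                     cv, V, state$time, as.integer(diag_every), conv_tol,
                     nb, invitro,
                     if (invitro) invitro_pars else list())
  } else {
    if (invitro) stop("the in vitro variant is 2D only")
    out <- rd_run_3d(state$P_o, state$P_g, state$P_d, state$W, state$W_I,
                     state$N, unclass(params), ops, as.integer(nsteps), dt,
                     cv, V, state$time, as.integer(diag_every), conv_tol, nb)
  }
  if (nzchar(out$diverged_field))
    stop("field '", out$diverged_field,
         "' diverged or became non-finite at t = ", out$time,
         " (total P_g = ", signif(sum(out$P_g) * cv, 4), ")", call. = FALSE)
  fields <- out[field_names()]
  st <- new_field_state(fields, time = out$time, seed = state$seed,
                        grid = grid)
  if (invitro) st$L <- out$L
  list(state = st, diag = out$diag, converged = out$converged,
       clipped_mass = out$clipped_mass, steps = out$steps, ops = ops)
}

#' Simulate the in vivo Wnt/metabolism model
#'
#' Integrates the model from the boundary-seeded initial condition (or a
#' supplied state) until `t_end` or until the pattern stops changing
#' (maximum relative field change per unit time below `conv_tol`).  With
#' the mock parameter set on the default 12 x 12 domain the glycolytic
#' field self-organises into a spotted array that is denser near the
#' domain boundary.
#'
#' @param params A [model_params()] object.
#' @param grid A [sim_grid()]; default a 2D 128 x 128 grid over the
#'   parameter set's domain.
#' @param t_end Final nondimensional time.
#' @param dt Time step (default 5e-4).
#' @param seed RNG seed for the initial condition.
#' @param snapshot_every Interval (in time units) between stored snapshot
#'   states, or `NULL` to keep only the final state.
#' @param state Optional starting `field_state` (overrides `seed`).
#' @param conv_tol Steady-state tolerance on the relative change per unit
#'   time (default 1e-6; set to 0 to disable early exit).
#' @param shell_width Boundary seeding shell width for the initial state.
#' @param Nb_override Fixed nutrient Dirichlet value (`NULL` = coupled).
#' @return An object of class `sim_result`: final `state`, `snapshots`,
#'   a `diagnostics` data frame (time, field totals, mean nutrient,
#'   maximum relative change), `converged` flag, cumulative clipped mass
#'   and the parameters used.
#' @examples
#' \donttest{
#' res <- simulate_model(mock_params(), grid = sim_grid(48), t_end = 5,
#'                       dt = 1e-3, seed = 1)
#' tail(res$diagnostics)
#' }
#' @export
simulate_model <- function(params, grid = NULL, t_end = 200, dt = 5e-4,
                           seed = 1, snapshot_every = NULL, state = NULL,
                           conv_tol = 1e-6, shell_width = 1.2,
                           Nb_override = NULL) {
  stopifnot(t_end > 0, dt > 0)
  if (is.null(grid)) {
    grid <- if (is.null(state)) sim_grid(128, 2, c(params$S_x, params$S_y))
            else state$grid
  }
  if (is.null(state)) state <- initial_state(grid, params, seed, shell_width)
  t0 <- state$time
  diag_every <- max(1L, round(0.5 / dt))
  ops <- build_ops(grid, params, dt)
  snapshots <- NULL
  diags <- list()
  converged <- FALSE
  clipped <- 0
  if (is.null(snapshot_every)) {
    res <- run_core(state, params, nsteps = ceiling((t_end - t0) / dt),
                    dt = dt, diag_every = diag_every, conv_tol = conv_tol,
                    Nb_override = Nb_override, ops = ops)
    state <- res$state
    diags[[1]] <- res$diag
    converged <- res$converged
    clipped <- res$clipped_mass
  } else {
    snapshots <- list()
    chunk <- max(1L, round(snapshot_every / dt))
    nchunks <- ceiling((t_end - t0) / (chunk * dt))
    for (i in seq_len(nchunks)) {
      res <- run_core(state, params, nsteps = chunk, dt = dt,
                      diag_every = diag_every, conv_tol = conv_tol,
                      Nb_override = Nb_override, ops = ops)
      state <- res$state
      snapshots[[length(snapshots) + 1L]] <- state
      diags[[i]] <- res$diag
      clipped <- clipped + res$clipped_mass
      if (res$converged) { converged <- TRUE; break }
    }
  }
  structure(list(state = state, snapshots = snapshots,
                 diagnostics = do.call(rbind, diags), converged = converged,
                 clipped_mass = clipped, params = params, dt = dt,
                 seed = state$seed),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("sim_result: t = %.4g, converged = %s\n", x$state$time,
              x$converged))
  if (!is.null(d) && nrow(d))
    cat(sprintf("  totals: P_o %.4g, P_g %.4g, P_d %.4g; mean N %.4g\n",
                d$total_P_o[nrow(d)], d$total_P_g[nrow(d)],
                d$total_P_d[nrow(d)], d$mean_N[nrow(d)]))
  invisible(x)
}

#' Total live tumour burden of a state
#'
#' Domain integral of `P_o + P_g`.
#' @param state A `field_state`.
#' @return A scalar.
#' @export
tumor_burden <- function(state) {
  (sum(state$P_o) + sum(state$P_g)) * grid_cell_volume(state$grid)
}
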