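#' Parameters of the in vitro (spheroid/colony) model variant
#'
#' In the gel-embedded colony there is no angiogenesis: the nutrient has
#' no glycolysis-coupled bulk source and enters only by diffusion from the
#' gel boundary, held at a fixed Dirichlet level.  Instead, metabolic
#' symbiosis is explicit: glycolytic cells export a diffusible by-product
#' `L` (lactate) in proportion to their glycolytic flux, oxidative cells
#' consume it as auxiliary fuel (their proliferation uses `N + beta_L * L`
#' in place of `N`), and `L` decays.
#'
#' @param base A [model_params()] object for the cell/Wnt dynamics; its
#'   nutrient-source coupling is disabled in this variant.
#' @param D_L By-product diffusivity.
#' @param c_prod By-product produced per unit of glycolytic nutrient flux.
#' @param c_feed Consumption rate of `L` by oxidative cells.
#' @param mu_L By-product decay rate.
#' @param beta_L Weight of `L` as fuel in oxidative proliferation.
#' @param gel_N Fixed nutrient level at the gel boundary.
#' @return An object of class `invitro_params` (also `model_params`).
#' @export
invitro_params <- function(base = mock_params(), D_L = 1, c_prod = 1,
                           c_feed = 1, mu_L = 1, beta_L = 0.5, gel_N = 1) {
  stopifnot(inherits(base, "model_params"), D_L > 0, c_prod >= 0,
            c_feed >= 0, mu_L > 0, beta_L >= 0, gel_N > 0)
  p <- base
  p$D_L <- D_L; p$c_prod <- c_prod; p$c_feed <- c_feed
  p$mu_L <- mu_L; p$beta_L <- beta_L; p$gel_N <- gel_N
  class(p) <- c("invitro_params", "model_params")
  p
}

#' In vitro reaction terms
#'
#' The reaction right-hand sides of the colony model: identical to the in
#' vivo [reaction_rhs()] except that the global nutrient source is absent
#' and the cross-feeding by-product `L` is added (with `c_feed = 0` and
#' `beta_L = 0` the cell/Wnt/nutrient terms reduce exactly to the in vivo
#' ones minus the source).
#'
#' @param state Named list with `P_o`, `P_g`, `P_d`, `W`, `W_I`, `N`, `L`.
#' @param params An [invitro_params()] object.
#' @return A list of derivatives including `dL`.
#' @export
invitro_reaction_rhs <- function(state, params) {
  p <- params
  base <- reaction_rhs(state[c("P_o", "P_g", "P_d", "W", "W_I", "N")],
                       integral_Pg = 0, params = p)
  L <- state$L
  if (any(L < 0)) stop("negative value in field 'L'", call. = FALSE)
  # remove the bulk source: in the gel, nutrient arrives only by diffusion
  base$dN <- base$dN - nutrient_source(0, p)
  # oxidative proliferation fuelled by nutrient plus by-product
  ng <- nutrient_gates(state$N, p)
  P_tot <- state$P_o + state$P_g + state$P_d
  base$dP_o <- base$dP_o +
    (1 / p$tau_o) * (p$beta_L * L) * state$P_o * (1 - P_tot)
  base$dL <- p$c_prod * p$nu_NG * state$N * state$P_g -
    p$c_feed * L * state$P_o - p$mu_L * L
  base
}

#' Initial condition of a gel-embedded colony
#'
#' A small central disk of glycolytic cells with weak Wnt activity,
#' bathed in nutrient at the gel level; no oxidative or dead cells and no
#' by-product initially.
#'
#' @param grid A 2D [sim_grid()].
#' @param params An [invitro_params()] object.
#' @param seed RNG seed.
#' @param seed_radius Radius of the seeded disk (nondimensional units).
#' @return A `field_state` with the extra field `L`.
#' @export
colony_initial_state <- function(grid, params, seed = 1, seed_radius = 1.5) {
  stopifnot(inherits(grid, "sim_grid"), grid$ndim == 2)
  set.seed(seed)
  n <- grid$n
  cx <- grid$lengths / 2
  r <- sqrt(outer((grid$coords[[1]] - cx[1])^2,
                  (grid$coords[[2]] - cx[2])^2, "+"))
  core <- r < seed_radius
  zero <- matrix(0, n[1], n[2])
  P_g <- zero; W <- zero; W_I <- zero
  P_g[core] <- stats::runif(sum(core), 0, 0.5)
  W[core] <- stats::runif(sum(core), 0, 0.1)
  W_I[core] <- stats::runif(sum(core), 0, 0.1)
  st <- new_field_state(list(P_o = zero, P_g = P_g, P_d = zero, W = W,
                             W_I = W_I, N = zero + params$gel_N),
                        time = 0, seed = seed, grid = grid)
  st$L <- zero
  st
}

#' Simulate a gel-embedded colony, optionally under treatment
#'
#' Integrates the in vitro model from a central seed.  A [therapy_plan()]
#' is applied for the whole run (drugs are present in the medium
#' throughout), modifying `S_W`, diffusivities and `tau_go` via
#' [combo_params()]; in this variant DCA doses below the baseline switch
#' rate are accepted verbatim.
#'
#' @param params An [invitro_params()] object.
#' @param grid A 2D [sim_grid()]; defaults to 96 points over the domain.
#' @param seed RNG seed for the colony seed.
#' @param plan Optional [therapy_plan()] applied from `t = 0`.
#' @param t_end Final time.
#' @param dt Time step.
#' @param conv_tol Steady-state tolerance (0 disables early exit).
#' @return An object of class `colony_result`: `state`, `diagnostics`
#'   (with colony size `total_P_o + total_P_g` over time), `final_size`
#'   and `converged`.
#' @export
simulate_colony <- function(params, grid = NULL, seed = 1, plan = NULL,
                            t_end = 40, dt = 1e-3, conv_tol = 0) {
  stopifnot(inherits(params, "invitro_params"))
  if (is.null(grid))
    grid <- sim_grid(96, 2, c(params$S_x, params$S_y))
  p <- params
  if (!is.null(plan)) {
    p$S_W <- plan$xav_factor * p$S_W
    if (plan$diffusion_scaling) {
      p$D_W <- p$D_W + XAV_DW_SLOPE * (1 - plan$xav_factor)
      p$D_WI <- p$D_WI + XAV_DWI_SLOPE * (1 - plan$xav_factor)
    }
    if (!is.null(plan$dca_rate)) p$tau_go <- 1 / plan$dca_rate
    p$mu_Po <- p$mu_Po + plan$mu_Po
    p$mu_Pg <- p$mu_Pg + plan$mu_Pg
  }
  state <- colony_initial_state(grid, p, seed)
  diag_every <- max(1L, round(0.5 / dt))
  inv <- list(L = state$L, c_prod = p$c_prod, c_feed = p$c_feed,
              mu_L = p$mu_L, beta_L = p$beta_L, gel_N = p$gel_N)
  res <- run_core(state, p, nsteps = ceiling(t_end / dt), dt = dt,
                  diag_every = diag_every, conv_tol = conv_tol,
                  invitro = TRUE, invitro_pars = inv)
  d <- res$diag
  d$colony_size <- d$total_P_o + d$total_P_g
  structure(list(state = res$state, diagnostics = d,
                 final_size = d$colony_size[nrow(d)],
                 converged = res$converged, params = p, plan = plan,
                 seed = seed),
            class = "colony_result")
}

#' @export
print.colony_result <- function(x, ...) {
  cat(sprintf("colony_result: t = %.4g, colony size %.5g%s\n",
              x$state$time, x$final_size,
              if (is.null(x$plan)) " (untreated)" else " (treated)"))
  invisible(x)
}

#' Bliss combination index of XAV939 + DCA in the colony model
#'
#' Grows four colonies from the same seed - untreated, XAV939 alone, DCA
#' alone, and the combination - computes each fractional effect as one
#' minus the final colony size relative to untreated (clipped to
#' `[0, 1]`), and scores synergy with [bliss_ci()].
#'
#' @param params An [invitro_params()] object.
#' @param xav_factor XAV939 multiplier on `S_W`.
#' @param dca_rate Treated `1/tau_go` (the in vitro dose convention admits
#'   values below baseline and is applied verbatim).
#' @param grid,seed,t_end,dt Passed to [simulate_colony()].
#' @param diffusion_scaling Passed through to the XAV model.
#' @return A list with the `bliss_result` (`$bliss`), the four final
#'   sizes, and the three effects.
#' @export
invitro_bliss <- function(params, xav_factor = 0.8, dca_rate = 0.25,
                          grid = NULL, seed = 1, t_end = 40, dt = 1e-3,
                          diffusion_scaling = TRUE) {
  run <- function(f, dca) {
    plan <- if (is.null(f) && is.null(dca)) NULL else
      therapy_plan("none", xav_factor = if (is.null(f)) 1 else f,
                   diffusion_scaling = diffusion_scaling,
                   dca_rate = dca)
    simulate_colony(params, grid = grid, seed = seed, plan = plan,
                    t_end = t_end, dt = dt)$final_size
  }
  s0 <- run(NULL, NULL)
  sA <- run(xav_factor, NULL)
  sB <- run(NULL, dca_rate)
  sAB <- run(xav_factor, dca_rate)
  eff <- function(s) min(max(1 - s / s0, 0), 1)
  bl <- bliss_ci(eff(sA), eff(sB), eff(sAB))
  list(bliss = bl, size_untreated = s0, size_xav = sA, size_dca = sB,
       size_combo = sAB, E_A = eff(sA), E_B = eff(sB), E_AB = eff(sAB))
}
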