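#' Wnt metabolic switch functions
#'
#' The propensity of cells to emphasise glycolysis over OXPHOS is a smooth
#' sigmoidal function of local Wnt activity,
#' `chi_W = (1 + tanh(gamma_W * (W - W_star))) / 2`, with complement
#' `chi_W_star = 1 - chi_W`.  Cells above the half-switch level `W_star`
#' favour glycolysis; below it they favour OXPHOS.
#'
#' @param W Wnt activity (scalar or array); must be nonnegative.
#' @param params A [model_params()] object.
#' @return A list with components `chi_W` and `chi_W_star`, both in
#'   \eqn{[0, 1]} and summing to one elementwise.
#' @examples
#' wnt_switch(5, mock_params())$chi_W      # 0.5 at the threshold
#' wnt_switch(6, mock_params())$chi_W      # (1 + tanh(1)) / 2
#' @export
wnt_switch <- function(W, params) {
  if (any(!is.finite(W))) stop("non-finite Wnt activity", call. = FALSE)
  if (any(W < 0)) stop("Wnt activity must be nonnegative", call. = FALSE)
  chi <- 0.5 * (1 + tanh(params$gamma_W * (W - params$W_star)))
  list(chi_W = chi, chi_W_star = 1 - chi)
}

#' Nutrient survival and switch-permission gates
#'
#' Two sigmoidal gates of local nutrient level: `chi_N` rises around the
#' death threshold `N_star` (cells die where `chi_N` is small) and
#' `chi_N_star` rises around `N_g_star`, the floor below which oxidative
#' cells cannot switch to glycolysis.  Both use steepness `gamma_N`; at the
#' default `gamma_N = 100` they are effectively step functions.
#'
#' @param N Nutrient level (scalar or array); must be nonnegative.
#' @param params A [model_params()] object.
#' @return A list with components `chi_N` and `chi_N_star` in \eqn{[0, 1]}.
#' @export
nutrient_gates <- function(N, params) {
  if (any(!is.finite(N))) stop("non-finite nutrient level", call. = FALSE)
  if (any(N < 0)) stop("nutrient level must be nonnegative", call. = FALSE)
  list(chi_N      = 0.5 * (1 + tanh(params$gamma_N * (N - params$N_star))),
       chi_N_star = 0.5 * (1 + tanh(params$gamma_N * (N - params$N_g_star))))
}

#' Domain volume (area in 2D) of the parameter set
#' @param params A [model_params()] object.
#' @param ndim 2 or 3.
#' @return `S_x * S_y` (2D) or `S_x * S_y * S_z` (3D).
#' @keywords internal
domain_volume <- function(params, ndim = 2) {
  stopifnot(ndim %in% c(2, 3))
  if (ndim == 2) params$S_x * params$S_y else params$S_x * params$S_y * params$S_z
}

#' Glycolysis-coupled nutrient source
#'
#' The bulk nutrient source models the angiogenic response to lactate
#' secreted by glycolytic cells: it is linear in the total glycolytic
#' population,
#' `N_S = N_s * ((1 - alpha_N) * int_Pg / denom + alpha_N)`.
#' In the plain closure (`integral_live = NULL`) the normaliser `denom` is
#' the domain volume `V = S_x * S_y` (or the 3D volume), so that the source
#' equals `N_s * alpha_N` at zero glycolysis and the amplitude `N_s` at the
#' maximal population `int_Pg = V`.  The dynamical closure used by the
#' simulator normalises instead by the tumour bulk
#' `max(integral_live, live_floor * V)` with
#' `integral_live = int(P_o + P_g + P_d)`, i.e. by the glycolytic share
#' of the tumour mass: vascular support tracks how glycolytic the tumour
#' is, not how large it is.  Both closures agree at full occupancy and
#' share the two endpoint identities.
#'
#' @param integral_Pg Domain integral of `P_g`; must lie in `[0, V]`.
#' @param params A [model_params()] object.
#' @param ndim Dimensionality of the domain (2 or 3).
#' @param integral_live Domain integral of `P_o + P_g + P_d`, or `NULL`
#'   for the plain domain-volume normalisation.
#' @return The scalar source `N_S`.
#' @examples
#' nutrient_source(0, mock_params())           # N_s * alpha_N = 0.05
#' nutrient_source(144, mock_params())         # N_s = 2 at int_Pg = S_x*S_y
#' @export
nutrient_source <- function(integral_Pg, params, ndim = 2,
                            integral_live = NULL) {
  V <- domain_volume(params, ndim)
  if (!is.numeric(integral_Pg) || length(integral_Pg) != 1L ||
      !is.finite(integral_Pg) || integral_Pg < 0 || integral_Pg > V)
    stop("integral_Pg must lie in [0, ", V, "]", call. = FALSE)
  denom <- if (is.null(integral_live)) V else
    max(integral_live, params$live_floor * V)
  frac <- min(integral_Pg / denom, 1)
  params$N_s * ((1 - params$alpha_N) * frac + params$alpha_N)
}

#' Nutrient Dirichlet boundary value
#'
#' The nutrient boundary condition follows the same glycolysis-coupled law
#' as the bulk source, rescaled by the amplitude:
#' `N_b = (1 - alpha_N) * int_Pg / V + alpha_N`, which lies in
#' `[alpha_N, 1]` and equals 1 at maximal glycolysis.
#'
#' @inheritParams nutrient_source
#' @return The scalar boundary value.
#' @export
nutrient_boundary <- function(integral_Pg, params, ndim = 2,
                              integral_live = NULL) {
  nutrient_source(integral_Pg, params, ndim, integral_live) / params$N_s
}

#' Reaction terms of the in vivo model
#'
#' Evaluates the local (diffusion-free) time derivatives of all six fields.
#' The terms are: logistic proliferation `(1/tau) * N * P * (1 - P_tot)`
#' (for `P_g` additionally scaled by the Michaelis-Menten factor
#' `W / (alpha_W + W)`); metabolic switching
#' `(1/tau_og) * chi_W * chi_N_star * P_o` from OXPHOS to glycolysis and
#' `(1/tau_go) * chi_W_star * P_g` back; starvation death
#' `mu * (1 - chi_N) * P` routed into the dead pool `P_d`, which decays at
#' `mu_d`; autocatalytic Wnt production
#' `kappa_W * N * P_g * W^2 / (a + b * W_I)` plus constitutive production
#' `S_W * (P_o + P_g)` minus decay; quadratic inhibitor production
#' `kappa_WI * W^2 * (P_o + P_g)` minus decay; and nutrient uptake, decay
#' and the global source [nutrient_source()].  The total population
#' `P_tot = P_o + P_g + P_d` includes dead cells, which occupy space.
#' Optional therapy death rates `mu_Po`, `mu_Pg` in `params` add
#' `-mu_Po * P_o` and `-mu_Pg * P_g`, also routed into `P_d`.
#'
#' @param state Named list with components `P_o`, `P_g`, `P_d`, `W`, `W_I`,
#'   `N` (scalars or congruent arrays), all nonnegative.
#' @param integral_Pg Domain integral of `P_g` used by the global source.
#' @param params A [model_params()] object.
#' @param ndim Domain dimensionality for the source normalisation.
#' @param integral_live Domain integral of `P_o + P_g + P_d` for the
#'   glycolytic-share source closure (see [nutrient_source()]).
#' @return A list of class `reaction_derivatives` with components `dP_o`,
#'   `dP_g`, `dP_d`, `dW`, `dW_I`, `dN`.
#' @export
reaction_rhs <- function(state, integral_Pg, params, ndim = 2,
                         integral_live = NULL) {
  fields <- c("P_o", "P_g", "P_d", "W", "W_I", "N")
  for (f in fields) {
    v <- state[[f]]
    if (is.null(v)) stop("state is missing field '", f, "'", call. = FALSE)
    if (any(is.na(v) | !is.finite(v)))
      stop("non-finite value in field '", f, "'", call. = FALSE)
    if (any(v < 0))
      stop("negative value in field '", f, "'", call. = FALSE)
  }
  P_o <- state$P_o; P_g <- state$P_g; P_d <- state$P_d
  W <- state$W; W_I <- state$W_I; N <- state$N
  p <- params
  sw <- wnt_switch(W, p)
  ng <- nutrient_gates(N, p)
  P_tot <- P_o + P_g + P_d
  mm <- W / (p$alpha_W + W)
  prol_o <- (1 / p$tau_o) * N * P_o * (1 - P_tot)
  prol_g <- (1 / p$tau_g) * N * P_g * (1 - P_tot) * mm
  sw_og <- (1 / p$tau_og) * sw$chi_W * ng$chi_N_star * P_o
  sw_go <- (1 / p$tau_go) * sw$chi_W_star * P_g
  death_o <- (p$mu_o * (1 - ng$chi_N) + p$mu_Po) * P_o
  death_g <- (p$mu_g * (1 - ng$chi_N) + p$mu_Pg) * P_g
  N_S <- nutrient_source(integral_Pg, p, ndim, integral_live)
  out <- list(
    dP_o = prol_o - sw_og + sw_go - death_o,
    dP_g = prol_g + sw_og - sw_go - death_g,
    dP_d = death_o + death_g - p$mu_d * P_d,
    dW   = p$kappa_W * N * P_g * W^2 / (p$a + p$b * W_I) +
           p$S_W * (P_o + P_g) - p$mu_W * W,
    dW_I = p$kappa_WI * W^2 * (P_o + P_g) - p$mu_WI * W_I,
    dN   = -p$nu_NO * N * P_o - p$nu_NG * N * P_g - p$mu_N * N + N_S
  )
  class(out) <- "reaction_derivatives"
  out
}

#' Analytic Jacobian of the reaction terms at a uniform state
#'
#' Returns the 6x6 Jacobian of [reaction_rhs()] with respect to
#' `(P_o, P_g, P_d, W, W_I, N)` evaluated at a spatially uniform state,
#' used by the diffusive (Turing) stability analysis.  The global
#' glycolytic-share source coupling contributes to `d(dN)/d(P_o)` and
#' `d(dN)/d(P_g)` only for the homogeneous (`k = 0`) mode; set
#' `include_global = FALSE` for finite-wavenumber modes.
#'
#' @param state Named list of six scalar field values (uniform state).
#' @param params A [model_params()] object.
#' @param include_global Include the `k = 0` mean-field source coupling?
#' @return A 6x6 numeric matrix with rows/columns named
#'   `P_o, P_g, P_d, W, W_I, N`.
#' @export
reaction_jacobian <- function(state, params, include_global = TRUE) {
  p <- params
  P_o <- state$P_o; P_g <- state$P_g; P_d <- state$P_d
  W <- state$W; W_I <- state$W_I; N <- state$N
  stopifnot(length(P_o) == 1L, length(N) == 1L)
  chi_W <- 0.5 * (1 + tanh(p$gamma_W * (W - p$W_star)))
  dchi_W <- 0.5 * p$gamma_W / cosh(p$gamma_W * (W - p$W_star))^2
  chi_N <- 0.5 * (1 + tanh(p$gamma_N * (N - p$N_star)))
  dchi_N <- 0.5 * p$gamma_N / cosh(p$gamma_N * (N - p$N_star))^2
  chi_Ns <- 0.5 * (1 + tanh(p$gamma_N * (N - p$N_g_star)))
  dchi_Ns <- 0.5 * p$gamma_N / cosh(p$gamma_N * (N - p$N_g_star))^2
  Tt <- P_o + P_g + P_d
  mm <- W / (p$alpha_W + W)
  dmm <- p$alpha_W / (p$alpha_W + W)^2
  inh <- p$a + p$b * W_I
  J <- matrix(0, 6, 6,
              dimnames = list(c("P_o", "P_g", "P_d", "W", "W_I", "N"),
                              c("P_o", "P_g", "P_d", "W", "W_I", "N")))
  ro <- 1 / p$tau_o; rg <- 1 / p$tau_g
  rog <- 1 / p$tau_og; rgo <- 1 / p$tau_go
  # dP_o row
  J[1, 1] <- ro * N * (1 - Tt) - ro * N * P_o - rog * chi_W * chi_Ns -
    p$mu_o * (1 - chi_N) - p$mu_Po
  J[1, 2] <- -ro * N * P_o + rgo * (1 - chi_W)
  J[1, 3] <- -ro * N * P_o
  J[1, 4] <- -rog * dchi_W * chi_Ns * P_o - rgo * dchi_W * P_g
  J[1, 6] <- ro * P_o * (1 - Tt) - rog * chi_W * dchi_Ns * P_o +
    p$mu_o * dchi_N * P_o
  # dP_g row
  J[2, 1] <- -rg * N * P_g * mm + rog * chi_W * chi_Ns
  J[2, 2] <- rg * N * mm * (1 - Tt) - rg * N * P_g * mm -
    rgo * (1 - chi_W) - p$mu_g * (1 - chi_N) - p$mu_Pg
  J[2, 3] <- -rg * N * P_g * mm
  J[2, 4] <- rg * N * P_g * (1 - Tt) * dmm + rog * dchi_W * chi_Ns * P_o +
    rgo * dchi_W * P_g
  J[2, 6] <- rg * P_g * (1 - Tt) * mm + rog * chi_W * dchi_Ns * P_o +
    p$mu_g * dchi_N * P_g
  # dP_d row
  J[3, 1] <- p$mu_o * (1 - chi_N) + p$mu_Po
  J[3, 2] <- p$mu_g * (1 - chi_N) + p$mu_Pg
  J[3, 3] <- -p$mu_d
  J[3, 6] <- -p$mu_o * dchi_N * P_o - p$mu_g * dchi_N * P_g
  # dW row
  J[4, 1] <- p$S_W
  J[4, 2] <- p$kappa_W * N * W^2 / inh + p$S_W
  J[4, 4] <- 2 * p$kappa_W * N * P_g * W / inh - p$mu_W
  J[4, 5] <- -p$kappa_W * N * P_g * W^2 * p$b / inh^2
  J[4, 6] <- p$kappa_W * P_g * W^2 / inh
  # dW_I row
  J[5, 1] <- p$kappa_WI * W^2
  J[5, 2] <- p$kappa_WI * W^2
  J[5, 4] <- 2 * p$kappa_WI * W * (P_o + P_g)
  J[5, 5] <- -p$mu_WI
  # dN row
  J[6, 1] <- -p$nu_NO * N
  J[6, 2] <- -p$nu_NG * N
  J[6, 6] <- -p$nu_NO * P_o - p$nu_NG * P_g - p$mu_N
  if (include_global) {
    # glycolytic-share source: N_S = N_s ((1 - alpha_N) P_g / L + alpha_N)
    # with L = max(P_o + P_g + P_d, live_floor); piecewise in the floor.
    live <- P_o + P_g + P_d
    cN <- p$N_s * (1 - p$alpha_N)
    if (live > p$live_floor) {
      J[6, 1] <- J[6, 1] - cN * P_g / live^2
      J[6, 2] <- J[6, 2] + cN * (live - P_g) / live^2
      J[6, 3] <- J[6, 3] - cN * P_g / live^2
    } else {
      J[6, 2] <- J[6, 2] + cN / p$live_floor
    }
  }
  J
}
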