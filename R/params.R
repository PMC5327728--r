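#' Model parameters for the in vivo Wnt/metabolism model
#'
#' Constructs and validates the full parameter set of the coupled
#' Wnt/metabolism reaction-diffusion model.  The defaults are the "mock"
#' (parental xenograft) values; [dnlef_params()] gives the preset used to
#' model partial Wnt interference by dominant-negative LEF-1/TCF-1
#' (reduced constitutive Wnt production `S_W`, doubled Wnt diffusivity
#' `D_W`, Wnt-inhibitor diffusivity raised to 1.5).
#'
#' All quantities are nondimensional: time is measured in units of the
#' characteristic proliferation time (1 day) and space in units of the Wnt
#' inhibitor diffusion length (about 40 um); see [unit_calibration()].
#'
#' @param D_o,D_g Diffusivities of oxidative (`P_o`) and glycolytic (`P_g`)
#'   cells.
#' @param D_d Diffusivity of dead cells; defaults to `D_o` (dead cells are
#'   assumed to undergo the same random motion as live ones).
#' @param D_W,D_WI Diffusivities of Wnt activity and of the Wnt inhibitor.
#'   The inhibitor must diffuse longer range than Wnt (`D_W < D_WI`),
#'   the Gierer-Meinhardt short-range-activator/long-range-inhibitor
#'   requirement.
#' @param D_N Nutrient diffusivity.
#' @param tau_o,tau_g Proliferation times of the two live populations.
#' @param tau_og,tau_go Metabolic switch times (OXPHOS to glycolysis and
#'   back); the corresponding rates are `1/tau_og`, `1/tau_go`.
#' @param alpha_W Michaelis-Menten constant of the Wnt dependence of
#'   glycolytic proliferation, term `W / (alpha_W + W)`.
#' @param kappa_W,kappa_WI Nonlinear (autocatalytic) production rates of Wnt
#'   and of the Wnt inhibitor.
#' @param mu_o,mu_g,mu_d Death rate of starving live cells and decay rate of
#'   dead cells.
#' @param mu_W,mu_WI,mu_N Decay rates of Wnt, Wnt inhibitor and nutrient.
#' @param S_W Constitutive Wnt production rate through both live cell types.
#' @param a,b Constants of Wnt inhibition: the autocatalytic Wnt term is
#'   divided by `a + b * W_I`.
#' @param gamma_W,gamma_N Steepness of the Wnt and nutrient switch functions
#'   (modified hyperbolic tangents).
#' @param nu_NG,nu_NO Nutrient uptake rates of glycolytic and oxidative
#'   cells.
#' @param N_s Amplitude of the glycolysis-coupled nutrient source.
#' @param alpha_N Value of the nutrient-source scaling function when the
#'   total glycolytic population is zero; must lie in (0, 1].
#' @param W_star Wnt level at which half of the cells switch metabolism.
#' @param N_star Nutrient level below which cells die.
#' @param N_g_star Nutrient level below which oxidative cells cannot switch
#'   to glycolysis; must exceed `N_star`.
#' @param S_x,S_y,S_z Side lengths of the rectangular spatial domain
#'   (nondimensional); `S_z` is used only for 3D simulations.
#' @param mu_Po,mu_Pg Additional targeted-therapy death rates applied to
#'   `P_o` and `P_g` (zero when untreated); see [therapy_plan()].
#' @param live_floor Lower bound, as a fraction of the domain volume, on
#'   the tumour bulk (`P_o + P_g + P_d`) used to normalise the glycolytic
#'   share in the angiogenic nutrient coupling; prevents a vanishing
#'   remnant of glycolytic cells from sustaining full vascular support.
#'
#' @return An object of class `model_params` (a validated named list).
#' @seealso [load_params()], [unit_calibration()], [reaction_rhs()]
#' @examples
#' p <- mock_params()
#' p$S_W
#' d <- dnlef_params()
#' c(d$D_W, d$D_WI, d$S_W)
#' @export
model_params <- function(D_o = 0.01, D_g = 0.01, D_d = NULL,
                         D_W = 0.004, D_WI = 1, D_N = 100,
                         tau_o = 1, tau_g = 1, tau_og = 1 / 24, tau_go = 1,
                         alpha_W = 1, kappa_W = 5, kappa_WI = 1,
                         mu_o = 1, mu_g = 1, mu_d = 1,
                         mu_W = 2, mu_WI = 3, mu_N = 0.1,
                         S_W = 7.5, a = 1e-8, b = 1,
                         gamma_W = 1, gamma_N = 100,
                         nu_NG = 10, nu_NO = 10,
                         N_s = 2, alpha_N = 0.025,
                         W_star = 5, N_star = 0.07, N_g_star = 0.1,
                         S_x = 12, S_y = 12, S_z = 12,
                         mu_Po = 0, mu_Pg = 0, live_floor = 0.05) {
  if (is.null(D_d)) D_d <- D_o
  p <- list(D_o = D_o, D_g = D_g, D_d = D_d, D_W = D_W, D_WI = D_WI,
            D_N = D_N, tau_o = tau_o, tau_g = tau_g, tau_og = tau_og,
            tau_go = tau_go, alpha_W = alpha_W, kappa_W = kappa_W,
            kappa_WI = kappa_WI, mu_o = mu_o, mu_g = mu_g, mu_d = mu_d,
            mu_W = mu_W, mu_WI = mu_WI, mu_N = mu_N, S_W = S_W, a = a,
            b = b, gamma_W = gamma_W, gamma_N = gamma_N, nu_NG = nu_NG,
            nu_NO = nu_NO, N_s = N_s, alpha_N = alpha_N, W_star = W_star,
            N_star = N_star, N_g_star = N_g_star, S_x = S_x, S_y = S_y,
            S_z = S_z, mu_Po = mu_Po, mu_Pg = mu_Pg,
            live_floor = live_floor)
  class(p) <- "model_params"
  validate_params(p)
  p
}

#' @rdname model_params
#' @export
mock_params <- function() model_params()

#' @rdname model_params
#' @export
dnlef_params <- function() model_params(D_W = 0.008, D_WI = 1.5, S_W = 6.5)

validate_params <- function(p) {
  pos <- c("D_o", "D_g", "D_d", "D_W", "D_WI", "D_N", "tau_o", "tau_g",
           "tau_og", "tau_go", "alpha_W", "kappa_W", "kappa_WI", "mu_o",
           "mu_g", "mu_d", "mu_W", "mu_WI", "mu_N", "a", "b", "gamma_W",
           "gamma_N", "nu_NG", "nu_NO", "N_s", "W_star", "N_star",
           "N_g_star", "S_x", "S_y", "S_z")
  for (k in pos) {
    v <- p[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("parameter '", k, "' must be a single strictly positive number",
           call. = FALSE)
  }
  for (k in c("S_W", "mu_Po", "mu_Pg")) {
    v <- p[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("parameter '", k, "' must be a single nonnegative number",
           call. = FALSE)
  }
  if (p$D_W >= p$D_WI)
    stop("the Wnt inhibitor must diffuse longer range than Wnt: ",
         "require D_W < D_WI (got D_W = ", p$D_W, ", D_WI = ", p$D_WI, ")",
         call. = FALSE)
  if (p$alpha_N <= 0 || p$alpha_N > 1)
    stop("alpha_N must lie in (0, 1]", call. = FALSE)
  if (p$N_star >= p$N_g_star)
    stop("the death threshold N_star must be below the glycolysis-switch ",
         "floor N_g_star", call. = FALSE)
  if (!is.numeric(p$live_floor) || p$live_floor <= 0 || p$live_floor > 1)
    stop("live_floor must lie in (0, 1]", call. = FALSE)
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Wnt/metabolism model parameters (nondimensional)\n")
  nm <- setdiff(names(x), c("mu_Po", "mu_Pg"))
  v <- unlist(x[nm])
  print(noquote(formatC(v, digits = 6, width = 10)))
  if (x$mu_Po > 0 || x$mu_Pg > 0)
    cat(sprintf("therapy death rates: mu_Po = %g, mu_Pg = %g\n",
                x$mu_Po, x$mu_Pg))
  invisible(x)
}

#' Physical calibration of the nondimensional model
#'
#' The model is solved in nondimensional variables; one space unit is the
#' diffusion length of the Wnt inhibitor and one time unit the
#' characteristic proliferation time.  Matching simulated to stained
#' patterns fixes the length scale at about 40 um per unit and the time
#' scale at 1 day per unit.
#'
#' @param length_scale_um Micrometres per nondimensional length unit.
#' @param time_scale_days Days per nondimensional time unit.
#' @return An object of class `unit_calibration`.
#' @examples
#' cal <- unit_calibration()
#' 12 * cal$length_scale_um   # physical side of the default domain, um
#' @export
unit_calibration <- function(length_scale_um = 40, time_scale_days = 1) {
  stopifnot(is.numeric(length_scale_um), length(length_scale_um) == 1L,
            is.finite(length_scale_um), length_scale_um > 0,
            is.numeric(time_scale_days), length(time_scale_days) == 1L,
            is.finite(time_scale_days), time_scale_days > 0)
  structure(list(length_scale_um = length_scale_um,
                 time_scale_days = time_scale_days),
            class = "unit_calibration")
}

#' Read a model parameter set from a YAML key-value file
#'
#' Keys are named as the model symbols (`D_W`, `tau_og`, `W_star`, ...).
#' Unknown keys are rejected; keys missing from the file are filled from
#' the mock preset with a warning.  The two presets shipped with the
#' package are `system.file("params", "mock.yaml", package = "wntpattern")`
#' and `system.file("params", "dnlef.yaml", package = "wntpattern")`.
#'
#' @param path Path to a flat YAML file of `key: value` pairs.
#' @return A validated [model_params()] object.
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path,
                               call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(model_params))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown parameter key(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  missing <- setdiff(setdiff(known, "D_d"), names(vals))
  if (length(missing))
    warning("missing key(s) filled from the mock preset: ",
            paste(missing, collapse = ", "), call. = FALSE)
  do.call(model_params, vals)
}
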