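#' Homogeneous steady states of the reaction system
#'
#' Finds spatially uniform nonnegative states at which every reaction term
#' vanishes, using damped Newton iterations with the analytic Jacobian
#' from multiple starting points.  The global nutrient source is closed
#' with its uniform-state value (glycolytic share of the live population).
#' Multiple distinct roots are reported; the all-zero state is always a
#' root when `S_W = 0` and, depending on parameters, a strictly positive
#' glycolytic root may coexist (the patterned state grows out of it).
#'
#' @param params A [model_params()] object.
#' @param initial_guess Optional numeric vector of length 6
#'   (`P_o, P_g, P_d, W, W_I, N`) used as an additional start.
#' @param n_multistart Number of deterministic multistart points.
#' @param tol Residual infinity-norm required of a root.
#' @return An object of class `steady_state_set`: a list with `roots` (a
#'   data frame, one row per distinct root, with a `residual` column) and
#'   `best` (the root with the largest live mass, as a named list), or
#'   `best = NULL` when only no root was found.
#' @export
homogeneous_steady_state <- function(params, initial_guess = NULL,
                                     n_multistart = 24, tol = 1e-10) {
  p <- params
  V <- domain_volume(p, 2)
  fvec <- function(x) {
    st <- as.list(stats::setNames(x, c("P_o", "P_g", "P_d", "W", "W_I", "N")))
    r <- reaction_rhs(st, integral_Pg = min(st$P_g, 1) * V, params = p,
                      integral_live = (st$P_o + st$P_g + st$P_d) * V)
    unlist(r, use.names = FALSE)
  }
  jac <- function(x) {
    st <- as.list(stats::setNames(x, c("P_o", "P_g", "P_d", "W", "W_I", "N")))
    reaction_jacobian(st, p, include_global = TRUE)
  }
  newton <- function(x0) {
    x <- pmax(x0, 0)
    for (it in 1:80) {
      f <- tryCatch(fvec(x), error = function(e) NULL)
      if (is.null(f)) return(NULL)
      if (max(abs(f)) < tol) return(x)
      J <- jac(x)
      dx <- tryCatch(solve(J, -f), error = function(e) NULL)
      if (is.null(dx)) return(NULL)
      lambda <- 1
      repeat {
        xn <- pmax(x + lambda * dx, 0)
        fn <- tryCatch(fvec(xn), error = function(e) NULL)
        if (!is.null(fn) && (max(abs(fn)) < max(abs(f)) || lambda < 1e-6))
          break
        lambda <- lambda / 2
      }
      if (max(abs(xn - x)) < 1e-14 && max(abs(f)) >= tol) return(NULL)
      x <- xn
    }
    if (max(abs(fvec(x))) < tol) x else NULL
  }
  # deterministic multistart grid spanning the physically plausible ranges
  set.seed(1234)
  starts <- list(c(0, 0, 0, 0, 0, 0.5),
                 c(0.1, 0.9, 0, 6, 10, 0.5),
                 c(0.5, 0.5, 0, 5, 8, 0.3),
                 c(0.8, 0.2, 0, 2, 1, 0.2))
  for (i in seq_len(max(0, n_multistart - length(starts))))
    starts[[length(starts) + 1]] <-
      c(stats::runif(2, 0, 1), 0, stats::runif(1, 0, 10),
        stats::runif(1, 0, 15), stats::runif(1, 0.05, 1.5))
  if (!is.null(initial_guess)) starts <- c(list(initial_guess), starts)
  roots <- list()
  for (x0 in starts) {
    r <- newton(x0)
    if (is.null(r)) next
    key <- paste(signif(r, 6), collapse = "|")
    if (is.null(roots[[key]])) roots[[key]] <- r
  }
  if (!length(roots)) {
    return(structure(list(roots = NULL, best = NULL), class = "steady_state_set"))
  }
  df <- do.call(rbind, lapply(roots, function(r)
    data.frame(P_o = r[1], P_g = r[2], P_d = r[3], W = r[4], W_I = r[5],
               N = r[6], residual = max(abs(fvec(r))))))
  rownames(df) <- NULL
  df <- df[order(-(df$P_o + df$P_g)), , drop = FALSE]
  best <- as.list(df[1, 1:6])
  if (best$P_o + best$P_g <= 0) best <- as.list(df[1, 1:6])
  structure(list(roots = df, best = best), class = "steady_state_set")
}

#' @export
print.steady_state_set <- function(x, ...) {
  if (is.null(x$roots)) {
    cat("no nonnegative homogeneous steady state found\n")
  } else {
    cat("homogeneous steady states (one per row):\n")
    print(x$roots, digits = 4)
  }
  invisible(x)
}

#' Dispersion relation of the linearised model
#'
#' For each wavenumber `k`, assembles `J - k^2 D` (reaction Jacobian at
#' the uniform state plus diffusive damping, `D` the diagonal of field
#' diffusivities) and records the largest real part of its eigenvalues.
#' The global nutrient-source coupling acts only on the homogeneous mode
#' and is included only at `k = 0`.  The state is Turing (diffusion-
#' driven) unstable when it is stable at `k = 0` but some `k > 0` grows.
#'
#' @param params A [model_params()] object.
#' @param steady_state Named list/vector of the six uniform field values
#'   (typically `homogeneous_steady_state(params)$best`).
#' @param k_values Wavenumbers; default 400 points log-spaced on
#'   `[1e-2, 1e2]`.
#' @param calibration A [unit_calibration()] for the reported wavelength.
#' @return An object of class `dispersion_result`: `k`, `growth` (max real
#'   eigenvalue part per `k`), `growth0` (homogeneous mode), `k_max`,
#'   `wavelength` and `wavelength_um`, `unstable_band` (range of unstable
#'   `k`, or `NULL`), and flags `turing` and `non_turing_instability`.
#' @export
dispersion <- function(params, steady_state, k_values = NULL,
                       calibration = unit_calibration()) {
  p <- params
  if (is.null(k_values)) k_values <- pracma::logspace(-2, 2, 400)
  st <- as.list(steady_state)
  J <- reaction_jacobian(st, p, include_global = FALSE)
  J0 <- reaction_jacobian(st, p, include_global = TRUE)
  D <- diag(c(p$D_o, p$D_g, p$D_d, p$D_W, p$D_WI, p$D_N))
  growth0 <- max(Re(eigen(J0, only.values = TRUE)$values))
  growth <- vapply(k_values, function(k) {
    max(Re(eigen(J - k^2 * D, only.values = TRUE)$values))
  }, numeric(1))
  unstable <- which(growth > 0)
  band <- if (length(unstable)) range(k_values[unstable]) else NULL
  k_max <- if (length(unstable)) k_values[which.max(growth)] else NA_real_
  wl <- if (is.na(k_max) || k_max == 0) NA_real_ else 2 * pi / k_max
  structure(list(k = k_values, growth = growth, growth0 = growth0,
                 k_max = k_max, wavelength = wl,
                 wavelength_um = wl * calibration$length_scale_um,
                 unstable_band = band,
                 turing = growth0 <= 0 && !is.null(band),
                 non_turing_instability = growth0 > 0,
                 steady_state = st),
            class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  if (x$non_turing_instability)
    cat("unstable already at k = 0 (non-Turing instability)\n")
  if (is.null(x$unstable_band)) {
    cat("no diffusive instability: max growth", signif(max(x$growth), 4),
        "\n")
  } else {
    cat(sprintf("unstable band k in [%.4g, %.4g]; k_max = %.4g\n",
                x$unstable_band[1], x$unstable_band[2], x$k_max))
    cat(sprintf("predicted wavelength %.4g units = %.4g um\n",
                x$wavelength, x$wavelength_um))
    cat(if (x$turing) "Turing-unstable (stable homogeneous mode)\n"
        else "unstable, but not of Turing type\n")
  }
  invisible(x)
}

#' One-parameter scan of pattern phenotype
#'
#' For each value of a chosen parameter, runs a standardised 2D simulation
#' and the spot pipeline on the glycolytic field, reporting spot count,
#' mean spot area, background glycolytic level and the dispersion
#' prediction.  Values whose simulation produces no detectable spots are
#' flagged as `"no pattern"`.
#'
#' @param params Baseline [model_params()].
#' @param name Parameter to vary.
#' @param values Numeric vector of values.
#' @param grid,t_end,dt,seed Simulation settings for the standardised runs.
#' @param field Field whose spots are quantified (`"P_g"` or `"W"`).
#' @param calibration A [unit_calibration()].
#' @return A data frame with one row per value: value, pattern flag,
#'   k_max, n_spots, mean_area_um2, background_Pg, mean_nn_um.
#' @export
parameter_effect_scan <- function(params, name, values, grid = sim_grid(96),
                                  t_end = 80, dt = 2e-3, seed = 1,
                                  field = "P_g",
                                  calibration = unit_calibration()) {
  stopifnot(name %in% names(params))
  rows <- lapply(values, function(v) {
    p <- params
    p[[name]] <- v
    p <- tryCatch(validate_params(p), error = function(e) NULL)
    if (is.null(p))
      return(data.frame(value = v, pattern = FALSE, k_max = NA, n_spots = 0,
                        mean_area_um2 = NA, background_Pg = NA,
                        mean_nn_um = NA))
    res <- tryCatch(
      simulate_model(p, grid = grid, t_end = t_end, dt = dt, seed = seed,
                     conv_tol = 1e-5),
      error = function(e) NULL)
    if (is.null(res))
      return(data.frame(value = v, pattern = FALSE, k_max = NA, n_spots = 0,
                        mean_area_um2 = NA, background_Pg = NA,
                        mean_nn_um = NA))
    sp <- field_spots(res$state, field, calibration = calibration)
    st <- spot_statistics(sp)
    kmax <- tryCatch({
      hs <- homogeneous_steady_state(p)
      if (is.null(hs$best)) NA_real_ else
        dispersion(p, hs$best, calibration = calibration)$k_max
    }, error = function(e) NA_real_)
    bg <- background_level(res$state$P_g, sp)
    data.frame(value = v, pattern = st$n_spots >= 3, k_max = kmax,
               n_spots = st$n_spots,
               mean_area_um2 = st$mean_area_um2, background_Pg = bg,
               mean_nn_um = st$mean_nn_dist_um)
  })
  out <- do.call(rbind, rows)
  out$pattern[is.na(out$pattern)] <- FALSE
  out
}

# Median field level outside the detected spot hulls.
background_level <- function(field, spotset) {
  if (!nrow(spotset$spots)) return(stats::median(field))
  u <- rasterize_hulls(spotset)$union
  stats::median(field[!u])
}
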