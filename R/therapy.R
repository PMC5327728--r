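#' Targeted or combination therapy protocol
#'
#' A treatment plan combines selective cell killing (extra death rates on
#' the oxidative and/or glycolytic population), Wnt-pathway inhibition by
#' a tankyrase inhibitor such as XAV939 (scaling down the constitutive
#' Wnt production `S_W`, optionally with the compensatory linear increase
#' of the Wnt and Wnt-inhibitor diffusivities), and PDK inhibition by
#' dichloroacetate (raising the glycolysis-to-OXPHOS switch rate
#' `1/tau_go`).
#'
#' @param target `"none"`, `"P_o"`, `"P_g"` or `"both"`: which population
#'   the extra death rate applies to.
#' @param dose Added death rate (per time unit) for the targeted
#'   population(s).
#' @param duration Treatment duration (time units).
#' @param recovery Post-treatment follow-up duration under the original
#'   parameters.
#' @param xav_factor Multiplier on `S_W` in `(0, 1]`; 1 means no Wnt
#'   inhibition.
#' @param diffusion_scaling Increase `D_W` and `D_WI` linearly with the
#'   Wnt reduction (the upregulation of Wnt diffusers)?
#' @param dca_rate Treated value of the switch rate `1/tau_go`, or `NULL`
#'   to leave it at baseline.
#' @return An object of class `therapy_plan`.
#' @export
therapy_plan <- function(target = c("none", "P_o", "P_g", "both"),
                         dose = 0, duration = 0, recovery = 0,
                         xav_factor = 1, diffusion_scaling = TRUE,
                         dca_rate = NULL) {
  target <- match.arg(target)
  stopifnot(dose >= 0, duration >= 0, recovery >= 0,
            xav_factor > 0, xav_factor <= 1,
            is.null(dca_rate) || dca_rate >= 0)
  structure(list(target = target,
                 mu_Po = if (target %in% c("P_o", "both")) dose else 0,
                 mu_Pg = if (target %in% c("P_g", "both")) dose else 0,
                 duration = duration, recovery = recovery,
                 xav_factor = xav_factor,
                 diffusion_scaling = diffusion_scaling,
                 dca_rate = dca_rate), class = "therapy_plan")
}

# Slopes of the compensatory diffusivity increase, calibrated so that a
# Wnt reduction matching the dnLEF preset (S_W 7.5 -> 6.5, factor 6.5/7.5)
# reproduces the dnLEF diffusivities (D_W 0.004 -> 0.008, D_WI 1 -> 1.5).
XAV_DW_SLOPE <- (0.008 - 0.004) / (1 - 6.5 / 7.5)
XAV_DWI_SLOPE <- (1.5 - 1) / (1 - 6.5 / 7.5)

#' Parameter set under combined XAV939 / DCA treatment
#'
#' XAV939 scales `S_W` by `xav_factor` and (optionally) increases `D_W`
#' and `D_WI` linearly in the Wnt reduction `1 - xav_factor`, with slopes
#' calibrated on the dnLEF preset; DCA raises the glycolysis-to-OXPHOS
#' switch rate to `dca_rate` (i.e. `tau_go = 1/dca_rate`).
#'
#' @param params Baseline [model_params()].
#' @param xav_factor Multiplier on `S_W`, in `(0, 1]`.
#' @param dca_rate Treated `1/tau_go`, at least the baseline rate; `NULL`
#'   leaves switching untouched.
#' @param diffusion_scaling Apply the compensatory diffusivity increase?
#' @return A modified [model_params()] object.
#' @examples
#' p <- combo_params(mock_params(), xav_factor = 6.5 / 7.5)
#' c(p$S_W, p$D_W, p$D_WI)    # the dnLEF column
#' @export
combo_params <- function(params, xav_factor = 1, dca_rate = NULL,
                         diffusion_scaling = TRUE) {
  if (!is.numeric(xav_factor) || length(xav_factor) != 1L ||
      xav_factor <= 0 || xav_factor > 1)
    stop("xav_factor must lie in (0, 1]", call. = FALSE)
  base_rate <- 1 / params$tau_go
  if (!is.null(dca_rate)) {
    if (!is.numeric(dca_rate) || length(dca_rate) != 1L || dca_rate <= 0)
      stop("dca_rate must be a positive rate", call. = FALSE)
    if (dca_rate < base_rate)
      stop("dca_rate (", dca_rate, ") is below the untreated switch rate ",
           base_rate, call. = FALSE)
  }
  p <- params
  p$S_W <- xav_factor * p$S_W
  if (diffusion_scaling) {
    p$D_W <- p$D_W + XAV_DW_SLOPE * (1 - xav_factor)
    p$D_WI <- p$D_WI + XAV_DWI_SLOPE * (1 - xav_factor)
  }
  if (!is.null(dca_rate)) p$tau_go <- 1 / dca_rate
  validate_params(p)
  p
}

#' Apply a therapy plan to a patterned state
#'
#' Integrates the model from `state` with the plan's modifications active
#' for `plan$duration` time units, then under the original parameters for
#' `plan$recovery`.  Tumour size is the domain integral of `P_o + P_g`
#' relative to its pre-treatment value; the tumour counts as eradicated
#' when the relative size ends below `eradication_tol`.
#'
#' @param state A converged patterned `field_state` (a warning is issued
#'   if `converged` is `FALSE` on the supplied attribute or unknown).
#' @param params The untreated [model_params()] that produced `state`.
#' @param plan A [therapy_plan()].
#' @param dt Time step.
#' @param eradication_tol Relative-size threshold for eradication.
#' @param converged Set `FALSE` if the input state is known not to be at
#'   steady state (triggers a warning only).
#' @return An object of class `therapy_outcome`: a `series` data frame
#'   (time, relative `P_o`, `P_g` and total), `relative_size`,
#'   `eradicated`, and the final `state`.
#' @export
apply_therapy <- function(state, params, plan, dt = 1e-3,
                          eradication_tol = 1e-3, converged = TRUE) {
  stopifnot(inherits(state, "field_state"), inherits(plan, "therapy_plan"))
  if (!isTRUE(converged))
    warning("input state is not a converged patterned state")
  treated <- combo_params(params, plan$xav_factor, plan$dca_rate,
                          plan$diffusion_scaling)
  treated$mu_Po <- treated$mu_Po + plan$mu_Po
  treated$mu_Pg <- treated$mu_Pg + plan$mu_Pg
  cv <- grid_cell_volume(state$grid)
  base_o <- sum(state$P_o) * cv
  base_g <- sum(state$P_g) * cv
  base_tot <- base_o + base_g
  t0 <- state$time
  series <- data.frame(time = 0, rel_P_o = base_o / base_tot,
                       rel_P_g = base_g / base_tot, rel_total = 1)
  run_phase <- function(st, p, tlen) {
    if (tlen <= 0) return(list(state = st, diag = NULL))
    res <- simulate_model(p, grid = st$grid, t_end = st$time + tlen, dt = dt,
                          state = st, conv_tol = 0)
    list(state = res$state, diag = res$diagnostics)
  }
  ph1 <- run_phase(state, treated, plan$duration)
  ph2 <- run_phase(ph1$state, params, plan$recovery)
  for (d in list(ph1$diag, ph2$diag)) {
    if (is.null(d)) next
    series <- rbind(series, data.frame(
      time = d$time - t0,
      rel_P_o = d$total_P_o / base_tot,
      rel_P_g = d$total_P_g / base_tot,
      rel_total = (d$total_P_o + d$total_P_g) / base_tot))
  }
  final <- ph2$state
  rel <- tumor_burden(final) / base_tot
  structure(list(series = series, relative_size = rel,
                 eradicated = rel < eradication_tol,
                 plan = plan, state = final),
            class = "therapy_outcome")
}

#' @export
print.therapy_outcome <- function(x, ...) {
  p <- x$plan
  cat(sprintf("therapy_outcome: target %s, dose %.3g, duration %.3g + %.3g recovery\n",
              p$target, max(p$mu_Po, p$mu_Pg), p$duration, p$recovery))
  if (p$xav_factor < 1 || !is.null(p$dca_rate))
    cat(sprintf("  combo: xav_factor %.3g, dca_rate %s\n", p$xav_factor,
                if (is.null(p$dca_rate)) "baseline" else p$dca_rate))
  cat(sprintf("  final relative size %.5g; eradicated: %s\n",
              x$relative_size, x$eradicated))
  invisible(x)
}

#' Response surface of combined XAV939 / DCA treatment
#'
#' Runs [apply_therapy()] from a patterned state over a grid of XAV939
#' factors and DCA switch rates, recording the final relative tumour size
#' and, for each DCA rate, the largest `xav_factor` that still eradicates
#' the tumour (linear bracketing over the supplied grid).
#'
#' @param params Untreated [model_params()].
#' @param state The patterned starting `field_state`.
#' @param xav_factors,dca_rates Grids of treatment levels.
#' @param duration Treatment duration (time units).
#' @param dt Time step.
#' @param diffusion_scaling Passed to [combo_params()].
#' @return A list with `surface` (data frame: xav_factor, dca_rate,
#'   final_rel_size, eradicated, E_AB) and `boundary` (data frame:
#'   dca_rate, xav_eradication_boundary).
#' @export
therapy_surface <- function(params, state, xav_factors, dca_rates,
                            duration = 50, dt = 1e-3,
                            diffusion_scaling = TRUE) {
  stopifnot(length(xav_factors) > 0, length(dca_rates) > 0)
  rows <- list()
  for (dca in dca_rates) for (f in xav_factors) {
    plan <- therapy_plan("none", duration = duration, xav_factor = f,
                         diffusion_scaling = diffusion_scaling,
                         dca_rate = dca)
    out <- apply_therapy(state, params, plan, dt = dt)
    rows[[length(rows) + 1]] <- data.frame(
      xav_factor = f, dca_rate = dca,
      final_rel_size = out$relative_size, eradicated = out$eradicated,
      E_AB = min(max(1 - out$relative_size, 0), 1))
  }
  surface <- do.call(rbind, rows)
  boundary <- do.call(rbind, lapply(split(surface, surface$dca_rate),
    function(d) {
      er <- d$xav_factor[d$eradicated]
      data.frame(dca_rate = d$dca_rate[1],
                 xav_eradication_boundary =
                   if (length(er)) max(er) else NA_real_)
    }))
  rownames(boundary) <- NULL
  list(surface = surface, boundary = boundary)
}

#' Locate the XAV939 eradication boundary by bisection
#'
#' At a fixed DCA rate, bisects on the XAV939 factor for the largest Wnt
#' reduction multiplier at which the combination still eradicates the
#' patterned tumour.
#'
#' @param params Untreated [model_params()].
#' @param state Patterned starting `field_state`.
#' @param dca_rate Treated `1/tau_go`.
#' @param lower,upper Initial bracket on `xav_factor` (lower must
#'   eradicate, upper must not; checked and reported otherwise).
#' @param tol Bracket width at which bisection stops.
#' @param duration,dt Passed to [apply_therapy()].
#' @return A list with `xav_threshold` (midpoint of the final bracket),
#'   `bracket`, and `evaluations` (data frame of tested factors).
#' @export
eradication_threshold <- function(params, state, dca_rate = 12,
                                  lower = 0.55, upper = 0.95, tol = 0.05,
                                  duration = 50, dt = 1e-3) {
  evals <- list()
  test <- function(f) {
    plan <- therapy_plan("none", duration = duration, xav_factor = f,
                         dca_rate = dca_rate)
    out <- apply_therapy(state, params, plan, dt = dt)
    evals[[length(evals) + 1]] <<- data.frame(xav_factor = f,
                                              final_rel_size = out$relative_size,
                                              eradicated = out$eradicated)
    out$eradicated
  }
  if (!test(lower))
    stop("lower bracket xav_factor = ", lower, " does not eradicate",
         call. = FALSE)
  if (test(upper))
    stop("upper bracket xav_factor = ", upper, " already eradicates",
         call. = FALSE)
  lo <- lower; hi <- upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (test(mid)) lo <- mid else hi <- mid
  }
  list(xav_threshold = (lo + hi) / 2, bracket = c(lo, hi),
       evaluations = do.call(rbind, evals))
}

#' Bliss independence combination index
#'
#' For fractional effects (relative tumour-size reductions) of two single
#' agents and their combination, the Bliss expectation under independence
#' is `E_A + E_B - E_A * E_B` and the combination index is
#' `CI = (E_A + E_B - E_A * E_B) / E_AB`.  `CI < 1` indicates synergy.
#' When neither single agent has any effect and the combination does,
#' `CI = 0`; when `E_AB = 0` with nonzero single-agent effects the index
#' is undefined and reported as `NA`.
#'
#' @param effect_A,effect_B,effect_AB Fractional effects in `[0, 1]`.
#' @return An object of class `bliss_result`: the three effects, the
#'   independent expectation, `CI`, `defined`, and the `synergy` verdict
#'   (`CI < 1`; `NA` when undefined).
#' @examples
#' bliss_ci(0.2, 0.3, 0.9)    # CI = 0.44/0.9
#' bliss_ci(0, 0, 0.8)        # CI = 0: synergy revealed only in combination
#' @export
bliss_ci <- function(effect_A, effect_B, effect_AB) {
  for (e in list(effect_A, effect_B, effect_AB))
    if (!is.numeric(e) || length(e) != 1L || is.na(e) || e < 0 || e > 1)
      stop("effects must be single values in [0, 1]", call. = FALSE)
  expected <- effect_A + effect_B - effect_A * effect_B
  if (effect_AB == 0) {
    if (expected == 0) {
      ci <- 0; defined <- TRUE
    } else {
      ci <- NA_real_; defined <- FALSE
    }
  } else {
    ci <- expected / effect_AB
    defined <- TRUE
  }
  structure(list(E_A = effect_A, E_B = effect_B, E_AB = effect_AB,
                 expected_independent = expected, CI = ci,
                 defined = defined,
                 synergy = if (defined) ci < 1 else NA),
            class = "bliss_result")
}

#' @export
print.bliss_result <- function(x, ...) {
  cat(sprintf("Bliss: E_A = %.3g, E_B = %.3g, E_AB = %.3g\n",
              x$E_A, x$E_B, x$E_AB))
  if (!x$defined) {
    cat("combination index undefined (E_AB = 0 with single-agent effects)\n")
  } else {
    cat(sprintf("combination index CI = %.4g (%s)\n", x$CI,
                if (isTRUE(x$synergy)) "synergy" else "no synergy"))
  }
  invisible(x)
}
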