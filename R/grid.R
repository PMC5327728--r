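#' Rectangular simulation grid
#'
#' A uniform node-centred grid over the rectangular domain
#' `[0, S_x] x [0, S_y]` (times `[0, S_z]` in 3D) with `n` points per side
#' and spacing `length / (n - 1)` per axis.
#'
#' @param n Points per side; a single integer (used for every axis) or a
#'   vector of length `ndim`.
#' @param ndim Dimensionality, 2 or 3.
#' @param lengths Side lengths; defaults to `c(S_x, S_y[, S_z])` of the
#'   mock parameter set.
#' @return An object of class `sim_grid` with components `ndim`, `n`,
#'   `lengths`, `h` (spacings) and `coords` (list of axis coordinates).
#' @examples
#' g <- sim_grid(64)
#' g$h
#' @export
sim_grid <- function(n = 128, ndim = 2, lengths = NULL) {
  stopifnot(ndim %in% c(2, 3))
  if (is.null(lengths)) lengths <- rep(12, ndim)
  if (length(lengths) == 1L) lengths <- rep(lengths, ndim)
  stopifnot(length(lengths) == ndim, all(lengths > 0))
  if (length(n) == 1L) n <- rep(as.integer(n), ndim)
  n <- as.integer(n)
  stopifnot(length(n) == ndim, all(n >= 4L))
  h <- lengths / (n - 1)
  coords <- lapply(seq_len(ndim), function(d) seq(0, lengths[d], length.out = n[d]))
  structure(list(ndim = ndim, n = n, lengths = lengths, h = h,
                 coords = coords),
            class = "sim_grid")
}

#' @export
print.sim_grid <- function(x, ...) {
  cat(sprintf("%dD grid: %s points, domain %s, spacing %s\n", x$ndim,
              paste(x$n, collapse = " x "),
              paste(format(x$lengths), collapse = " x "),
              paste(format(x$h, digits = 4), collapse = " x ")))
  invisible(x)
}

#' Cell volume (area) of one grid node
#' @keywords internal
grid_cell_volume <- function(grid) prod(grid$h)

#' Distance of every grid node to the domain boundary
#' @keywords internal
grid_boundary_distance <- function(grid) {
  dmin <- function(d) pmin(grid$coords[[d]], grid$lengths[d] - grid$coords[[d]])
  if (grid$ndim == 2) {
    outer(dmin(1), dmin(2), pmin)
  } else {
    d1 <- dmin(1); d2 <- dmin(2); d3 <- dmin(3)
    a <- array(0, grid$n)
    for (k in seq_len(grid$n[3]))
      a[, , k] <- pmin(outer(d1, d2, pmin), d3[k])
    a
  }
}

new_field_state <- function(fields, time, seed, grid) {
  structure(c(fields, list(time = time, seed = seed, grid = grid)),
            class = "field_state")
}

field_names <- function() c("P_o", "P_g", "P_d", "W", "W_I", "N")

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf("field_state at t = %.4g (%s grid, seed %s)\n", x$time,
              paste(x$grid$n, collapse = "x"),
              if (is.null(x$seed)) "none" else x$seed))
  for (f in field_names())
    cat(sprintf("  %-4s range [%.4g, %.4g]\n", f, min(x[[f]]), max(x[[f]])))
  invisible(x)
}

#' Initial condition of the in vivo model
#'
#' Seeds a random distribution of glycolytic cells in a shell near the
#' domain boundary (reflecting implanted cells surviving close to the
#' vasculature), with small random Wnt and Wnt-inhibitor activity at the
#' same sites, a uniform high nutrient level `N = 1`, and no oxidative or
#' dead cells.  `P_g` values are drawn uniform on (0, 0.5) and `W`, `W_I`
#' uniform on (0, 0.1) inside the shell; the interior is exactly zero.
#' The same seed reproduces the state bit for bit.
#'
#' @param grid A [sim_grid()].
#' @param params A [model_params()] object.
#' @param seed Integer RNG seed.
#' @param shell_width Width of the boundary seeding shell in nondimensional
#'   units (default 1.2, i.e. 10 percent of the default domain side).
#' @return A `field_state`.
#' @export
initial_state <- function(grid, params, seed = 1, shell_width = 1.2) {
  stopifnot(inherits(grid, "sim_grid"))
  set.seed(seed)
  dist <- grid_boundary_distance(grid)
  shell <- dist < shell_width
  dims <- grid$n
  zero <- array(0, dims)
  P_g <- zero; W <- zero; W_I <- zero
  ns <- sum(shell)
  P_g[shell] <- stats::runif(ns, 0, 0.5)
  W[shell] <- stats::runif(ns, 0, 0.1)
  W_I[shell] <- stats::runif(ns, 0, 0.1)
  if (grid$ndim == 2) {
    P_g <- matrix(P_g, dims[1], dims[2])
    W <- matrix(W, dims[1], dims[2]); W_I <- matrix(W_I, dims[1], dims[2])
    zero <- matrix(0, dims[1], dims[2])
  }
  N <- zero + 1
  new_field_state(list(P_o = zero, P_g = P_g, P_d = zero,
                       W = W, W_I = W_I, N = N),
                  time = 0, seed = seed, grid = grid)
}

#' Central slice of a 3D field state
#'
#' Extracts the horizontal mid-plane (index `floor(n_z / 2) + 1` along the
#' third axis, i.e. the centre of the domain) of every field, the view
#' used to compare 3D simulations with stained tissue sections.  A 2D
#' input is returned unchanged with a warning.
#'
#' @param state A `field_state`.
#' @return A 2D `field_state`.
#' @export
central_slice <- function(state) {
  stopifnot(inherits(state, "field_state"))
  g <- state$grid
  if (g$ndim == 2) {
    warning("state is already 2D; returning it unchanged")
    return(state)
  }
  k <- floor(g$n[3] / 2) + 1L
  g2 <- sim_grid(g$n[1:2], ndim = 2, lengths = g$lengths[1:2])
  fields <- lapply(state[field_names()], function(a) a[, , k])
  new_field_state(fields, time = state$time, seed = state$seed, grid = g2)
}
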