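#' Specification for a synthetic spotted staining image
#'
#' Describes a ground-truthed synthetic micrograph: dark disks (stained
#' cell clusters) on a lighter background, with optional additive Gaussian
#' noise and a radial background gradient that emulates denser staining
#' toward the tissue edge.  Disk geometry is exact, so detection accuracy
#' can be measured against closed-form truth.
#'
#' @param size_px Image side length in pixels (square image).
#' @param pixel_size_um Physical pixel size.
#' @param n_spots Number of disks.
#' @param radius_mean_um,radius_sd_um Disk radius distribution (truncated
#'   normal, minimum one pixel).
#' @param min_spacing_um Minimum centre-to-centre spacing.
#' @param spot_intensity,background Gray levels of disks and background.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param gradient_amplitude Radial darkening of the background toward the
#'   image edge (gray levels).
#' @param seed RNG seed; the same spec is reproduced bit for bit.
#' @return An object of class `synthetic_image_spec`.
#' @export
synthetic_image_spec <- function(size_px = 256, pixel_size_um = 1,
                                 n_spots = 50, radius_mean_um = 8,
                                 radius_sd_um = 0, min_spacing_um = 25,
                                 spot_intensity = 60, background = 200,
                                 noise_sd = 0, gradient_amplitude = 0,
                                 seed = 1) {
  stopifnot(size_px >= 16, pixel_size_um > 0, n_spots >= 0,
            radius_mean_um > 0, radius_sd_um >= 0, min_spacing_um >= 0,
            spot_intensity >= 0, spot_intensity <= 255,
            background >= 0, background <= 255, noise_sd >= 0,
            gradient_amplitude >= 0)
  structure(as.list(environment()), class = "synthetic_image_spec")
}

place_centers <- function(n, size_px, spacing_px, rng_margin, max_tries = 1e4) {
  centers <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(centers) < n && tries < max_tries) {
    tries <- tries + 1
    cand <- stats::runif(2, rng_margin, size_px - 1 - rng_margin)
    if (nrow(centers) == 0 ||
        all(sqrt(rowSums(sweep(centers, 2, cand)^2)) >= spacing_px)) {
      centers <- rbind(centers, cand)
    }
  }
  if (nrow(centers) < n)
    stop("infeasible packing: placed ", nrow(centers), " of ", n,
         " spots in ", max_tries, " attempts", call. = FALSE)
  centers
}

draw_disks <- function(spec, centers, radii_px) {
  n <- spec$size_px
  img <- matrix(spec$background, n, n)
  if (spec$gradient_amplitude > 0) {
    cx <- (n - 1) / 2
    r <- sqrt(outer((seq_len(n) - 1 - cx)^2, (seq_len(n) - 1 - cx)^2, "+"))
    img <- img - spec$gradient_amplitude * r / max(r)
  }
  xs <- seq_len(n) - 1
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, 1]; cy <- centers[i, 2]; rad <- radii_px[i]
    xr <- max(1, floor(cx - rad)):min(n, ceiling(cx + rad) + 1)
    yr <- max(1, floor(cy - rad)):min(n, ceiling(cy + rad) + 1)
    d2 <- outer((xs[xr] - cx)^2, (xs[yr] - cy)^2, "+")
    sub <- img[xr, yr]
    sub[d2 <= rad^2] <- spec$spot_intensity
    img[xr, yr] <- sub
  }
  if (spec$noise_sd > 0)
    img <- img + matrix(stats::rnorm(n * n, 0, spec$noise_sd), n, n)
  pmin(pmax(img, 0), 255)
}

truth_table <- function(spec, centers, radii_px) {
  data.frame(id = seq_len(nrow(centers)),
             centroid_x = centers[, 1], centroid_y = centers[, 2],
             radius_um = radii_px * spec$pixel_size_um,
             area_um2 = pi * (radii_px * spec$pixel_size_um)^2)
}

#' Generate a synthetic spotted image with ground truth
#'
#' @param spec A [synthetic_image_spec()].
#' @return A list with `image` (matrix in `[0, 255]`, attribute
#'   `pixel_size_um`) and `truth` (data frame of true centres, radii and
#'   areas).
#' @export
make_spot_image <- function(spec) {
  stopifnot(inherits(spec, "synthetic_image_spec"))
  set.seed(spec$seed)
  rmean <- spec$radius_mean_um / spec$pixel_size_um
  margin <- rmean + 3 * spec$radius_sd_um / spec$pixel_size_um + 1
  centers <- place_centers(spec$n_spots, spec$size_px,
                           spec$min_spacing_um / spec$pixel_size_um, margin)
  radii <- pmax(1, stats::rnorm(spec$n_spots, rmean,
                                spec$radius_sd_um / spec$pixel_size_um))
  img <- draw_disks(spec, centers, radii)
  attr(img, "pixel_size_um") <- spec$pixel_size_um
  list(image = img, truth = truth_table(spec, centers, radii))
}

#' Generate a pair of synthetic serial-section images
#'
#' Image A is drawn from `spec`; image B reuses a fraction
#' `target_overlap` of A's spot centres (jittered by at most
#' `jitter_um`) and places the remaining spots independently, away from
#' the reused ones.  The realised shared fraction is returned as the
#' construction truth.
#'
#' @param spec A [synthetic_image_spec()].
#' @param target_overlap Fraction of spots shared between the sections.
#' @param jitter_um Maximum per-axis jitter of shared centres (about one
#'   cell diameter by default).
#' @return A list with `imageA`, `imageB`, `truthA`, `truthB` and
#'   `true_overlap` (realised shared fraction).
#' @export
make_serial_pair <- function(spec, target_overlap, jitter_um = 7) {
  stopifnot(inherits(spec, "synthetic_image_spec"),
            target_overlap >= 0, target_overlap <= 1)
  set.seed(spec$seed)
  rmean <- spec$radius_mean_um / spec$pixel_size_um
  margin <- rmean + 3 * spec$radius_sd_um / spec$pixel_size_um + 1
  spacing <- spec$min_spacing_um / spec$pixel_size_um
  centersA <- place_centers(spec$n_spots, spec$size_px, spacing, margin)
  radiiA <- pmax(1, stats::rnorm(spec$n_spots, rmean,
                                 spec$radius_sd_um / spec$pixel_size_um))
  n_shared <- round(target_overlap * spec$n_spots)
  shared <- if (n_shared > 0) {
    jit <- matrix(stats::runif(2 * n_shared, -jitter_um, jitter_um) /
                    spec$pixel_size_um, n_shared, 2)
    pmin(pmax(centersA[seq_len(n_shared), , drop = FALSE] + jit, margin),
         spec$size_px - 1 - margin)
  } else matrix(numeric(0), 0, 2)
  centersB <- shared
  tries <- 0
  while (nrow(centersB) < spec$n_spots && tries < 2e4) {
    tries <- tries + 1
    cand <- stats::runif(2, margin, spec$size_px - 1 - margin)
    ok_spacing <- nrow(centersB) == 0 ||
      all(sqrt(rowSums(sweep(centersB, 2, cand)^2)) >= spacing)
    # keep fresh spots away from every A spot so they cannot overlap it
    clear_of_A <- all(sqrt(rowSums(sweep(centersA, 2, cand)^2)) >=
                        2 * rmean + 2)
    if (ok_spacing && clear_of_A) centersB <- rbind(centersB, cand)
  }
  if (nrow(centersB) < spec$n_spots)
    stop("infeasible packing for section B: placed ", nrow(centersB),
         " of ", spec$n_spots, call. = FALSE)
  radiiB <- pmax(1, stats::rnorm(spec$n_spots, rmean,
                                 spec$radius_sd_um / spec$pixel_size_um))
  imgA <- draw_disks(spec, centersA, radiiA)
  imgB <- draw_disks(spec, centersB, radiiB)
  attr(imgA, "pixel_size_um") <- spec$pixel_size_um
  attr(imgB, "pixel_size_um") <- spec$pixel_size_um
  list(imageA = imgA, imageB = imgB,
       truthA = truth_table(spec, centersA, radiiA),
       truthB = truth_table(spec, centersB, radiiB),
       true_overlap = n_shared / max(spec$n_spots, 1))
}

#' Analytic field fixtures for solver and pipeline tests
#'
#' `"uniform"` sets every field to a constant; `"gaussian_lattice"` places
#' a square lattice of Gaussian bumps of known width in `P_g` and `W`
#' over a low background; `"boundary_shell"` is the model's own seeded
#' initial condition (shared generator with [initial_state()]).
#'
#' @param kind One of `"uniform"`, `"gaussian_lattice"`, `"boundary_shell"`.
#' @param grid A [sim_grid()] (2D).
#' @param params A [model_params()] object (used by `"boundary_shell"`).
#' @param seed RNG seed (used by `"boundary_shell"`).
#' @param n_bumps Number of bumps per side for the lattice.
#' @param bump_sigma Bump width (nondimensional length units).
#' @param value Constant value for `"uniform"`.
#' @return A `field_state`.
#' @export
make_field_fixture <- function(kind, grid, params = mock_params(), seed = 1,
                               n_bumps = 4, bump_sigma = 0.3, value = 0.5) {
  stopifnot(inherits(grid, "sim_grid"), grid$ndim == 2)
  kinds <- c("uniform", "gaussian_lattice", "boundary_shell")
  if (!kind %in% kinds)
    stop("unknown fixture kind '", kind, "'; use one of ",
         paste(kinds, collapse = ", "), call. = FALSE)
  if (kind == "boundary_shell") return(initial_state(grid, params, seed))
  n <- grid$n
  zero <- matrix(0, n[1], n[2])
  if (kind == "uniform") {
    fields <- list(P_o = zero + value, P_g = zero + value, P_d = zero,
                   W = zero + value, W_I = zero + value, N = zero + 1)
  } else {
    cx <- seq(0, grid$lengths[1], length.out = n_bumps + 2)[2:(n_bumps + 1)]
    cy <- seq(0, grid$lengths[2], length.out = n_bumps + 2)[2:(n_bumps + 1)]
    x <- grid$coords[[1]]; y <- grid$coords[[2]]
    bump <- zero
    for (a in cx) for (b in cy)
      bump <- bump + outer(exp(-(x - a)^2 / (2 * bump_sigma^2)),
                           exp(-(y - b)^2 / (2 * bump_sigma^2)))
    fields <- list(P_o = pmax(0.5 - bump, 0), P_g = bump, P_d = zero,
                   W = 10 * bump, W_I = bump, N = zero + 1)
  }
  new_field_state(fields, time = 0, seed = seed, grid = grid)
}
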