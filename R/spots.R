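#' Binarize a grayscale staining image
#'
#' Thresholds a grayscale image into a staining mask and applies the noise
#' filter (median smoothing followed by removal of connected components
#' below `min_area_px`) used throughout the spot pipeline.  Intensities
#' are on the usual 0-255 scale; set `invert = TRUE` for dark-stain-on-
#' light-background images (DAB-stained sections and the synthetic images
#' of [make_spot_image()]), in which case staining intensity is
#' `255 - value`.
#'
#' @param image Numeric matrix of grayscale intensities in `[0, 255]`.
#' @param method `"otsu"` (threshold maximising between-class variance) or
#'   `"manual"` (use `threshold`).
#' @param threshold Manual threshold on staining intensity; staining
#'   strictly above it is in the mask.
#' @param invert Treat dark pixels as stained?
#' @param median_radius Radius (px) of the median noise filter; 0 disables.
#' @param min_area_px Components smaller than this are removed; 0 disables.
#' @return A logical matrix with attributes `threshold` (on the staining
#'   scale used) and `settings`.  A warning is issued if the mask is empty.
#' @export
binarize <- function(image, method = c("otsu", "manual"), threshold = NULL,
                     invert = FALSE, median_radius = 1, min_area_px = 4) {
  method <- match.arg(method)
  if (!is.matrix(image) || !is.numeric(image) || any(!is.finite(image)))
    stop("image must be a finite numeric matrix", call. = FALSE)
  stain <- if (invert) 255 - image else image
  if (method == "otsu") {
    rng <- range(stain)
    if (rng[1] == rng[2]) {
      threshold <- rng[1]   # degenerate constant image: empty mask below
    } else {
      sc <- (stain - rng[1]) / (rng[2] - rng[1])
      threshold <- EBImage::otsu(EBImage::Image(sc)) * (rng[2] - rng[1]) +
        rng[1]
    }
  } else if (is.null(threshold)) {
    stop("manual method requires a threshold", call. = FALSE)
  }
  mask <- stain > threshold
  if (median_radius > 0 && any(mask)) {
    sm <- EBImage::medianFilter(EBImage::Image(mask * 1), median_radius)
    mask <- EBImage::imageData(sm) > 0.5
  }
  if (min_area_px > 0 && any(mask)) {
    lab <- EBImage::bwlabel(mask)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_area_px)
    mask <- matrix(lab %in% keep, nrow(image), ncol(image))
  }
  if (!any(mask)) warning("binarize: empty mask")
  structure(mask, threshold = threshold,
            settings = list(method = method, invert = invert,
                            median_radius = median_radius,
                            min_area_px = min_area_px))
}

#' Convert a simulated field to an 8-bit image
#'
#' Linearly rescales a field to `[0, 255]` so the spot pipeline can be
#' applied to simulation output exactly as to micrographs.  The pixel size
#' is the physical grid spacing, `length_scale_um * S / n`.
#'
#' @param field Numeric matrix (one field of a 2D `field_state`).
#' @param grid The [sim_grid()] the field lives on.
#' @param calibration A [unit_calibration()].
#' @return A numeric matrix in `[0, 255]` with attribute `pixel_size_um`.
#' @export
field_to_image <- function(field, grid, calibration = unit_calibration()) {
  stopifnot(is.matrix(field))
  rng <- range(field)
  img <- if (rng[1] == rng[2]) field * 0 else
    (field - rng[1]) / (rng[2] - rng[1]) * 255
  px <- calibration$length_scale_um * grid$lengths[1] / grid$n[1]
  attr(img, "pixel_size_um") <- px
  img
}

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Minimum distance between two point sets (rows are points).
min_cross_dist <- function(a, b) {
  # chunked to bound memory; point sets here are contour samples
  best <- Inf
  for (i in seq(1, nrow(a), by = 256)) {
    ii <- i:min(i + 255, nrow(a))
    d2 <- outer(a[ii, 1], b[, 1], "-")^2 + outer(a[ii, 2], b[, 2], "-")^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}

#' Detect and group spots in a binary mask
#'
#' Connected components at least `min_area_px` large become candidate
#' spots; components whose boundary-to-boundary distance is at most
#' `group_distance_px` are merged into a single spot (mirroring the
#' convex-hull grouping of stained cell clusters that sit close to one
#' another).  Each spot carries its contour(s), the convex hull of the
#' merged pixels, the pixel centroid and areas in both pixels and um^2.
#' Coordinates are pixel-centred, 0-based, row = x, column = y; hull
#' polygons are closed.
#'
#' @param mask Logical matrix (from [binarize()] or ground truth).
#' @param min_area_px Minimum component area in pixels.
#' @param group_distance_px Boundary gap at or below which components are
#'   merged; `NULL` uses 15 um (about two cell diameters) divided by
#'   `pixel_size_um`.
#' @param pixel_size_um Physical pixel size.
#' @return An object of class `spot_set`: a list with `spots` (data frame
#'   of id, centroid_x, centroid_y, area_px, area_um2, hull_area_px,
#'   n_components), `hulls` (list of closed polygons), `contours` (list of
#'   per-component contour polygons), `pixel_size_um`, `dim` and
#'   `settings`.
#' @export
detect_spots <- function(mask, min_area_px = 4, group_distance_px = NULL,
                         pixel_size_um = 1) {
  stopifnot(is.matrix(mask), is.logical(mask) || all(mask %in% c(0, 1)))
  stopifnot(pixel_size_um > 0)
  if (is.null(group_distance_px)) group_distance_px <- 15 / pixel_size_um
  mask <- mask > 0
  empty <- function() {
    structure(list(spots = data.frame(id = integer(), centroid_x = numeric(),
                                      centroid_y = numeric(),
                                      area_px = numeric(), area_um2 = numeric(),
                                      hull_area_px = numeric(),
                                      n_components = integer()),
                   hulls = list(), contours = list(),
                   pixel_size_um = pixel_size_um, dim = dim(mask),
                   settings = list(min_area_px = min_area_px,
                                   group_distance_px = group_distance_px)),
              class = "spot_set")
  }
  if (!any(mask)) return(empty())
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area_px)
  if (!length(keep)) return(empty())
  contours <- EBImage::ocontour(EBImage::Image(lab))
  contours <- contours[keep]
  ncomp <- length(keep)
  # component centroids and radii for the cheap pre-filter
  cent <- t(vapply(contours, colMeans, numeric(2)))
  rad <- vapply(seq_len(ncomp), function(i) {
    sqrt(max(rowSums(sweep(contours[[i]], 2, cent[i, ])^2)))
  }, numeric(1))
  parent <- seq_len(ncomp)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (ncomp > 1) {
    for (i in 1:(ncomp - 1)) for (j in (i + 1):ncomp) {
      lower <- sqrt(sum((cent[i, ] - cent[j, ])^2)) - rad[i] - rad[j]
      if (lower > group_distance_px) next
      if (min_cross_dist(contours[[i]], contours[[j]]) <= group_distance_px) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(ncomp), find, integer(1))
  groups <- split(seq_len(ncomp), roots)
  px_area <- pixel_size_um^2
  rows <- list(); hulls <- list(); conts <- list()
  for (gi in seq_along(groups)) {
    members <- groups[[gi]]
    labs <- keep[members]
    idx <- which(matrix(lab %in% labs, nrow(lab), ncol(lab)), arr.ind = TRUE)
    pix <- cbind(idx[, 1] - 1, idx[, 2] - 1)   # 0-based pixel centres
    ctr <- colMeans(pix)
    hull_i <- grDevices::chull(pix)
    hull <- pix[c(hull_i, hull_i[1]), , drop = FALSE]
    rows[[gi]] <- data.frame(id = gi, centroid_x = ctr[1], centroid_y = ctr[2],
                             area_px = nrow(pix),
                             area_um2 = nrow(pix) * px_area,
                             hull_area_px = max(polygon_area(hull), nrow(pix)),
                             n_components = length(members))
    hulls[[gi]] <- hull
    conts[[gi]] <- lapply(contours[members], function(m) m)
  }
  structure(list(spots = do.call(rbind, rows), hulls = hulls,
                 contours = conts, pixel_size_um = pixel_size_um,
                 dim = dim(mask),
                 settings = list(min_area_px = min_area_px,
                                 group_distance_px = group_distance_px)),
            class = "spot_set")
}

#' @export
print.spot_set <- function(x, ...) {
  cat(sprintf("spot_set: %d spots on a %d x %d image (%.3g um/px)\n",
              nrow(x$spots), x$dim[1], x$dim[2], x$pixel_size_um))
  if (nrow(x$spots))
    cat(sprintf("  mean area %.4g um^2 (range %.4g-%.4g)\n",
                mean(x$spots$area_um2), min(x$spots$area_um2),
                max(x$spots$area_um2)))
  invisible(x)
}

#' Summary statistics of a spot set
#'
#' Mean and standard deviation of spot areas, nearest-neighbour centroid
#' distances, the fraction of tissue covered by spots, and the mean number
#' of cells per spot (mean area divided by a nominal single-cell area).
#' Nearest-neighbour distances are centroid-to-centroid and are reported
#' as absent when fewer than two spots exist.
#'
#' @param spotset A `spot_set` from [detect_spots()].
#' @param tissue_mask Logical matrix defining the tissue region (the
#'   denominator of the area fraction); `NULL` means the whole image.
#' @param cell_area_um2 Nominal cell area; the default 44 um^2 makes a
#'   309 um^2 stained cluster about 7 cells.
#' @return An object of class `spot_stats`: n_spots, mean/sd area (um^2),
#'   mean/sd nearest-neighbour distance (um; `NA` when n_spots < 2), area
#'   fraction, and mean cells per spot.
#' @export
spot_statistics <- function(spotset, tissue_mask = NULL, cell_area_um2 = 44) {
  stopifnot(inherits(spotset, "spot_set"), cell_area_um2 > 0)
  sp <- spotset$spots
  n <- nrow(sp)
  tissue_px <- if (is.null(tissue_mask)) prod(spotset$dim) else {
    stopifnot(all(dim(tissue_mask) == spotset$dim))
    sum(tissue_mask > 0)
  }
  nn <- rep(NA_real_, n)
  if (n >= 2) {
    d <- as.matrix(stats::dist(sp[, c("centroid_x", "centroid_y")]))
    diag(d) <- Inf
    nn <- apply(d, 1, min) * spotset$pixel_size_um
  }
  structure(list(
    n_spots = n,
    mean_area_um2 = if (n) mean(sp$area_um2) else NA_real_,
    sd_area_um2 = if (n >= 2) stats::sd(sp$area_um2) else NA_real_,
    mean_nn_dist_um = if (n >= 2) mean(nn) else NA_real_,
    sd_nn_dist_um = if (n >= 3) stats::sd(nn) else NA_real_,
    area_fraction = sum(sp$area_px) / tissue_px,
    mean_cells_per_spot = if (n) mean(sp$area_um2) / cell_area_um2
                          else NA_real_,
    nn_dist_um = nn), class = "spot_stats")
}

#' @export
print.spot_stats <- function(x, ...) {
  cat(sprintf("spot_stats: n = %d\n", x$n_spots))
  cat(sprintf("  area: %.4g +/- %.4g um^2\n", x$mean_area_um2, x$sd_area_um2))
  cat(sprintf("  NN distance: %.4g +/- %.4g um\n", x$mean_nn_dist_um,
              x$sd_nn_dist_um))
  cat(sprintf("  area fraction %.3g; ~%.3g cells/spot\n", x$area_fraction,
              x$mean_cells_per_spot))
  invisible(x)
}

# Rasterize the hull polygons of a spot set; returns a list with the union
# mask and one mask index set per spot.
rasterize_hulls <- function(spotset) {
  d <- spotset$dim
  union <- matrix(FALSE, d[1], d[2])
  per_spot <- vector("list", length(spotset$hulls))
  for (i in seq_along(spotset$hulls)) {
    h <- spotset$hulls[[i]]
    xr <- floor(min(h[, 1])):ceiling(max(h[, 1]))
    yr <- floor(min(h[, 2])):ceiling(max(h[, 2]))
    xr <- xr[xr >= 0 & xr < d[1]]; yr <- yr[yr >= 0 & yr < d[2]]
    gx <- rep(xr, times = length(yr)); gy <- rep(yr, each = length(xr))
    inside <- pracma::inpolygon(gx, gy, h[, 1], h[, 2], boundary = TRUE)
    sel <- cbind(gx[inside] + 1, gy[inside] + 1)
    per_spot[[i]] <- sel
    union[sel] <- TRUE
  }
  list(union = union, per_spot = per_spot)
}

#' Overlap between two spot sets on serial sections
#'
#' Counts, in each direction, the percentage of spots whose convex hull
#' intersects (by at least one pixel) a hull of the other set, and the
#' fraction of tissue covered by the mutual intersection of the two hull
#' maps, treating corresponding pixels of the two images as the same
#' physical location.
#'
#' @param spotsA,spotsB `spot_set` objects on congruent pixel grids.
#' @param tissue_mask Optional logical tissue mask (denominator of the
#'   joint-area fraction).
#' @return An object of class `overlap_result`: `pct_A_overlapping_B`,
#'   `pct_B_overlapping_A`, `joint_area_fraction`, and the settings of
#'   both inputs.
#' @export
overlap_analysis <- function(spotsA, spotsB, tissue_mask = NULL) {
  stopifnot(inherits(spotsA, "spot_set"), inherits(spotsB, "spot_set"))
  if (!all(spotsA$dim == spotsB$dim))
    stop("spot sets live on different pixel grids", call. = FALSE)
  ra <- rasterize_hulls(spotsA)
  rb <- rasterize_hulls(spotsB)
  pct <- function(per_spot, other_union) {
    if (!length(per_spot)) return(NA_real_)
    hit <- vapply(per_spot, function(sel) any(other_union[sel]), logical(1))
    100 * mean(hit)
  }
  tissue_px <- if (is.null(tissue_mask)) prod(spotsA$dim) else sum(tissue_mask > 0)
  structure(list(
    pct_A_overlapping_B = pct(ra$per_spot, rb$union),
    pct_B_overlapping_A = pct(rb$per_spot, ra$union),
    joint_area_fraction = sum(ra$union & rb$union) / tissue_px,
    settings = list(A = spotsA$settings, B = spotsB$settings)),
    class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap: %.1f%% of A spots touch B; %.1f%% of B touch A\n",
              x$pct_A_overlapping_B, x$pct_B_overlapping_A))
  cat(sprintf("joint hull area fraction of tissue: %.3g\n",
              x$joint_area_fraction))
  invisible(x)
}

#' Stratified association between two staining masks
#'
#' Tests whether staining in two congruent masks co-occurs at the pixel
#' level with a Cochran-Mantel-Haenszel test (no continuity correction)
#' over a 2 x 2 table per stratum.  By default pixels are stratified into
#' concentric bands by distance to the tissue boundary, which partially
#' absorbs the radial gradient in spot density.  Strata with a zero
#' margin are dropped with a warning.
#'
#' @param maskA,maskB Logical matrices of identical dimension.
#' @param strata Optional integer/factor matrix of the same dimension
#'   assigning each pixel to a stratum; `NULL` builds `n_bands` distance
#'   bands.
#' @param n_bands Number of concentric bands for the default strata.
#' @param tissue_mask Optional logical matrix restricting the analysis.
#' @return A list with `statistic` (CMH chi-square), `p_value`, `df` and
#'   `tables` (the per-stratum 2 x 2 tables).
#' @export
cmh_association <- function(maskA, maskB, strata = NULL, n_bands = 4,
                            tissue_mask = NULL) {
  stopifnot(is.matrix(maskA), is.matrix(maskB), all(dim(maskA) == dim(maskB)))
  if (is.null(strata)) {
    n <- dim(maskA)
    dx <- pmin(seq_len(n[1]) - 1, n[1] - seq_len(n[1]))
    dy <- pmin(seq_len(n[2]) - 1, n[2] - seq_len(n[2]))
    dist <- outer(dx, dy, pmin)
    br <- stats::quantile(dist, probs = seq(0, 1, length.out = n_bands + 1))
    br <- unique(br); br[1] <- -Inf; br[length(br)] <- Inf
    strata <- matrix(cut(dist, br, labels = FALSE), n[1], n[2])
  }
  stopifnot(all(dim(strata) == dim(maskA)))
  sel <- if (is.null(tissue_mask)) TRUE else as.vector(tissue_mask > 0)
  a <- factor(as.vector(maskA)[sel], levels = c(FALSE, TRUE))
  b <- factor(as.vector(maskB)[sel], levels = c(FALSE, TRUE))
  s <- as.vector(strata)[sel]
  tab <- table(A = a, B = b, stratum = s)
  ok <- vapply(seq_len(dim(tab)[3]), function(k) {
    t2 <- tab[, , k]
    all(rowSums(t2) > 0) && all(colSums(t2) > 0)
  }, logical(1))
  if (!all(ok)) {
    warning("dropping ", sum(!ok), " stratum/strata with a zero margin")
    tab <- tab[, , ok, drop = FALSE]
  }
  if (dim(tab)[3] == 0) stop("no usable strata", call. = FALSE)
  if (dim(tab)[3] >= 2) {
    mh <- stats::mantelhaen.test(tab, correct = FALSE)
    stat <- unname(mh$statistic); pval <- mh$p.value
  } else {
    # single stratum: the CMH statistic in closed form,
    # (a - E[a])^2 / Var(a) with the hypergeometric variance
    t2 <- matrix(as.numeric(tab[, , 1]), 2, 2)
    n <- sum(t2)
    e <- sum(t2[2, ]) * sum(t2[, 2]) / n
    v <- prod(rowSums(t2)) * prod(colSums(t2)) / (n^2 * (n - 1))
    stat <- (t2[2, 2] - e)^2 / v
    pval <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  list(statistic = stat, p_value = pval, df = 1,
       tables = lapply(seq_len(dim(tab)[3]), function(k) tab[, , k]))
}

#' Write a spot set to CSV
#'
#' One row per spot: id, centroid coordinates (px), area in px and um^2,
#' and nearest-neighbour distance in um.
#'
#' @param spotset A `spot_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spots_csv <- function(spotset, path) {
  st <- spot_statistics(spotset)
  df <- spotset$spots[, c("id", "centroid_x", "centroid_y", "area_px",
                          "area_um2")]
  df$nn_dist_um <- st$nn_dist_um
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Detect spots directly in a simulated field
#'
#' Convenience pipeline for simulation output: rescales one field of a 2D
#' `field_state` to an 8-bit image ([field_to_image()]), thresholds it
#' ([binarize()], Otsu by default; simulated spots are bright, so no
#' inversion), and runs [detect_spots()] with the physical pixel size
#' implied by the grid and calibration.
#'
#' Otsu assumes a bimodal histogram; on spike-like fields (narrow intense
#' maxima over a broad background, as the Wnt field is) it can land above
#' almost every pixel and leave a degenerate, empty mask.  When Otsu
#' detection returns no spots, the pipeline falls back to an upper-
#' quantile threshold (`fallback_quantile`, default the top 5 percent of
#' pixels) and records the fallback in the returned settings.
#'
#' @param state A 2D `field_state` (use [central_slice()] for 3D runs).
#' @param field Field name, e.g. `"P_g"` or `"W"`.
#' @param calibration A [unit_calibration()].
#' @param method,threshold Passed to [binarize()].
#' @param median_radius,min_area_px Noise-filter settings; simulated fields
#'   are noise-free, so the median filter is off by default here.
#' @param group_distance_um Hull-grouping distance in um.
#' @param fallback_quantile Upper-quantile threshold used when Otsu
#'   detection is degenerate; `NULL` disables the fallback.
#' @return A `spot_set`.
#' @export
field_spots <- function(state, field = "P_g",
                        calibration = unit_calibration(),
                        method = "otsu", threshold = NULL,
                        median_radius = 0, min_area_px = 4,
                        group_distance_um = 15, fallback_quantile = 0.95) {
  stopifnot(inherits(state, "field_state"), field %in% field_names())
  grid <- state$grid
  if (grid$ndim != 2)
    stop("field_spots needs a 2D state; apply central_slice() first",
         call. = FALSE)
  img <- field_to_image(state[[field]], grid, calibration)
  px <- attr(img, "pixel_size_um")
  mask <- suppressWarnings(
    binarize(img, method = method, threshold = threshold,
             invert = FALSE, median_radius = median_radius,
             min_area_px = min_area_px))
  sp <- detect_spots(mask, min_area_px = min_area_px,
                     group_distance_px = group_distance_um / px,
                     pixel_size_um = px)
  if (nrow(sp$spots) == 0 && method == "otsu" &&
      !is.null(fallback_quantile)) {
    qthr <- stats::quantile(img, fallback_quantile)
    if (qthr < max(img)) {
      mask <- suppressWarnings(
        binarize(img, method = "manual", threshold = qthr,
                 invert = FALSE, median_radius = median_radius,
                 min_area_px = min_area_px))
      sp <- detect_spots(mask, min_area_px = min_area_px,
                         group_distance_px = group_distance_um / px,
                         pixel_size_um = px)
      sp$settings$threshold <- "quantile_fallback"
      sp$settings$fallback_quantile <- fallback_quantile
    }
  }
  sp
}
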