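# Exhaustive-search oracle for Otsu: maximise between-class variance over
# all candidate thresholds.
otsu_oracle <- function(values) {
  cand <- sort(unique(values))
  cand <- (cand[-1] + cand[-length(cand)]) / 2
  best <- cand[1]; best_v <- -Inf
  for (t in cand) {
    lo <- values[values <= t]; hi <- values[values > t]
    v <- length(lo) * length(hi) / length(values)^2 *
      (mean(hi) - mean(lo))^2
    if (v > best_v) { best_v <- v; best <- t }
  }
  best
}

disk_mask <- function(n, centers, radius) {
  m <- matrix(FALSE, n, n)
  xs <- seq_len(n) - 1
  for (i in seq_len(nrow(centers))) {
    d2 <- outer((xs - centers[i, 1])^2, (xs - centers[i, 2])^2, "+")
    m <- m | (d2 <= radius^2)
  }
  m
}

test_that("manual thresholding separates two-level images exactly", {
  img <- matrix(50, 64, 64)
  truth <- disk_mask(64, cbind(c(15, 45), c(20, 44)), 6)
  img[truth] <- 200
  mask <- binarize(img, "manual", threshold = 125, invert = TRUE,
                   median_radius = 0, min_area_px = 0)
  expect_identical(unclass(mask) > 0, !truth)  # inverted polarity
  mask2 <- binarize(img, "manual", threshold = 125, median_radius = 0,
                    min_area_px = 0)
  expect_identical(unclass(mask2) > 0, truth)
  # constant image above threshold -> empty mask with a warning
  expect_warning(m3 <- binarize(matrix(10, 8, 8), "manual", threshold = 20),
                 "empty mask")
  expect_false(any(m3))
})

test_that("Otsu recovers a threshold between the modes of a bimodal image", {
  set.seed(11)
  img <- matrix(rnorm(64 * 64, 80, 8), 64, 64)
  truth <- disk_mask(64, cbind(c(20, 48, 30), c(18, 40, 52)), 7)
  img[truth] <- rnorm(sum(truth), 190, 8)
  img <- pmin(pmax(img, 0), 255)
  mask <- binarize(img, "otsu", median_radius = 0, min_area_px = 0)
  th <- attr(mask, "threshold")
  expect_gt(th, 100); expect_lt(th, 170)
  # against the exhaustive between-class-variance oracle (coarse grid of
  # the same image to keep the oracle cheap)
  sub <- img[seq(1, 64, by = 2), seq(1, 64, by = 2)]
  th_oracle <- otsu_oracle(round(as.vector(sub)))
  mask_sub <- binarize(sub, "otsu", median_radius = 0, min_area_px = 0)
  expect_equal(attr(mask_sub, "threshold"), th_oracle, tolerance = 12)
})

test_that("noise filtering removes speckle but keeps real spots", {
  set.seed(5)
  img <- matrix(60, 96, 96)
  truth <- disk_mask(96, cbind(c(30, 70), c(30, 66)), 8)
  img[truth] <- 200
  # salt noise: isolated bright pixels
  idx <- sample(96 * 96, 60)
  img[idx] <- pmax(img[idx], 210)
  mask <- binarize(img, "manual", threshold = 130, median_radius = 1,
                   min_area_px = 5)
  sp <- detect_spots(mask, min_area_px = 5, group_distance_px = 2)
  expect_equal(nrow(sp$spots), 2)
})

test_that("grouping merges components by boundary distance", {
  # two disks of radius 5 with a 3 px boundary gap
  n <- 48
  m <- disk_mask(n, cbind(c(17, 30), c(24, 24)), 5)
  sp1 <- detect_spots(m, min_area_px = 1, group_distance_px = 4)
  expect_equal(nrow(sp1$spots), 1)
  expect_equal(sp1$spots$n_components, 2)
  sp2 <- detect_spots(m, min_area_px = 1, group_distance_px = 2)
  expect_equal(nrow(sp2$spots), 2)
  # the merged hull contains both centroids
  h <- sp1$hulls[[1]]
  expect_true(pracma::inpolygon(17, 24, h[, 1], h[, 2], boundary = TRUE))
  expect_true(pracma::inpolygon(30, 24, h[, 1], h[, 2], boundary = TRUE))
  # hull area at least the pixel area
  expect_gte(sp1$spots$hull_area_px, sp1$spots$area_px * 0.99)
})

test_that("noiseless synthetic disks are recovered with exact count", {
  spec <- synthetic_image_spec(size_px = 256, n_spots = 50,
                               radius_mean_um = 8, min_spacing_um = 25,
                               seed = 42)
  out <- make_spot_image(spec)
  mask <- binarize(out$image, "otsu", invert = TRUE, median_radius = 0,
                   min_area_px = 4)
  sp <- detect_spots(mask, min_area_px = 4, group_distance_px = 1,
                     pixel_size_um = 1)
  expect_equal(nrow(sp$spots), 50)
  expect_equal(mean(sp$spots$area_um2), pi * 64, tolerance = 0.05)
  st <- spot_statistics(sp)
  expect_equal(st$n_spots, 50)
  # every detected centroid matches a true centre within a pixel
  d <- as.matrix(pracma::distmat(
    as.matrix(sp$spots[, c("centroid_x", "centroid_y")]),
    as.matrix(out$truth[, c("centroid_x", "centroid_y")])))
  expect_lt(max(apply(d, 1, min)), 1)
})

test_that("spot statistics follow their definitions on a square lattice", {
  n <- 96; d <- 30
  centers <- as.matrix(expand.grid(c(25, 25 + d), c(25, 25 + d)))
  m <- disk_mask(n, centers, 6)
  sp <- detect_spots(m, min_area_px = 1, group_distance_px = 1,
                     pixel_size_um = 2)
  st <- spot_statistics(sp, cell_area_um2 = 44)
  expect_equal(st$n_spots, 4)
  expect_equal(st$mean_nn_dist_um, d * 2, tolerance = 0.02)
  expect_equal(st$sd_nn_dist_um, 0, tolerance = 1e-6)
  expect_equal(st$area_fraction, 4 * sum(disk_mask(n, centers[1, , drop = FALSE], 6)) / n^2,
               tolerance = 0.05)
  expect_equal(st$mean_cells_per_spot, st$mean_area_um2 / 44)
  # single spot: NN absent, area fraction still defined
  one <- detect_spots(disk_mask(48, cbind(24, 24), 6), min_area_px = 1,
                      group_distance_px = 1, pixel_size_um = 1)
  s1 <- spot_statistics(one)
  expect_true(is.na(s1$mean_nn_dist_um))
  expect_gt(s1$area_fraction, 0)
})

test_that("statistics are scale-equivariant in the pixel size", {
  m <- disk_mask(64, cbind(c(18, 44), c(20, 44)), 5)
  a <- spot_statistics(detect_spots(m, group_distance_px = 1, pixel_size_um = 1))
  b <- spot_statistics(detect_spots(m, group_distance_px = 1, pixel_size_um = 2))
  expect_equal(b$mean_nn_dist_um, 2 * a$mean_nn_dist_um)
  expect_equal(b$mean_area_um2, 4 * a$mean_area_um2)
  expect_equal(b$area_fraction, a$area_fraction)
})

test_that("detection is idempotent on its own rasterized hulls", {
  spec <- synthetic_image_spec(size_px = 200, n_spots = 12,
                               radius_mean_um = 7, min_spacing_um = 40,
                               seed = 3)
  out <- make_spot_image(spec)
  mask <- binarize(out$image, "otsu", invert = TRUE, median_radius = 0)
  sp <- detect_spots(mask, min_area_px = 4, group_distance_px = 5)
  rast <- wntpattern:::rasterize_hulls(sp)$union
  sp2 <- detect_spots(rast, min_area_px = 4, group_distance_px = 5)
  expect_equal(nrow(sp2$spots), nrow(sp$spots))
})

test_that("overlap analysis matches construction on serial pairs", {
  spec <- synthetic_image_spec(size_px = 220, n_spots = 16,
                               radius_mean_um = 7, min_spacing_um = 36,
                               seed = 9)
  pair <- make_serial_pair(spec, target_overlap = 1, jitter_um = 0)
  spots_of <- function(img) {
    detect_spots(binarize(img, "otsu", invert = TRUE, median_radius = 0),
                 min_area_px = 4, group_distance_px = 1)
  }
  spA <- spots_of(pair$imageA); spB <- spots_of(pair$imageB)
  ov <- overlap_analysis(spA, spB)
  expect_equal(ov$pct_A_overlapping_B, 100)
  expect_equal(ov$pct_B_overlapping_A, 100)
  expect_gt(ov$joint_area_fraction, 0)
  # disjoint sets
  pair0 <- make_serial_pair(spec, target_overlap = 0)
  ov0 <- overlap_analysis(spots_of(pair0$imageA), spots_of(pair0$imageB))
  expect_equal(ov0$pct_A_overlapping_B, 0)
  expect_equal(ov0$joint_area_fraction, 0)
  # identical sets trivially overlap fully
  ovI <- overlap_analysis(spA, spA)
  expect_equal(ovI$pct_A_overlapping_B, 100)
  # mismatched grids are a hard error
  small <- spots_of(pair$imageA[1:100, 1:100])
  expect_error(overlap_analysis(spA, small), "different pixel grids")
})

test_that("intermediate target overlap is recovered within five points", {
  spec <- synthetic_image_spec(size_px = 256, n_spots = 20,
                               radius_mean_um = 7, min_spacing_um = 34,
                               seed = 1)
  meas <- vapply(1:10, function(s) {
    sp <- spec; sp$seed <- s
    pair <- make_serial_pair(sp, target_overlap = 0.7, jitter_um = 5)
    f <- function(img)
      detect_spots(binarize(img, "otsu", invert = TRUE, median_radius = 0),
                   min_area_px = 4, group_distance_px = 1)
    overlap_analysis(f(pair$imageA), f(pair$imageB))$pct_A_overlapping_B
  }, numeric(1))
  expect_lt(abs(mean(meas) - 70), 5)
})

test_that("CMH association detects identity and matches the 2x2 oracle", {
  set.seed(21)
  m <- matrix(runif(60 * 60) < 0.25, 60, 60)
  res <- cmh_association(m, m)
  expect_lt(res$p_value, 1e-10)
  # single stratum equals the closed-form CMH statistic of the pooled table
  strata1 <- matrix(1L, 60, 60)
  set.seed(22)
  b <- matrix(runif(60 * 60) < 0.3, 60, 60)
  res1 <- cmh_association(m, b, strata = strata1)
  tab <- matrix(as.numeric(table(factor(m, c(FALSE, TRUE)),
                                 factor(b, c(FALSE, TRUE)))), 2, 2)
  n <- sum(tab)
  e11 <- sum(tab[2, ]) * sum(tab[, 2]) / n
  v11 <- sum(tab[2, ]) * sum(tab[1, ]) * sum(tab[, 2]) * sum(tab[, 1]) /
    (n^2 * (n - 1))
  expect_equal(res1$statistic, (tab[2, 2] - e11)^2 / v11, tolerance = 1e-10)
})

test_that("strata with zero margins are dropped with a warning", {
  set.seed(8)
  m <- matrix(runif(40 * 40) < 0.3, 40, 40)
  b <- matrix(runif(40 * 40) < 0.3, 40, 40)
  strata <- matrix(1L, 40, 40)
  strata[1:10, ] <- 2L
  m[strata == 2] <- FALSE    # stratum 2 has a zero margin in A
  expect_warning(res <- cmh_association(m, b, strata = strata),
                 "zero margin")
  expect_true(is.finite(res$statistic))
})

test_that("spot CSV export carries one row per spot", {
  m <- disk_mask(64, cbind(c(18, 44), c(20, 44)), 5)
  sp <- detect_spots(m, group_distance_px = 1, pixel_size_um = 1.5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_spots_csv(sp, f)
  df <- read.csv(f)
  expect_equal(nrow(df), 2)
  expect_named(df, c("id", "centroid_x", "centroid_y", "area_px",
                     "area_um2", "nn_dist_um"))
})
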