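# independent Otsu oracle: exhaustive threshold search maximizing
# between-class variance directly on the value vector
otsu_oracle <- function(vals) {
  u <- sort(unique(vals))
  cand <- (u[-1] + u[-length(u)]) / 2
  bcv <- vapply(cand, function(t) {
    lo <- vals[vals <= t]; hi <- vals[vals > t]
    length(lo) * length(hi) / length(vals)^2 * (mean(hi) - mean(lo))^2
  }, 0)
  cand[which.max(bcv)]
}

test_that("the myocardial mask matches an exhaustive Otsu oracle", {
  # bimodal slice: background 1, shell 10, equal counts
  s <- matrix(c(rep(1, 128), rep(10, 128)), 16, 16)
  m <- myocardium_mask(s)
  thr <- otsu_oracle(as.vector(s))
  expect_gt(thr, 1); expect_lt(thr, 10)
  expect_identical(m, s > thr)
  expect_identical(m, s == 10)
  # annulus with faint blood pool: mask covers the shell, excludes the pool
  sl <- annulus_slice(n = 32, inner_r = 6, outer_r = 11, hot = 10, bg = 1)
  ctr <- (dim(sl) + 1) / 2
  r <- sqrt(outer((seq_len(32) - ctr[1])^2, (seq_len(32) - ctr[2])^2, "+"))
  sl[r < 6] <- 3  # blood pool
  m <- myocardium_mask(sl)
  thr <- otsu_oracle(as.vector(sl))
  expect_identical(m, sl > thr)
  expect_true(all(m[sl == 10]))
  expect_false(any(m[sl == 3]))
  expect_error(myocardium_mask(matrix(5, 8, 8)), "unprocessable")
})

test_that("manual mask override validates shape and content", {
  sl <- annulus_slice()
  auto <- myocardium_mask(sl)
  same <- override_mask(sl, auto)
  expect_equal(unclass(same), unclass(auto), ignore_attr = TRUE)
  expect_error(override_mask(sl, matrix(TRUE, 4, 4)), "shape")
  expect_error(override_mask(sl, matrix(FALSE, nrow(sl), ncol(sl))),
               "empty")
})

test_that("ring extraction reproduces a perfect annulus", {
  sl <- annulus_slice(n = 32, inner_r = 8, outer_r = 12, hot = 10)
  ctr <- (dim(sl) + 1) / 2
  ring <- extract_ring(sl, sl > 0, ctr)
  expect_false(any(ring$open))
  expect_equal(ring$samples$value, rep(10, 360))
  expect_true(all(ring$samples$radius >= 8 - 0.5))
  expect_true(all(ring$samples$radius <= 12 + 0.5))
})

test_that("the ring centre update equals the brute-force max-point centroid", {
  sl <- annulus_slice(n = 40, center = c(20.5, 20.5), inner_r = 8,
                      outer_r = 12, hot = 10)
  start <- c(22.5, 20.5)
  ring <- extract_ring(sl, sl > 0, start)
  # oracle: dense independent search of the maximizing point on each ray
  oracle_pts <- t(vapply(0:359, function(a) {
    th <- a * pi / 180
    d <- c(sin(th), -cos(th))
    rr <- seq(0, 25, by = 0.5)
    px <- start[1] + rr * d[1]; py <- start[2] + rr * d[2]
    ok <- px >= 1 & px <= 40 & py >= 1 & py <= 40
    ok[ok] <- sl[cbind(round(px[ok]), round(py[ok]))] > 0
    v <- rep(-Inf, length(rr))
    v[ok] <- pracma::interp2(1:40, 1:40, sl, py[ok], px[ok])
    r_best <- rr[which.max(v)]
    c(start[1] + r_best * d[1], start[2] + r_best * d[2])
  }, numeric(2)))
  expect_equal(ring$center_updated, colMeans(oracle_pts), tolerance = 1e-9)
  # one recalculation moves the centre toward the true centre
  expect_lt(abs(ring$center_updated[1] - 20.5), abs(start[1] - 20.5))
  # a second pass from the updated centre converges within half a pixel
  ring2 <- extract_ring(sl, sl > 0, ring$center_updated)
  expect_true(all(abs(ring2$center_updated - c(20.5, 20.5)) < 0.5))
})

test_that("a hot pixel captures only its own ray", {
  sl <- annulus_slice(n = 41, center = c(21, 21), inner_r = 8, outer_r = 12,
                      hot = 10)
  # hot pixel on the 90-degree ray at radius 10 (a sampled lattice point)
  sl[31, 21] <- 20
  ang_hp <- 90
  ring <- extract_ring(sl, sl > 0, c(21, 21))
  expect_equal(ring$samples$value[ring$samples$angle == ang_hp], 20)
  expect_equal(ring$samples$radius[ring$samples$angle == ang_hp], 10)
  far <- abs(((ring$samples$angle - ang_hp + 180) %% 360) - 180) > 15
  expect_true(all(abs(ring$samples$value[far] - 10) < 1e-9))
})

test_that("excluding a papillary-muscle blob restores the ring radii", {
  sl <- annulus_slice(n = 41, center = c(21, 21), inner_r = 9, outer_r = 13,
                      hot = 10)
  blob <- sl
  # papillary blob inside the cavity toward +y, i.e. at 180 degrees in the
  # map convention (0 = anterior = -y)
  blob[19:23, 25:27] <- 10
  mask_auto <- blob > 5
  ring_blob <- extract_ring(blob, mask_auto, c(21, 21))
  corrected <- override_mask(blob, mask_auto & (sl > 0))
  ring_fix <- extract_ring(blob, corrected, c(21, 21))
  sel <- ring_fix$samples$angle %in% 170:190
  expect_true(all(ring_fix$samples$radius[sel] >= 9 - 0.5))
  expect_true(any(ring_blob$samples$radius[sel] < 9 - 0.5))
})

test_that("a uniform phantom yields a uniform polar map", {
  ph <- generate_phantom(small_spec())
  res <- process_scan(ph$pet, ph$ct, smoothing_mm = 0)
  pm <- res$polar_map
  u <- ph$spec$base_suv
  expect_true(all(abs(pm$values[pm$valid] - u) / u < 0.05))
})

test_that("an apical defect appears in the central radial bins", {
  ph <- generate_phantom(small_spec(apical = 0.5))
  res <- process_scan(ph$pet, ph$ct, smoothing_mm = 0)
  pm <- res$polar_map
  u <- ph$spec$base_suv
  central <- pm$values[, seq_len(pm$n_cap)]
  expect_lt(mean(central[pm$valid[, seq_len(pm$n_cap)]]), 0.62 * u)
  basal <- pm$values[, ncol(pm$values) - (0:2)]
  expect_gt(mean(basal[pm$valid[, ncol(pm$values) - (0:2)]]), 0.9 * u)
})

test_that("septal basal extension is truncated to the lateral limit", {
  base <- generate_phantom(small_spec())
  ext <- generate_phantom(small_spec(septal_base_extension_mm = 10))
  rb <- process_scan(base$pet, base$ct, smoothing_mm = 0)$polar_map
  re <- process_scan(ext$pet, ext$ct, smoothing_mm = 0)$polar_map
  expect_equal(re$n_rings, rb$n_rings)
})

test_that("segment aggregation partitions the polar map exactly", {
  set.seed(21)
  vals <- matrix(runif(360 * 24, 1, 9), 360, 24)
  vals[sample(length(vals), 200)] <- NA  # invalid cells
  pm <- make_polar_map(vals, n_cap = 6, n_rings = 18)
  segs <- aggregate_segments(pm)
  expect_equal(sum(segs$n_cells), sum(pm$valid))
  expect_true(all(pm$segment[pm$valid] %in% 1:17))
  # count-weighted means reproduce the direct sum over valid cells
  expect_equal(sum(segs$n_cells * segs$suv_mean),
               sum(pm$values[pm$valid]), tolerance = 1e-12)
  expect_true(all(segs$suv_max >= segs$suv_mean))
})

test_that("prescribed segment patterns are reported exactly", {
  vals <- matrix(1, 360, 24)
  pm <- make_polar_map(vals, n_cap = 6, n_rings = 18)
  segs <- aggregate_segments(pm)
  expect_equal(segs$suv_mean, rep(1, 17))
  expect_equal(segs$suv_max, rep(1, 17))
  pm2 <- pm
  pm2$values[pm2$segment %in% c(2, 3, 8, 9)] <- 0.8
  segs2 <- aggregate_segments(pm2)
  expect_equal(segs2$suv_mean[c(2, 3, 8, 9)], rep(0.8, 4))
  expect_equal(segs2$suv_mean[-c(2, 3, 8, 9)], rep(1, 13))
})

test_that("rotating the uptake sectors by 60 degrees permutes the segments", {
  base <- generate_phantom(small_spec(septal = 0.7))
  rot <- generate_phantom(small_spec(septal = 0.7, sector_rotation_deg = 60))
  sb <- process_scan(base$pet, base$ct, smoothing_mm = 0)$segments
  sr <- process_scan(rot$pet, rot$ct, smoothing_mm = 0)$segments
  # basal and mid rings shift by one 60-degree position
  perm <- c(6, 1, 2, 3, 4, 5)
  expect_equal(sr$suv_mean[1:6], sb$suv_mean[1:6][perm], tolerance = 0.05)
  expect_equal(sr$suv_mean[7:12], sb$suv_mean[7:12][perm], tolerance = 0.05)
})

test_that("scaling the map scales segment statistics linearly", {
  set.seed(5)
  vals <- matrix(runif(360 * 24, 1, 9), 360, 24)
  pm <- make_polar_map(vals, n_cap = 6, n_rings = 18)
  segs1 <- aggregate_segments(pm)
  pm$values <- 3 * pm$values
  segs3 <- aggregate_segments(pm)
  expect_equal(segs3$suv_mean, 3 * segs1$suv_mean, tolerance = 1e-12)
  expect_equal(segs3$suv_max, 3 * segs1$suv_max, tolerance = 1e-12)
})

test_that("polar map CSV export is tidy and complete", {
  vals <- matrix(runif(360 * 12), 360, 12)
  pm <- make_polar_map(vals, n_cap = 3, n_rings = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  export_polar_map(pm, path)
  df <- read.csv(path)
  expect_equal(nrow(df), 360 * 12)
  expect_setequal(names(df),
                  c("angle_bin", "radial_bin", "value", "valid", "segment_id"))
  expect_equal(sum(df$valid), sum(pm$valid))
})
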