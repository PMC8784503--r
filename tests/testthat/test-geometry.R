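test_that("an ellipsoid enclosing the whole volume keeps every voxel", {
  set.seed(3)
  vol <- scalar_volume(array(runif(6 * 7 * 8), c(6, 7, 8)), c(4, 4, 5),
                       unit = "SUV")
  big <- ellipsoid_voi(c(12, 14, 20), c(1e3, 1e3, 1e3))
  mv <- apply_voi(vol, big)
  expect_true(all(mv$mask))
  expect_equal(mv$values, vol$values)
})

test_that("the VOI excludes a hot tumour next to the heart", {
  tum <- list(center_mm = NULL, radius_mm = 12, suv = 12)
  ph0 <- generate_phantom(small_spec())
  tum$center_mm <- ph0$truth$center_mm + c(85, 0, 0)
  ph <- generate_phantom(small_spec(tumor = tum))
  expect_gt(max(ph$pet$values), 10)  # tumour present in the volume
  mv <- apply_voi(ph$pet, ellipsoid_voi(ph$truth$center_mm, c(55, 55, 75)))
  expect_equal(max(mv$values[mv$mask]), ph$spec$base_suv)
})

test_that("VOI application errors on empty intersection and is idempotent", {
  vol <- scalar_volume(array(1, c(8, 8, 8)), c(4, 4, 4), unit = "SUV")
  outside <- ellipsoid_voi(c(1e4, 1e4, 1e4), c(10, 10, 10))
  expect_error(apply_voi(vol, outside), "intersect")
  voi <- ellipsoid_voi(c(14, 14, 14), c(10, 12, 9), euler_deg = c(0, 0, 20))
  once <- apply_voi(vol, voi)
  twice <- apply_voi(once, voi)
  expect_equal(sum(once$mask), sum(twice$mask))
  expect_equal(once$values[once$mask], twice$values[twice$mask])
})

test_that("identity rotation reproduces the input subvolume", {
  ph <- generate_phantom(small_spec())
  mv <- apply_voi(ph$pet, ellipsoid_voi(ph$truth$center_mm, c(55, 55, 75)))
  olv <- orient_lv(mv, 0, 0)
  expect_s3_class(olv, "oriented_lv")
  # integral of retained uptake conserved within 2%
  int_in <- sum(mv$values[mv$mask]) * prod(mv$spacing)
  int_out <- sum(olv$values[olv$mask]) * prod(olv$spacing)
  expect_lt(abs(int_out - int_in) / int_in, 0.02)
  expect_error(orient_lv(mv, 95, 0), "degrees")
})

test_that("rotation conserves retained uptake within 2% on phantoms", {
  ph <- generate_phantom(small_spec())
  mv <- apply_voi(ph$pet, ellipsoid_voi(ph$truth$center_mm, c(55, 55, 75)))
  int_in <- sum(mv$values[mv$mask]) * prod(mv$spacing)
  for (ang in list(c(20, 0), c(0, -25), c(15, 10))) {
    olv <- orient_lv(mv, ang[1], ang[2])
    int_out <- sum(olv$values[olv$mask]) * prod(olv$spacing)
    expect_lt(abs(int_out - int_in) / int_in, 0.02)
  }
})

test_that("principal-axis estimation recovers the pre-rotation within 2 degrees", {
  for (ang in list(c(15, 10), c(-25, 30), c(30, -20))) {
    ph <- generate_phantom(small_spec(rotation_deg = ang))
    suv <- denoise_poisson(ph$pet, 2)
    mv <- apply_voi(suv, ellipsoid_voi(ph$truth$center_mm, c(55, 55, 75)))
    th <- estimate_orientation(mv)
    # the estimated reorientation must map the true long axis onto z
    M <- cardpet:::rot_y(th[2]) %*% cardpet:::rot_x(th[1])
    aligned <- M %*% ph$truth$long_axis
    err_deg <- acos(min(1, abs(aligned[3]))) * 180 / pi
    expect_lt(err_deg, 2)
  }
})

test_that("successive rotations about one axis compose additively", {
  ph <- generate_phantom(small_spec())
  mv <- apply_voi(ph$pet, ellipsoid_voi(ph$truth$center_mm, c(55, 55, 75)))
  one <- orient_lv(mv, 35, 0)
  two <- orient_lv(orient_lv(mv, 15, 0), 20, 0)
  axis_of <- function(olv) {
    sm <- cardpet:::shell_mask3d(olv)
    idx <- which(sm, arr.ind = TRUE)
    pts <- sweep(sweep(idx - 1, 2, olv$spacing, "*"), 2, olv$origin, "+")
    v <- prcomp(pts)$rotation[, 1]
    v * sign(v[3])
  }
  dot <- sum(axis_of(one) * axis_of(two))
  expect_lt(acos(min(1, abs(dot))) * 180 / pi, 2)
  int1 <- sum(one$values[one$mask]) * prod(one$spacing)
  int2 <- sum(two$values[two$mask]) * prod(two$spacing)
  expect_lt(abs(int1 - int2) / int1, 0.03)
})
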