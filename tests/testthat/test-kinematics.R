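test_that("elementary rotations follow the documented conventions", {
  expect_equal(rotation_matrix("Z", 0), diag(3))
  expect_equal(drop(rotation_matrix("Z", 90) %*% c(1, 0, 0)), c(0, 1, 0),
               tolerance = 1e-12)
  expect_equal(rotation_matrix("X", 360), diag(3), tolerance = 1e-9)
  for (ax in c("X", "Y", "Z")) {
    R <- rotation_matrix(ax, 37.3)
    expect_true(is_rotation_matrix(R))
  }
  expect_error(rotation_matrix("Z", NaN), "finite")
})

test_that("horizontal angle matches its closed form and round-trips", {
  expect_equal(horizontal_angle(0, 57), 0)
  expect_equal(horizontal_angle(42, 0), 42)
  expect_equal(horizontal_angle(30, 60), 14.4775121859, tolerance = 1e-9)
  for (th in c(-80, -25, 10, 63)) {
    for (ph in c(-60, 0, 45)) {
      expect_equal(azimuth_from_horizontal(horizontal_angle(th, ph), ph), th,
                   tolerance = 1e-9)
    }
  }
})

test_that("Listing torsion is the radian half-product in degrees", {
  expect_equal(listing_torsion(0, 33), 0)
  expect_equal(listing_torsion(-12, 0), 0)
  expect_equal(listing_torsion(20, 10), 1.745329252, tolerance = 1e-8)
})

test_that("Fick compose/decompose round-trips across the pose space", {
  expect_equal(unclass(fick_decompose(diag(3)))[1:3],
               list(yaw = 0, pitch = 0, torsion = 0))
  expect_equal(fick_decompose(rotation_matrix("Z", 30))$yaw, 30,
               tolerance = 1e-9)
  set.seed(42)
  for (i in 1:200) {
    y <- runif(1, -89, 89); p <- runif(1, -89, 89); g <- runif(1, -179, 179)
    ang <- fick_decompose(fick_rotation(y, p, g))
    expect_equal(c(ang$yaw, ang$pitch, ang$torsion), c(y, p, g),
                 tolerance = 1e-9)
  }
  expect_error(fick_decompose(fick_rotation(0, 90, 0)), "gimbal")
})

test_that("head updates move the head as commanded and stay orthonormal", {
  u <- update_head_rotation(diag(3), 0, 0)
  expect_equal(u$head, c(1, 0, 0))
  u <- update_head_rotation(diag(3), 10, 0)
  expect_equal(u$angles$azimuth, 10, tolerance = 1e-9)
  expect_equal(u$angles$elevation, 0, tolerance = 1e-9)
  u <- update_head_rotation(diag(3), 0, 10)
  expect_equal(u$angles$elevation, 10, tolerance = 1e-9)
  set.seed(7)
  R <- diag(3)
  for (i in 1:1000) {
    R <- update_head_rotation(R, runif(1, -20, 20), runif(1, -20, 20))$R
  }
  expect_lt(max(abs(crossprod(R) - diag(3))), 1e-6)
  expect_error(update_head_rotation(matrix(1, 3, 3), 0, 0), "rotation")
})

test_that("head pose with roll composes and decomposes consistently", {
  p <- head_pose_with_roll(0, 0, 0)
  expect_equal(p$R, diag(3))
  expect_equal(p$angles$torsion, 0)
  p <- head_pose_with_roll(0, 0, 25)
  expect_equal(p$R, rotation_matrix("X", 25), tolerance = 1e-12)
  set.seed(11)
  for (i in 1:50) {
    y <- runif(1, -80, 80); ph <- runif(1, -80, 80); g <- runif(1, -40, 40)
    p <- head_pose_with_roll(y, ph, g)
    d <- fick_decompose(p$R)
    expect_equal(c(d$yaw, d$pitch, d$torsion),
                 c(y, ph, p$angles$torsion), tolerance = 1e-9)
  }
})

test_that("targets transform into head coordinates as the conventions say", {
  s <- direction_vector(25, -10)
  tic <- target_in_head_coords(diag(3), s)
  expect_equal(tic$angles$azimuth, 25, tolerance = 1e-9)
  expect_equal(tic$angles$elevation, -10, tolerance = 1e-9)
  ## aligned head: angles (0, 0) whatever the torsion
  p <- head_pose_with_roll(0, 0, 33)
  tic <- target_in_head_coords(t(p$R), c(1, 0, 0))
  expect_equal(abs(tic$angles$alpha), 0, tolerance = 1e-9)
  ## a pure +90 deg (left-ear-up) roll maps elevation into leftward azimuth
  p <- head_pose_with_roll(0, 0, 90)
  tic <- target_in_head_coords(t(p$R), direction_vector(0, 10))
  expect_equal(tic$angles$alpha, -10, tolerance = 1e-9)
  expect_equal(tic$angles$elevation, 0, tolerance = 1e-9)
  expect_error(target_in_head_coords(diag(3), c(0, 0, 0)), "nonzero")
})

test_that("marker pose estimation recovers ground-truth poses exactly", {
  expect_equal(unlist(estimate_pose_from_markers(marker_template()))[1:3],
               c(yaw = 0, pitch = 0, torsion = 0), tolerance = 1e-9)
  R <- fick_rotation(10, -5, 15)
  M <- t(R %*% t(marker_template())) + matrix(c(3, 4, 5), 3, 3, byrow = TRUE)
  ang <- estimate_pose_from_markers(M)
  expect_equal(c(ang$yaw, ang$pitch, ang$torsion), c(10, -5, 15),
               tolerance = 1e-6)
  set.seed(13)
  worst <- 0
  for (i in 1:500) {
    y <- runif(1, -60, 60); p <- runif(1, -60, 60); g <- runif(1, -45, 45)
    M <- t(fick_rotation(y, p, g) %*% t(marker_template()))
    ang <- estimate_pose_from_markers(M)
    worst <- max(worst, abs(c(ang$yaw - y, ang$pitch - p, ang$torsion - g)))
  }
  expect_lt(worst, 1e-6)
})

test_that("symmetric pinna raising barely perturbs the yaw estimate", {
  tpl <- marker_template()
  raised <- tpl
  raised[c("left_pinna", "right_pinna"), "z"] <-
    raised[c("left_pinna", "right_pinna"), "z"] + 3
  R <- fick_rotation(20, 10, -8)
  a0 <- estimate_pose_from_markers(t(R %*% t(tpl)))
  a1 <- estimate_pose_from_markers(t(R %*% t(raised)))
  expect_lt(abs(a1$yaw - a0$yaw), 1e-6)
})

test_that("collinear markers raise a degenerate-geometry error", {
  bad <- rbind(c(0, 10, 10), c(0, -10, -10), c(0, 0, 0))
  expect_error(estimate_pose_from_markers(bad), "collinear")
})

test_that("marker CSV round trip drives the per-frame estimator", {
  tpl <- marker_template()
  R <- fick_rotation(5, 7, -3)
  rot <- t(R %*% t(tpl))
  dimnames(rot) <- dimnames(tpl)
  df <- rbind(
    data.frame(frame = 1, marker = rownames(tpl), tpl),
    data.frame(frame = 2, marker = rownames(tpl), rot))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  poses <- estimate_pose_frames(read_marker_csv(path))
  expect_equal(nrow(poses), 2L)
  expect_equal(unlist(poses[2, c("yaw", "pitch", "torsion")]),
               c(yaw = 5, pitch = 7, torsion = -3), tolerance = 1e-6)
  out <- withr::local_tempfile(fileext = ".csv")
  write_pose_csv(poses, out)
  expect_equal(utils::read.csv(out)$yaw, poses$yaw)
})
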