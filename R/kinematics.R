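## 3D head-pose mathematics: elementary rotations, Fick gimbal
## composition/decomposition, Listing torsion, head-direction updates,
## target transforms and marker-based pose estimation.
## See ?batroll for the sign-convention table shared by all modules.

#' Elementary rotation matrix
#'
#' Right-handed rotation about a body axis. See the sign-convention table
#' in [batroll].
#'
#' @param axis One of `"X"`, `"Y"`, `"Z"`.
#' @param angle Rotation angle in degrees.
#' @return A 3x3 orthonormal rotation matrix with determinant +1.
#' @examples
#' rotation_matrix("Z", 90) %*% c(1, 0, 0)  # -> (0, 1, 0)
#' @export
rotation_matrix <- function(axis = c("X", "Y", "Z"), angle) {
  axis <- match.arg(axis)
  if (length(angle) != 1L || !is.finite(angle)) {
    stop_invalid("`angle` must be a single finite number (degrees)")
  }
  a <- deg2rad(angle)
  c_ <- cos(a); s_ <- sin(a)
  switch(axis,
    X = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
    Y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
    Z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
  )
}

#' Check that a matrix is a proper rotation
#'
#' @param R A 3x3 matrix.
#' @param tol Orthonormality / determinant tolerance.
#' @return `TRUE` or `FALSE`.
#' @export
is_rotation_matrix <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) && all(is.finite(R)) &&
    max(abs(crossprod(R) - diag(3))) <= tol && abs(det(R) - 1) <= tol
}

assert_rotation <- function(R, tol = 1e-6) {
  if (!is_rotation_matrix(R, tol)) {
    stop_invalid("matrix is not a proper rotation (orthonormal, det = +1)")
  }
  invisible(R)
}

## Gram-Schmidt re-orthonormalization; keeps accumulated rotations from
## drifting over long command chains.
orthonormalize3 <- function(R) {
  q <- qr.Q(qr(R))
  ## qr.Q may flip column signs; re-align with the input
  s <- sign(colSums(q * R))
  s[s == 0] <- 1
  q <- sweep(q, 2, s, `*`)
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}

#' Fick-gimbal composition and decomposition
#'
#' `fick_rotation()` composes `R_Z(yaw) %*% R_Y(pitch) %*% R_X(torsion)`,
#' the head-to-body rotation of a Fick gimbal.  `fick_decompose()` inverts
#' it away from gimbal lock (`|pitch| = 90`).
#'
#' @param yaw,pitch,torsion Fick angles in degrees (matrix-native signs:
#'   positive yaw leftward, positive pitch downward).
#' @param R A 3x3 rotation matrix.
#' @param lock_tol Gimbal-lock tolerance in degrees.
#' @return `fick_rotation()`: a rotation matrix. `fick_decompose()`: a
#'   `fick_angles` list with fields `yaw`, `pitch`, `torsion` (degrees).
#' @examples
#' ang <- fick_decompose(fick_rotation(10, -5, 15))
#' unlist(ang)
#' @export
fick_rotation <- function(yaw, pitch, torsion = 0) {
  if (!all(is.finite(c(yaw, pitch, torsion)))) {
    stop_invalid("Fick angles must be finite")
  }
  rotation_matrix("Z", yaw) %*% rotation_matrix("Y", pitch) %*%
    rotation_matrix("X", torsion)
}

#' @rdname fick_rotation
#' @export
fick_decompose <- function(R, lock_tol = 1e-6) {
  assert_rotation(R)
  sp <- -R[3, 1]
  if (abs(sp) >= cos(deg2rad(lock_tol))) {
    stop_invalid("degenerate pose: Fick decomposition undefined at |pitch| = 90 (gimbal lock)")
  }
  ang <- list(
    yaw = rad2deg(atan2(R[2, 1], R[1, 1])),
    pitch = rad2deg(asin(sp)),
    torsion = rad2deg(atan2(R[3, 2], R[3, 3]))
  )
  class(ang) <- "fick_angles"
  ang
}

#' @export
print.fick_angles <- function(x, ...) {
  cat(sprintf("Fick angles (deg): yaw %.4f, pitch %.4f, torsion %.4f\n",
              x$yaw, x$pitch, x$torsion))
  invisible(x)
}

#' Convert between azimuth/elevation and horizontal angle
#'
#' The horizontal angle is the cone-of-confusion coordinate
#' `alpha = asin(sin(theta) * cos(phi))`; it is the coordinate in which
#' head-related transfer functions are gridded here.
#'
#' @param theta Azimuth in degrees (positive rightward).
#' @param phi Elevation in degrees (positive up).
#' @param alpha Horizontal angle in degrees.
#' @return Degrees.
#' @examples
#' horizontal_angle(30, 60)  # 14.4775
#' @export
horizontal_angle <- function(theta, phi) {
  rad2deg(asin(sin(deg2rad(theta)) * cos(deg2rad(phi))))
}

#' @rdname horizontal_angle
#' @export
azimuth_from_horizontal <- function(alpha, phi) {
  s <- sin(deg2rad(alpha)) / cos(deg2rad(phi))
  if (any(abs(s) > 1 + 1e-12)) {
    stop_invalid("no azimuth with |theta| < 90 reaches this (alpha, phi)")
  }
  rad2deg(asin(pmin(1, pmax(-1, s))))
}

#' Direction vectors and direction angles
#'
#' @param v A unit 3-vector.
#' @param azimuth,elevation Degrees (azimuth positive rightward, elevation
#'   positive up).
#' @return `direction_angles()`: list with `azimuth`, `elevation` and the
#'   derived horizontal angle `alpha` (degrees). `direction_vector()`: a
#'   unit 3-vector.
#' @export
direction_angles <- function(v) {
  if (length(v) != 3L || !all(is.finite(v))) stop_invalid("need a finite 3-vector")
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop_invalid("zero direction vector")
  v <- v / n
  az <- rad2deg(atan2(-v[2], v[1]))
  el <- rad2deg(asin(pmin(1, pmax(-1, v[3]))))
  list(azimuth = az, elevation = el, alpha = horizontal_angle(az, el))
}

#' @rdname direction_angles
#' @export
direction_vector <- function(azimuth, elevation) {
  th <- deg2rad(azimuth); ph <- deg2rad(elevation)
  c(cos(th) * cos(ph), -sin(th) * cos(ph), sin(ph))
}

#' Mean torsion angle from Listing's law
#'
#' Half the yaw-pitch product, with the product evaluated in radians
#' (small-angle Listing approximation) and the result returned in degrees.
#'
#' @param yaw,pitch Head yaw and pitch in degrees.
#' @return Torsion in degrees.
#' @examples
#' listing_torsion(20, 10)  # ~1.7453
#' @export
listing_torsion <- function(yaw, pitch) {
  rad2deg(deg2rad(yaw) * deg2rad(pitch) / 2)
}

#' Full head pose including Listing torsion and an injected roll
#'
#' The head torsion is the Listing torsion of the (yaw, pitch) direction
#' perturbed by a roll sample: `torsion = listing_torsion(yaw, pitch) +
#' roll`.
#'
#' @param yaw,pitch Fick yaw and pitch of the head, degrees.
#' @param roll Injected head roll, degrees.
#' @return List with `angles` (a `fick_angles`) and the head-to-body
#'   rotation matrix `R`.
#' @export
head_pose_with_roll <- function(yaw, pitch, roll = 0) {
  torsion <- listing_torsion(yaw, pitch) + roll
  ang <- list(yaw = yaw, pitch = pitch, torsion = torsion)
  class(ang) <- "fick_angles"
  list(angles = ang, R = fick_rotation(yaw, pitch, torsion))
}

#' Update the accumulated head rotation with a yaw/pitch command
#'
#' Applies `R_Y(dphi) %*% R_Z(dtheta)` to the accumulated body-to-head
#' rotation and returns the new head direction (the image of the initial
#' forward direction (1,0,0) under the inverse rotation).  The result is
#' re-orthonormalized every update so chained commands do not drift.
#'
#' @param R_prev Accumulated body-to-head rotation (3x3).
#' @param dtheta Yaw command in degrees (positive turns the head to
#'   positive azimuth, i.e. rightward).
#' @param dphi Pitch command in degrees (positive turns the head up).
#' @return List with the updated rotation `R`, the head direction vector
#'   `head` (body frame) and its `angles` ([direction_angles()]).
#' @export
update_head_rotation <- function(R_prev, dtheta, dphi) {
  assert_rotation(R_prev)
  if (!all(is.finite(c(dtheta, dphi)))) stop_invalid("commands must be finite")
  R <- rotation_matrix("Y", dphi) %*% rotation_matrix("Z", dtheta) %*% R_prev
  R <- orthonormalize3(R)
  head <- drop(t(R) %*% c(1, 0, 0))
  list(R = R, head = head, angles = direction_angles(head))
}

#' Transform a target direction into head-centered coordinates
#'
#' @param R_BH Body-to-head rotation matrix.
#' @param s_B Unit target direction in body coordinates.
#' @return List with the head-frame direction `s_H` and its `angles`;
#'   `angles$alpha` and `angles$elevation` are (0, 0) iff the head points
#'   at the target.
#' @export
target_in_head_coords <- function(R_BH, s_B) {
  assert_rotation(R_BH)
  n <- sqrt(sum(s_B^2))
  if (length(s_B) != 3L || n < 1e-12) stop_invalid("target direction must be a nonzero 3-vector")
  s_H <- drop(R_BH %*% (s_B / n))
  list(s_H = s_H, angles = direction_angles(s_H))
}

## ---- marker-based pose estimation ---------------------------------------

#' Reference marker triplet
#'
#' Synthetic template emulating motion-capture markers on the left pinna
#' tip, right pinna tip and the head, in millimetres, in the reference
#' (zero yaw/pitch/torsion) pose.
#'
#' @return A 3x3 matrix with rows `left_pinna`, `right_pinna`, `head`.
#' @export
marker_template <- function() {
  m <- rbind(left_pinna = c(0, 10, 20),
             right_pinna = c(0, -10, 20),
             head = c(0, 0, 0))
  colnames(m) <- c("x", "y", "z")
  m
}

## Orthocenter of a triangle with vertices in the rows of `m`.
triangle_orthocenter <- function(a, b, c_) {
  n <- cross3(b - a, c_ - a)
  A <- rbind(c_ - b, c_ - a, n)
  rhs <- c(sum(a * (c_ - b)), sum(b * (c_ - a)), sum(a * n))
  drop(solve(A, rhs))
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

## Right-handed frame attached to a marker triplet: Vz runs from the head
## marker through the orthocenter of the triangle (perpendicular to the
## inter-pinna line, so symmetric pinna movements barely disturb it), Vy is
## the plane normal, Vx = Vy x Vz.
marker_frame <- function(markers) {
  lp <- markers[1, ]; rp <- markers[2, ]; hd <- markers[3, ]
  n <- cross3(lp - hd, rp - hd)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-9 * max(1, sum(abs(markers)))) {
    stop_invalid("degenerate geometry: markers are collinear")
  }
  vy <- n / nn
  o <- triangle_orthocenter(hd, lp, rp)
  vz <- o - hd
  vz <- vz - sum(vz * vy) * vy
  nz <- sqrt(sum(vz^2))
  if (nz < 1e-12) stop_invalid("degenerate geometry: head marker at orthocenter")
  vz <- vz / nz
  vx <- cross3(vy, vz)
  cbind(vx, vy, vz)
}

#' Estimate head pose from a marker triplet
#'
#' Builds an orthonormal frame from the three markers (see S1-style
#' construction in the package vignette: an axis through the head marker
#' and the orthocenter of the marker triangle, the marker-plane normal, and
#' their cross product) and reports the Fick angles of that frame relative
#' to the frame of [marker_template()].
#'
#' @param markers A 3x3 matrix, rows left pinna, right pinna, head (mm).
#' @param template Reference triplet; defaults to [marker_template()].
#' @return A `fick_angles` list.
#' @export
estimate_pose_from_markers <- function(markers, template = marker_template()) {
  if (!is.matrix(markers) || !all(dim(markers) == c(3L, 3L)) ||
      !all(is.finite(markers))) {
    stop_invalid("`markers` must be a finite 3x3 matrix (rows: left pinna, right pinna, head)")
  }
  Fm <- marker_frame(markers)
  Ft <- marker_frame(template)
  R <- orthonormalize3(Fm %*% t(Ft))
  fick_decompose(R)
}

#' Marker CSV input and pose CSV output
#'
#' `read_marker_csv()` reads a long-format table with columns `frame`,
#' `marker` (`left_pinna`, `right_pinna`, `head`), `x`, `y`, `z` (mm).
#' `estimate_pose_frames()` runs the per-frame marker pose estimator and
#' `write_pose_csv()` writes `frame`, `yaw`, `pitch`, `torsion` (deg).
#'
#' @param path CSV file path.
#' @param df Marker data frame as returned by `read_marker_csv()`.
#' @param template Reference triplet passed to the estimator.
#' @param poses Pose data frame as returned by `estimate_pose_frames()`.
#' @return `read_marker_csv()`: a data frame; `estimate_pose_frames()`: a
#'   data frame of Fick angles per frame.
#' @export
read_marker_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "marker", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop_invalid("marker CSV needs columns: ", paste(need, collapse = ", "))
  }
  df
}

#' @rdname read_marker_csv
#' @export
estimate_pose_frames <- function(df, template = marker_template()) {
  frames <- sort(unique(df$frame))
  out <- lapply(frames, function(fr) {
    sub <- df[df$frame == fr, ]
    rows <- c("left_pinna", "right_pinna", "head")
    idx <- match(rows, sub$marker)
    if (anyNA(idx)) stop_invalid("frame ", fr, " is missing a marker")
    m <- as.matrix(sub[idx, c("x", "y", "z")])
    rownames(m) <- rows
    ang <- estimate_pose_from_markers(m, template)
    data.frame(frame = fr, yaw = ang$yaw, pitch = ang$pitch,
               torsion = ang$torsion)
  })
  do.call(rbind, out)
}

#' @rdname read_marker_csv
#' @export
write_pose_csv <- function(poses, path) {
  utils::write.csv(poses, path, row.names = FALSE)
  invisible(path)
}
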