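# Forward modelling: fiducial-based rigid co-registration (and controlled
# co-registration error), the analytic current-dipole-in-a-homogeneous-
# sphere field (Sarvas solution), and lead-field assembly for
# normal-constrained sources.

MU0 <- 4 * pi * 1e-7  # vacuum permeability, T m / A

#' Construct a fiducial set
#'
#' The three standard anatomical landmarks used for MEG co-registration.
#'
#' @param nasion,left_preauricular,right_preauricular length-3 positions (mm).
#' @return object of class `fiducial_set`.
#' @export
fiducial_set <- function(nasion, left_preauricular, right_preauricular) {
  pts <- rbind(nasion = as.numeric(nasion),
               lpa = as.numeric(left_preauricular),
               rpa = as.numeric(right_preauricular))
  stopifnot(ncol(pts) == 3, all(is.finite(pts)))
  area <- vnorm(cross3(pts[2, ] - pts[1, ], pts[3, ] - pts[1, ])) / 2
  if (area <= 1) stop("fiducial points are (near-)collinear: triangle area <= 1 mm^2")
  structure(list(points = pts), class = "fiducial_set")
}

#' Construct a rigid transform
#'
#' @param rotation 3x3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 vector (mm).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation determinant is not +1 (reflection not allowed)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#' @param tf a `rigid_transform`.
#' @param points n x 3 matrix or length-3 vector (mm).
#' @return transformed points, same shape.
#' @export
apply_rigid <- function(tf, points) {
  v <- is.null(dim(points))
  p <- if (v) matrix(points, 1, 3) else as.matrix(points)
  out <- sweep(p %*% t(tf$rotation), 2, tf$translation, `+`)
  if (v) as.numeric(out) else out
}

#' Invert a rigid transform
#' @param tf a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_rigid <- function(tf) {
  rigid_transform(t(tf$rotation), -as.numeric(t(tf$rotation) %*% tf$translation))
}

#' Least-squares rigid alignment of two fiducial sets
#'
#' Orthogonal Procrustes with translation (Kabsch algorithm): finds the
#' rotation + translation mapping `source_fids` onto `target_fids` in the
#' least-squares sense, with no scaling and reflection excluded.
#'
#' @param source_fids,target_fids `fiducial_set` objects.
#' @return a `rigid_transform` `tf` with `apply_rigid(tf, source)` ~= target.
#' @export
fit_rigid_transform <- function(source_fids, target_fids) {
  stopifnot(inherits(source_fids, "fiducial_set"),
            inherits(target_fids, "fiducial_set"))
  S <- source_fids$points; T_ <- target_fids$points
  cs <- colMeans(S); ct <- colMeans(T_)
  H <- crossprod(sweep(S, 2, cs), sweep(T_, 2, ct))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, ct - as.numeric(R %*% cs))
}

#' Perturb fiducial positions with Gaussian error
#'
#' Adds independent zero-mean Gaussian displacement of standard deviation
#' `std_mm` to each of the three fiducials in each spatial dimension
#' (9 i.i.d. draws), emulating digitization/co-registration error.
#'
#' @param fids a `fiducial_set`.
#' @param std_mm per-point per-axis standard deviation (mm), >= 0.
#' @param rng_seed integer seed; the perturbation is deterministic per seed.
#' @return a perturbed `fiducial_set`.
#' @export
perturb_fiducials <- function(fids, std_mm, rng_seed) {
  stopifnot(inherits(fids, "fiducial_set"))
  if (std_mm < 0) stop("std_mm must be non-negative")
  if (std_mm == 0) return(fids)
  pts <- fids$points +
    with_seed(rng_seed, matrix(rnorm(9, 0, std_mm), 3, 3, byrow = TRUE))
  fiducial_set(pts[1, ], pts[2, ], pts[3, ])
}

#' Rigid transform realizing a given co-registration error level
#'
#' Perturbs the true fiducials by `std_mm` and fits the rigid transform
#' from the true to the perturbed set. In the simulation pipeline this
#' transform is applied to the inversion-side source space only; the
#' simulated sensor data are never altered.
#'
#' @param true_fids the true `fiducial_set`.
#' @param std_mm fiducial error standard deviation (mm).
#' @param rng_seed integer seed.
#' @return a `rigid_transform` (identity when `std_mm == 0`).
#' @export
coregistration_error_transform <- function(true_fids, std_mm, rng_seed) {
  if (std_mm == 0) return(rigid_transform())
  fit_rigid_transform(true_fids, perturb_fiducials(true_fids, std_mm, rng_seed))
}

#' Apply a rigid transform to a whole source space
#'
#' Vertices are rotated and translated; normals are rotated only.
#'
#' @param space a `source_space`.
#' @param tf a `rigid_transform`.
#' @return the transformed `source_space`.
#' @export
transform_source_space <- function(space, tf) {
  stopifnot(inherits(space, "source_space"), inherits(tf, "rigid_transform"))
  space$meshes <- lapply(space$meshes, function(m) {
    m$vertices <- apply_rigid(tf, m$vertices)
    m$normals <- m$normals %*% t(tf$rotation)
    if (!is.null(m$meta$centroid)) m$meta$centroid <- colMeans(m$vertices)
    m
  })
  space
}

## sensors ------------------------------------------------------------------

#' Construct an MEG sensor array
#'
#' @param positions n x 3 matrix of sensor positions (mm).
#' @param orientations n x 3 matrix of unit measurement axes
#'   (magnetometer orientation).
#' @param channel_names character vector of channel names.
#' @return object of class `sensor_array`.
#' @export
sensor_array <- function(positions, orientations, channel_names = NULL) {
  positions <- as.matrix(positions); orientations <- as.matrix(orientations)
  stopifnot(ncol(positions) == 3, all(dim(positions) == dim(orientations)))
  nn <- row_norms(orientations)
  if (any(abs(nn - 1) > 1e-9)) stop("sensor orientations must be unit vectors")
  channel_names <- channel_names %||% sprintf("MEG%03d", seq_len(nrow(positions)))
  structure(list(positions = unname(positions),
                 orientations = unname(orientations),
                 channel_names = channel_names),
            class = "sensor_array")
}

#' Generate a helmet-like MEG magnetometer array
#'
#' Places `n_channels` radial magnetometers quasi-uniformly (Fibonacci
#' lattice) on a spherical cap of radius `helmet_radius_mm` covering polar
#' angles up to `coverage_deg`, approximating a whole-head axial system.
#' The paper-equivalent preset is 274 channels.
#'
#' @param n_channels number of sensors (default 274).
#' @param helmet_radius_mm helmet sphere radius (mm).
#' @param coverage_deg angular coverage of the cap from the vertex.
#' @return a `sensor_array`.
#' @export
meg_helmet_array <- function(n_channels = 274, helmet_radius_mm = 110,
                             coverage_deg = 105) {
  n <- as.integer(n_channels)
  cmin <- cos(coverage_deg * pi / 180)
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n) - 0.5
  z <- 1 - (1 - cmin) * i / n           # cos(theta) from 1 down to cmin
  th <- acos(z)
  ph <- golden * (seq_len(n) - 1)
  dirs <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  sensor_array(helmet_radius_mm * dirs, dirs)
}

#' Distance from a point to the nearest sensor
#' @param sensors a `sensor_array`.
#' @param point length-3 position (mm).
#' @return minimum euclidean distance (mm).
#' @export
nearest_sensor_distance <- function(sensors, point) {
  min(row_norms(sweep(sensors$positions, 2, as.numeric(point))))
}

## spherical-conductor fields -----------------------------------------------

#' Magnetic field of a current dipole in a homogeneous conducting sphere
#'
#' Closed-form (Sarvas) solution for the field measured outside a
#' spherical volume conductor. Radial dipoles (moment parallel to the
#' dipole position relative to the sphere centre) produce exactly zero
#' field; the radial field component equals that of the primary (free
#' space) dipole term, since volume currents in a sphere contribute no
#' radial field.
#'
#' @param sensor_pos n x 3 (or length-3) sensor positions (mm).
#' @param sensor_ori n x 3 (or length-3) unit measurement axes.
#' @param dipole_pos length-3 dipole position (mm).
#' @param dipole_moment length-3 dipole moment (nAm).
#' @param center length-3 sphere centre (mm).
#' @return field component along each sensor axis, in fT.
#' @export
spherical_dipole_field <- function(sensor_pos, sensor_ori, dipole_pos,
                                   dipole_moment, center = c(0, 0, 0)) {
  one <- is.null(dim(sensor_pos))
  B <- sarvas_field(sensor_pos, dipole_pos, dipole_moment, center)
  ori <- if (one) matrix(sensor_ori, 1, 3) else as.matrix(sensor_ori)
  out <- rowSums(B * ori)
  if (one) as.numeric(out) else out
}

# full field vectors (n x 3) in fT; positions mm, moment nAm
sarvas_field <- function(sensor_pos, dipole_pos, dipole_moment, center) {
  P <- if (is.null(dim(sensor_pos))) matrix(sensor_pos, 1, 3) else as.matrix(sensor_pos)
  r <- sweep(P, 2, as.numeric(center)) * 1e-3          # m
  r0 <- (as.numeric(dipole_pos) - as.numeric(center)) * 1e-3
  q <- as.numeric(dipole_moment) * 1e-9                # A m
  nr0 <- vnorm(r0)
  if (nr0 < 1e-9) stop("dipole at the sphere centre: field direction undefined")
  nr <- row_norms(r)
  if (any(nr <= nr0 + 1e-12))
    stop("sensor inside the sphere of the dipole radius")
  a <- sweep(r, 2, r0)                                  # r - r0
  na <- row_norms(a)
  if (any(na < 1e-12)) stop("sensor coincides with the dipole")
  r_dot_r0 <- as.vector(r %*% r0)
  a_dot_r <- rowSums(a * r)
  F_ <- na * (nr * na + nr^2 - r_dot_r0)
  cF1 <- na^2 / nr + a_dot_r / na + 2 * na + 2 * nr
  cF2 <- na + 2 * nr + a_dot_r / na
  gradF <- r * cF1 - matrix(r0, nrow(r), 3, byrow = TRUE) * cF2
  qxr0 <- cross3(q, r0)
  qxr0_dot_r <- as.vector(r %*% qxr0)
  B <- (matrix(qxr0, nrow(r), 3, byrow = TRUE) * F_ - gradF * qxr0_dot_r) *
    (MU0 / (4 * pi * F_^2))
  B * 1e15                                              # T -> fT
}

#' Free-space field of a current dipole (primary term only)
#'
#' Biot-Savart field of a point current dipole, used as an independent
#' oracle for the radial component of the spherical-conductor solution.
#'
#' @inheritParams spherical_dipole_field
#' @return n x 3 matrix of field vectors (fT).
#' @export
free_space_dipole_field <- function(sensor_pos, dipole_pos, dipole_moment) {
  P <- if (is.null(dim(sensor_pos))) matrix(sensor_pos, 1, 3) else as.matrix(sensor_pos)
  a <- sweep(P, 2, as.numeric(dipole_pos)) * 1e-3
  na <- row_norms(a)
  q <- as.numeric(dipole_moment) * 1e-9
  qxa <- cbind(q[2] * a[, 3] - q[3] * a[, 2],
               q[3] * a[, 1] - q[1] * a[, 3],
               q[1] * a[, 2] - q[2] * a[, 1])
  (qxa / na^3) * (MU0 / (4 * pi)) * 1e15
}

## lead fields ---------------------------------------------------------------

# least-squares sphere fit (algebraic): returns list(center, radius)
fit_sphere <- function(points) {
  P <- as.matrix(points)
  A <- cbind(2 * P, 1)
  b <- rowSums(P^2)
  x <- qr.solve(A, b)
  ctr <- x[1:3]
  list(center = ctr, radius = sqrt(x[4] + sum(ctr^2)))
}

#' Assemble the lead field of a source space
#'
#' Gain matrix (channels x sources) of the spherical-conductor forward
#' model: column j is the sensor field (fT) of a unit 1 nAm dipole at
#' vertex j oriented along its outward surface normal (current flow along
#' the principal neuronal axis). The conductor centre defaults to the
#' centre of the best-fit sphere of the cortical mesh; for a combined
#' space the cortical gain block is bit-identical to the gain of the
#' cortical space alone.
#'
#' @param space a `source_space`.
#' @param sensors a `sensor_array`.
#' @param center optional conductor centre (mm).
#' @return object of class `lead_field`: list with `gain`,
#'   `conductor_center`, `source_space_ref`, `channel_names`.
#' @export
assemble_leadfield <- function(space, sensors, center = NULL) {
  stopifnot(inherits(space, "source_space"), inherits(sensors, "sensor_array"))
  ctr <- center %||% fit_sphere(space$meshes[[1]]$vertices)$center
  sv <- space_vertices(space)
  src_r <- row_norms(sweep(sv$vertices, 2, ctr))
  sens_r <- row_norms(sweep(sensors$positions, 2, ctr))
  bad <- which(src_r >= min(sens_r))
  if (length(bad))
    stop(sprintf("source vertex %d lies outside the sensor radius", bad[1]))
  ns <- nrow(sv$vertices)
  gain <- matrix(0, nrow(sensors$positions), ns)
  for (j in seq_len(ns)) {
    gain[, j] <- spherical_dipole_field(sensors$positions, sensors$orientations,
                                        sv$vertices[j, ], sv$normals[j, ], ctr)
  }
  structure(list(gain = gain,
                 conductor_center = as.numeric(ctr),
                 source_space_ref = sprintf("%s/%d", space$anatomy_kind, ns),
                 channel_names = sensors$channel_names),
            class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf("<lead_field: %d channels x %d sources (%s)>\n",
              nrow(x$gain), ncol(x$gain), x$source_space_ref))
  invisible(x)
}
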