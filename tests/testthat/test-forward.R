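# Co-registration and the spherical-conductor forward model.

test_that("rigid alignment recovers identity, translation and known rotations", {
  f <- fiducial_set(c(0, 90, 0), c(-70, 0, 0), c(70, 0, 0))
  tf0 <- fit_rigid_transform(f, f)
  expect_lt(max(abs(tf0$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(tf0$translation)), 1e-9)
  sh <- fiducial_set(c(5, 90, 0), c(-65, 0, 0), c(75, 0, 0))
  tfs <- fit_rigid_transform(f, sh)
  expect_equal(tfs$translation, c(5, 0, 0), tolerance = 1e-9)
  for (k in 1:5) {
    ax <- rnorm(3); ang <- runif(1, -170, 170)
    R0 <- hippomeg:::rotation_about_axis(ax, ang)
    tr0 <- rnorm(3, 0, 20)
    pts <- f$points %*% t(R0) + matrix(tr0, 3, 3, byrow = TRUE)
    tf <- fit_rigid_transform(f, fiducial_set(pts[1, ], pts[2, ], pts[3, ]))
    expect_lt(max(abs(tf$rotation - R0)), 1e-9)
  }
  expect_error(fiducial_set(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), "collinear")
})

test_that("rigid transforms round-trip and stay orthonormal", {
  tf <- rigid_transform(hippomeg:::rotation_about_axis(c(1, 1, 0), 40),
                        c(3, -4, 5))
  pts <- matrix(rnorm(60, 0, 30), 20, 3)
  back <- apply_rigid(invert_rigid(tf), apply_rigid(tf, pts))
  expect_lt(max(abs(back - pts)), 1e-9)
  expect_error(rigid_transform(diag(c(1, 1, -1))), "determinant")
})

test_that("fiducial perturbation is seeded, unbiased and correctly scaled", {
  f <- fiducial_set(c(0, 90, 0), c(-70, 0, 0), c(70, 0, 0))
  expect_identical(perturb_fiducials(f, 0, 1), f)
  a <- perturb_fiducials(f, 3, 42)
  expect_identical(a, perturb_fiducials(f, 3, 42))
  expect_false(identical(a, perturb_fiducials(f, 3, 43)))
  # Monte-Carlo: empirical per-axis std of the displacement
  disp <- vapply(1:5000, function(s)
    as.vector(perturb_fiducials(f, 2, s)$points - f$points), numeric(9))
  expect_gt(sd(disp), 1.97)
  expect_lt(sd(disp), 2.03)
  expect_error(perturb_fiducials(f, -1, 1), "non-negative")
})

test_that("co-registration error transforms scale with the fiducial error", {
  f <- fiducial_set(c(0, 90, 0), c(-70, 0, 0), c(70, 0, 0))
  tf0 <- coregistration_error_transform(f, 0, 1)
  expect_equal(tf0$rotation, diag(3))
  expect_equal(tf0$translation, c(0, 0, 0))
  pts <- matrix(rnorm(90, 0, 40), 30, 3)
  d1 <- d3 <- numeric(200)
  for (s in 1:200) {
    t1 <- coregistration_error_transform(f, 1, s)
    t3 <- coregistration_error_transform(f, 3, s)
    d1[s] <- mean(sqrt(rowSums((apply_rigid(t1, pts) - pts)^2)))
    d3[s] <- mean(sqrt(rowSums((apply_rigid(t3, pts) - pts)^2)))
    # round trip on a mesh-sized cloud
    if (s == 1) {
      back <- apply_rigid(invert_rigid(t3), apply_rigid(t3, pts))
      expect_lt(max(abs(back - pts)), 1e-9)
    }
  }
  expect_gt(mean(d3), mean(d1))
  expect_gt(mean(d3 > d1), 0.9)   # paired dominance, not just on average
})

test_that("radial dipoles are silent and fields are exactly linear", {
  ctr <- c(0, 0, 0)
  dp <- c(25, -10, 30)
  sens <- meg_helmet_array(40, 110)
  rad <- spherical_dipole_field(sens$positions, sens$orientations, dp,
                                3 * dp, ctr)
  tang <- hippomeg:::cross3(dp, c(0, 0, 1))
  tang <- 20 * tang / sqrt(sum(tang^2))
  ft <- spherical_dipole_field(sens$positions, sens$orientations, dp, tang, ctr)
  expect_lt(max(abs(rad)), 1e-12 * max(abs(ft)))
  ft2 <- spherical_dipole_field(sens$positions, sens$orientations, dp,
                                2 * tang, ctr)
  expect_identical(ft2, 2 * ft)
  expect_error(spherical_dipole_field(sens$positions, sens$orientations,
                                      c(0, 0, 0), tang, ctr), "centre")
  expect_error(spherical_dipole_field(c(10, 0, 0), c(1, 0, 0), dp, tang, ctr),
               "inside")
})

test_that("the radial field equals the free-space primary dipole component", {
  ctr <- c(0, 0, 0)
  for (k in 1:10) {
    dp <- rnorm(3, 0, 20)
    q <- rnorm(3, 0, 10)
    sens <- matrix(rnorm(30, 0, 1), 10, 3)
    sens <- 120 * sens / sqrt(rowSums(sens^2))
    B <- hippomeg:::sarvas_field(sens, dp, q, ctr)
    Bf <- free_space_dipole_field(sens, dp, q)
    rhat <- sens / sqrt(rowSums(sens^2))
    expect_equal(rowSums(B * rhat), rowSums(Bf * rhat), tolerance = 1e-9)
  }
})

test_that("gain columns superpose and decay with source depth", {
  anat <- small_anatomy()
  L <- anat$L_combined
  sv <- space_vertices(anat$space_combined)
  # superposition: two-dipole field equals the sum of single-dipole calls
  j1 <- 5L; j2 <- 200L
  f12 <- L$gain[, j1] * 2.5 + L$gain[, j2] * (-1.5)
  f1 <- spherical_dipole_field(anat$sensors$positions, anat$sensors$orientations,
                               sv$vertices[j1, ], 2.5 * sv$normals[j1, ],
                               L$conductor_center)
  f2 <- spherical_dipole_field(anat$sensors$positions, anat$sensors$orientations,
                               sv$vertices[j2, ], -1.5 * sv$normals[j2, ],
                               L$conductor_center)
  expect_equal(f12, f1 + f2, tolerance = 1e-12)
  # depth: tangential dipole strength decreases toward the sphere centre
  sens <- meg_helmet_array(80, 110)
  norms <- vapply(seq(55, 5, by = -10), function(r) {
    b <- spherical_dipole_field(sens$positions, sens$orientations,
                                c(r, 0, 20), c(0, 20, 0), c(0, 0, 0))
    sqrt(sum(b^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("combined lead fields embed the cortical block bit-exactly", {
  anat <- desk_anatomy()
  ncx <- nrow(anat$cortex$vertices)
  expect_identical(anat$L_combined$gain[, seq_len(ncx)], anat$L_cortical$gain)
  expect_equal(dim(anat$L_combined$gain), c(274L, ncx + 162L))
  expect_true(all(is.finite(anat$L_combined$gain)))
  # a source outside the helmet is rejected
  far <- anat$space_combined
  far$meshes[[2]]$vertices[1, ] <- c(500, 0, 0)
  expect_error(assemble_leadfield(far, anat$sensors), "outside")
})

test_that("helmet arrays have unit orientations and sit outside the sources", {
  sens <- meg_helmet_array(274, 110)
  expect_equal(nrow(sens$positions), 274L)
  expect_lt(max(abs(1 - sqrt(rowSums(sens$orientations^2)))), 1e-9)
  expect_true(all(abs(sqrt(rowSums(sens$positions^2)) - 110) < 1e-9))
})

test_that("zero co-registration error reproduces the unperturbed pipeline", {
  anat <- small_anatomy()
  tf0 <- coregistration_error_transform(
    fiducial_set(c(0, 60, 0), c(-55, 0, 0), c(55, 0, 0)), 0, 7)
  moved <- transform_source_space(anat$space_combined, tf0)
  expect_identical(moved$meshes[[1]]$vertices,
                   anat$space_combined$meshes[[1]]$vertices)
  expect_identical(moved$meshes[[2]]$normals,
                   anat$space_combined$meshes[[2]]$normals)
})
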