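# Source-space geometry: generators, spacing matching, patches, transforms.

test_that("cortex generator is deterministic and meets its spacing target", {
  a <- generate_cortex_mesh(2000, 3.7, seed = 1)
  b <- generate_cortex_mesh(2000, 3.7, seed = 1)
  expect_identical(a, b)
  expect_equal(nrow(a$vertices), 2000L)
  me <- mean(edge_lengths(a))
  expect_gt(me, 3.15)
  expect_lt(me, 4.25)
  expect_silent(validate_mesh(a))
})

test_that("paper-scale mesh presets reproduce the published vertex counts", {
  cx <- generate_cortex_mesh(10595, 3.73, seed = 1)
  expect_equal(nrow(cx$vertices), 10595L)
  hp <- generate_hippocampus_mesh(162, 3.69, seed = 1, cortex_mesh = cx)
  expect_equal(nrow(hp$vertices), 162L)
  expect_silent(validate_mesh(hp))
  # depth report: hippocampal centroid to nearest helmet sensor lands in
  # the ~9 cm regime of a whole-head system at full scale
  sens <- meg_helmet_array(274, cx$meta$sphere_radius + 18)
  d_cm <- nearest_sensor_distance(sens, hp$meta$centroid) / 10
  expect_gt(d_cm, 7)
  expect_lt(d_cm, 11)
})

test_that("generated meshes pass the structural audit across scales and seeds", {
  for (n in c(500, 1200)) for (s in c(2, 9)) {
    m <- generate_cortex_mesh(n, 3.7, seed = s)
    expect_silent(validate_mesh(m))
    expect_true(all(abs(1 - sqrt(rowSums(m$normals^2))) < 1e-9))
  }
  for (n in c(120, 200)) {
    h <- generate_hippocampus_mesh(n, 3.69, seed = 3)
    expect_silent(validate_mesh(h))
    expect_equal(nrow(h$vertices), n)
  }
})

test_that("hippocampal tube honours its axis length", {
  L <- 50
  hp <- generate_hippocampus_mesh(162, 3.69, seed = 1, axis_length_mm = L)
  edge <- mean(edge_lengths(hp))
  apexes <- hp$meta$apex_vertices
  # graph geodesic between the tips matches the analytic capsule meridian
  d <- geodesic_distances(hp, apexes[1])[1, apexes[2]]
  meridian <- L + (pi - 2) * hp$meta$tube_radius
  expect_lt(abs(d - meridian), edge)
  # tip-to-tip chord of the bent centreline
  bend <- hp$meta$bend_deg * pi / 180
  chord <- (L / bend) * 2 * sin(bend / 2)
  tip_dist <- sqrt(sum((hp$vertices[apexes[1], ] - hp$vertices[apexes[2], ])^2))
  expect_lt(abs(tip_dist - chord), edge)
})

test_that("hippocampus nests inside its paired cortex and reports sensor depth", {
  anat <- desk_anatomy()
  shell <- min(sqrt(rowSums(anat$cortex$vertices^2)))
  expect_true(all(sqrt(rowSums(anat$hippocampus$vertices^2)) < shell))
  d <- nearest_sensor_distance(anat$sensors, anat$hippocampus$meta$centroid)
  expect_gt(d, 0)
  expect_true(is.finite(d))
})

test_that("spacing matching is a no-op at target and lands within 5% otherwise", {
  hp <- generate_hippocampus_mesh(162, 3.69, seed = 1)
  expect_identical(match_mesh_spacing(hp, 3.69), hp)
  dense <- generate_hippocampus_mesh(900, 1.0, seed = 2, axis_length_mm = 30)
  dec <- match_mesh_spacing(dense, 3.69)
  me <- mean(edge_lengths(dec))
  expect_gt(me, 3.69 * 0.95)
  expect_lt(me, 3.69 * 1.05)
  expect_silent(validate_mesh(dec))   # includes single-component check
})

test_that("patch weights follow the Gaussian of geodesic distance", {
  cyl <- cylinder_mesh(radius = 10, length = 40, spacing = 1)
  nv <- nrow(cyl$vertices)
  seed <- which.min(rowSums(sweep(cyl$vertices, 2, c(10, 0, 20))^2))
  pw <- patch_weights(cyl, seed, 6)
  expect_s3_class(pw, "patch_weights")
  expect_equal(pw$weights[seed], 1)
  expect_equal(which.max(pw$weights), seed)
  sigma <- 6 / sqrt(8 * log(2))
  expect_equal(sigma, 6 / 2.3548, tolerance = 1e-4)
  # analytic geodesics on the unrolled cylinder (min over winding),
  # measured from the actual seed vertex
  th <- atan2(cyl$vertices[, 2], cyl$vertices[, 1])
  th0 <- th[seed]; z0 <- cyl$vertices[seed, 3]
  dth <- abs(((th - th0 + pi) %% (2 * pi)) - pi)
  d_true <- sqrt((10 * dth)^2 + (cyl$vertices[, 3] - z0)^2)
  # graph geodesics stay within the equilateral-lattice anisotropy bound
  d_graph <- geodesic_distances(cyl, seed)[1, ]
  sel <- which(d_true > 1 & d_true < 12)
  expect_true(all(d_graph[sel] / d_true[sel] > 0.999))
  expect_lt(max(d_graph[sel] / d_true[sel]), 1.16)
  # weights decay monotonically with geodesic distance
  o <- order(d_graph)
  expect_true(all(diff(pw$weights[o][d_graph[o] < 9]) <= 1e-12))
  # half-weight at half the FWHM, against the analytic cylinder geodesic
  ring <- which(abs(d_true - 3) < 0.4)
  expect_gt(length(ring), 5)
  expect_true(all(abs(pw$weights[ring] - 0.5) < 0.05))
})

test_that("hippocampal transforms are rigid, invertible and leave cortex alone", {
  anat <- small_anatomy()
  sp <- anat$space_combined
  expect_error(transform_hippocampus(anat$space_cortical),
               "combined")
  id <- transform_hippocampus(sp, shift_mm = c(0, 0, 0))
  expect_identical(id$meshes[[2]]$vertices, sp$meshes[[2]]$vertices)
  fwd <- transform_hippocampus(sp, shift_mm = c(10, 0, 0))
  back <- transform_hippocampus(fwd, shift_mm = c(-10, 0, 0))
  expect_lt(max(abs(back$meshes[[2]]$vertices - sp$meshes[[2]]$vertices)), 1e-12)
  rot <- transform_hippocampus(sp, rotation_deg = 30)
  expect_identical(rot$meshes[[1]], sp$meshes[[1]])   # cortical untouched
  # rigidity: pairwise distances preserved
  v0 <- sp$meshes[[2]]$vertices[1:40, ]
  v1 <- rot$meshes[[2]]$vertices[1:40, ]
  expect_lt(max(abs(dist(v0) - dist(v1))), 1e-9)
  # normals stay unit and consistent
  expect_lt(max(abs(1 - sqrt(rowSums(rot$meshes[[2]]$normals^2)))), 1e-9)
})

test_that("the shift battery contains 24 distinct models", {
  sp <- small_anatomy()$space_combined
  mods <- shifted_hippocampus_models(sp)
  expect_length(mods, 24)
  ctds <- t(vapply(mods, function(m) colMeans(m$meshes[[2]]$vertices),
                   numeric(3)))
  expect_equal(nrow(unique(round(ctds, 6))), 24L)
})

test_that("nearest cortical neighbours match the brute-force scan", {
  anat <- small_anatomy()
  sp <- anat$space_combined
  nb <- nearest_cortical_neighbours(sp)
  cv <- sp$meshes[[1]]$vertices
  hv <- sp$meshes[[2]]$vertices
  for (k in sample(nrow(hv), 25)) {
    d2 <- rowSums(sweep(cv, 2, hv[k, ])^2)
    expect_equal(nb$cortical_index[k], which.min(d2))
    expect_equal(nb$distance_mm[k], sqrt(min(d2)), tolerance = 1e-12)
  }
  # coincident points give zero distance
  sp2 <- sp
  sp2$meshes[[2]]$vertices[1, ] <- cv[7, ]
  nb2 <- nearest_cortical_neighbours(sp2, 1)
  expect_equal(nb2$distance_mm, 0)
  expect_equal(nb2$cortical_index, 7L)
})

test_that("combined and cortical spaces share bit-identical cortical blocks", {
  anat <- small_anatomy()
  expect_identical(anat$space_combined$meshes[[1]],
                   anat$space_cortical$meshes[[1]])
  expect_equal(n_sources(anat$space_combined),
               n_sources(anat$space_cortical) +
                 nrow(anat$hippocampus$vertices))
  expect_equal(anat$space_combined$vertex_offset,
               c(1L, nrow(anat$cortex$vertices) + 1L))
})
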