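# Shared fixtures, built once per test run. The desk-scale study anatomy
# (2000 + 162 vertices, 274 channels) backs the heavier integration and
# acceptance tests; the small anatomy keeps unit tests fast.

.fixtures <- new.env(parent = emptyenv())

desk_anatomy <- function() {
  if (is.null(.fixtures$desk))
    .fixtures$desk <- build_study_anatomy("desk", anatomy_seed = 1L)
  .fixtures$desk
}

small_anatomy <- function() {
  if (is.null(.fixtures$small)) {
    cx <- generate_cortex_mesh(500, 3.7, seed = 2)
    hp <- generate_hippocampus_mesh(120, 3.69, seed = 2, cortex_mesh = cx,
                                    axis_length_mm = 22)
    spb <- build_source_space(cx, hp)
    sens <- meg_helmet_array(60, helmet_radius_mm = cx$meta$sphere_radius + 18)
    .fixtures$small <- list(
      cortex = cx, hippocampus = hp,
      space_cortical = build_source_space(cx), space_combined = spb,
      sensors = sens,
      L_combined = assemble_leadfield(spb, sens))
  }
  .fixtures$small
}

# regular staggered-ring cylinder, open ends; analytic geodesics on the
# unrolled surface make it the reference for patch-weight checks
cylinder_mesh <- function(radius = 10, length = 40, spacing = 1) {
  nc <- round(2 * pi * radius / spacing)
  nz <- round(length / (spacing * sqrt(3) / 2)) + 1
  verts <- NULL
  for (i in seq_len(nz)) {
    phi <- 2 * pi * (seq_len(nc) - 1) / nc + (i %% 2) * pi / nc
    verts <- rbind(verts, cbind(radius * cos(phi), radius * sin(phi),
                                (i - 1) * length / (nz - 1)))
  }
  faces <- NULL
  for (i in seq_len(nz - 1)) {
    a <- (i - 1) * nc + seq_len(nc)
    b <- i * nc + seq_len(nc)
    a2 <- c(a[-1], a[1]); b2 <- c(b[-1], b[1])
    if (i %% 2 == 1) {
      # upper ring staggered half a step behind the lower one
      faces <- rbind(faces, cbind(a, b, b2), cbind(a, b2, a2))
    } else {
      faces <- rbind(faces, cbind(a, b, a2), cbind(a2, b, b2))
    }
  }
  refs <- cbind(0, 0, verts[, 3])
  surface_mesh(verts, faces, structure_label = "cortical",
               outward_ref = refs)
}
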