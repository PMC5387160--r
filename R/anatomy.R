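# Synthetic nested source-space anatomy: a cortical hemisphere shell and a
# deep, curved hippocampal tube, with matched mesh spacing, outward normals
# (dipole orientations), Gaussian geodesic patches, and the rigid
# shift/rotation control transforms used for mis-specified-anatomy models.

# make face winding consistent with outward references (one ref per vertex)
orient_faces <- function(vertices, faces, refs) {
  v1 <- vertices[faces[, 1], , drop = FALSE]
  v2 <- vertices[faces[, 2], , drop = FALSE]
  v3 <- vertices[faces[, 3], , drop = FALSE]
  fn <- cbind((v2 - v1)[, 2] * (v3 - v1)[, 3] - (v2 - v1)[, 3] * (v3 - v1)[, 2],
              (v2 - v1)[, 3] * (v3 - v1)[, 1] - (v2 - v1)[, 1] * (v3 - v1)[, 3],
              (v2 - v1)[, 1] * (v3 - v1)[, 2] - (v2 - v1)[, 2] * (v3 - v1)[, 1])
  fr <- (refs[faces[, 1], , drop = FALSE] + refs[faces[, 2], , drop = FALSE] +
         refs[faces[, 3], , drop = FALSE]) / 3
  fc <- (v1 + v2 + v3) / 3
  flip <- rowSums(fn * (fc - fr)) < 0
  faces[flip, ] <- faces[flip, c(1, 3, 2)]
  faces
}

#' Generate a synthetic cortical hemisphere mesh
#'
#' Builds a one-hemisphere shell of near-uniform triangle spacing: latitude
#' rings on a sphere of radius chosen so that `n_target_vertices` vertices
#' at `spacing_mm` tile the hemisphere area, plus a smooth low-amplitude
#' radial perturbation (a few percent) that tilts the vertex normals away
#' from the radial direction, mimicking the orientation variability of a
#' folded cortical sheet. Dipole orientations are the outward unit normals.
#'
#' The hemisphere occupies z >= 0 with the best-fit sphere centred at the
#' head-frame origin.
#'
#' @param n_target_vertices exact number of vertices to produce (>= 100).
#' @param spacing_mm target mean inter-vertex (edge) spacing in mm.
#' @param seed integer seed; the mesh is deterministic given the seed.
#' @param perturb_amp relative amplitude of the radial perturbation.
#' @return a [surface_mesh()] with `structure_label = "cortical"`.
#' @examples
#' cx <- generate_cortex_mesh(400, 3.7, seed = 1)
#' mean(edge_lengths(cx))
#' @export
generate_cortex_mesh <- function(n_target_vertices, spacing_mm, seed,
                                 perturb_amp = 0.07) {
  n <- as.integer(n_target_vertices)
  if (n < 100L) stop("n_target_vertices must be >= 100")
  if (spacing_mm <= 0) stop("spacing_mm must be positive")
  # hemisphere area 2*pi*R^2 = n * (sqrt(3)/2) * s^2  (hex lattice area/vertex)
  R <- spacing_mm * sqrt(n * sqrt(3) / (4 * pi))
  dm <- spacing_mm * sqrt(3) / 2          # meridian ring separation
  m <- round((R * pi / 2) / dm)
  if (m < 3)
    stop(sprintf("infeasible combination: %d vertices at %.2f mm spacing gives only %d latitude rings",
                 n, spacing_mm, m))
  theta <- seq_len(m) * (pi / 2) / m
  frac <- 2 * pi * R * sin(theta) / spacing_mm
  counts <- allocate_counts(frac, n - 1L)   # apex takes one vertex

  with_seed(seed, {
    # smooth radial "folding" field, vanishing at the apex; the angular
    # frequencies and amplitude are set so vertex normals tilt ~20-25
    # degrees from the radial direction on average (folded-sheet
    # orientation variability) while the mean edge length stays inside
    # the 15% spacing tolerance
    nb <- 6L
    a_k <- rnorm(nb, 0, 1); a_k <- a_k / sqrt(sum(a_k^2))
    l_k <- sample(6:14, nb, replace = TRUE)
    m_k <- sample(4:10, nb, replace = TRUE)
    p_k <- runif(nb, 0, 2 * pi)
    pert <- function(th, ph) {
      f <- 0
      for (k in seq_len(nb))
        f <- f + a_k[k] * sin(l_k[k] * ph + p_k[k]) * sin(m_k[k] * th)
      f
    }
    verts <- matrix(0, n, 3)
    verts[1, ] <- c(0, 0, R)                 # apex
    ring_idx <- vector("list", m)
    ring_ang <- vector("list", m)
    at <- 2L
    for (i in seq_len(m)) {
      ni <- counts[i]
      off <- (i %% 2) * pi / ni              # stagger alternate rings
      phi <- 2 * pi * (seq_len(ni) - 1) / ni + off
      r <- R * (1 + perturb_amp * pert(theta[i], phi))
      idx <- at:(at + ni - 1L)
      verts[idx, ] <- cbind(r * sin(theta[i]) * cos(phi),
                            r * sin(theta[i]) * sin(phi),
                            r * cos(theta[i]))
      ring_idx[[i]] <- idx
      ring_ang[[i]] <- phi
      at <- at + ni
    }
  })
  faces <- apex_fan(1L, ring_idx[[1]], ring_ang[[1]])
  for (i in seq_len(m - 1))
    faces <- rbind(faces, stitch_loops(ring_ang[[i]], ring_idx[[i]],
                                       ring_ang[[i + 1]], ring_idx[[i + 1]]))
  refs <- matrix(0, n, 3)                    # outward = away from origin
  faces <- orient_faces(verts, faces, refs)
  mesh <- surface_mesh(verts, faces, structure_label = "cortical",
                       target_spacing_mm = spacing_mm, outward_ref = refs)
  mesh$meta <- list(sphere_center = c(0, 0, 0), sphere_radius = R, seed = seed)
  mesh
}

# capsule meridian profile: tube radius at arc position t along a
# centreline of length L with cap radius r (caps at both ends)
capsule_profile <- function(t, L, r) {
  ifelse(t < r, sqrt(pmax(r^2 - (r - t)^2, 0)),
         ifelse(t > L - r, sqrt(pmax(r^2 - (t - (L - r))^2, 0)), r))
}

#' Generate a synthetic hippocampus-like mesh
#'
#' Builds a curved capsule ("banana") surface: cross-section rings along a
#' planar circular arc of tip-to-tip centreline length `axis_length_mm`,
#' closed by spherical caps, with the tube radius derived from the vertex
#' budget so that the mean edge length matches `spacing_mm`. The mesh is
#' nested deep inside the paired cortical shell; generation fails if any
#' vertex escapes the shell by more than `bulge_allowance_mm`.
#'
#' @param n_target_vertices exact vertex count (paper-scale preset: 162).
#' @param spacing_mm target mean edge spacing (mm).
#' @param centroid_depth_mm depth of the tube centroid below the cortical
#'   shell radius; `NULL` uses half the cortical radius.
#' @param seed integer seed (ring stagger phases).
#' @param cortex_mesh the paired cortical mesh (for placement and nesting
#'   checks); `NULL` leaves the tube centred at the origin.
#' @param axis_length_mm tip-to-tip centreline length (default 50 mm, the
#'   adult-human scale of the structure).
#' @param bend_deg total in-plane curvature of the centreline arc.
#' @param bulge_allowance_mm tolerated protrusion beyond the shell.
#' @return a [surface_mesh()] with `structure_label = "hippocampal"`.
#' @export
generate_hippocampus_mesh <- function(n_target_vertices, spacing_mm,
                                      centroid_depth_mm = NULL, seed = 1L,
                                      cortex_mesh = NULL,
                                      axis_length_mm = 50,
                                      bend_deg = 60,
                                      bulge_allowance_mm = 2) {
  n <- as.integer(n_target_vertices)
  if (n < 20L) stop("n_target_vertices must be >= 20")
  if (spacing_mm <= 0) stop("spacing_mm must be positive")
  L <- axis_length_mm
  # capsule area is exactly 2*pi*r*L; match the lattice area budget
  r <- n * (sqrt(3) / 2) * spacing_mm^2 / (2 * pi * L)
  if (2 * r >= L) stop("infeasible: tube radius exceeds half the axis length")

  # meridian (apex-to-apex along the surface): L + (pi - 2) * r
  M_len <- L + (pi - 2) * r
  dm <- spacing_mm * sqrt(3) / 2
  m <- max(3L, round(M_len / dm) - 1L)
  s_mer <- seq_len(m) * M_len / (m + 1L)     # interior ring meridian positions
  # meridian position -> centreline arc position t
  mer_to_t <- function(s) {
    ifelse(s < r * pi / 2, r * (1 - cos(s / r)),
           ifelse(s > M_len - r * pi / 2,
                  L - r * (1 - cos((M_len - s) / r)),
                  s - r * (pi / 2 - 1)))
  }
  t_j <- mer_to_t(s_mer)
  rho_j <- capsule_profile(t_j, L, r)
  counts <- allocate_counts(pmax(2 * pi * rho_j / spacing_mm, 3), n - 2L)

  # planar arc centreline (x-z plane), curvature radius Rc
  bend <- bend_deg * pi / 180
  Rc <- if (bend > 1e-6) L / bend else Inf
  cl_pos <- function(t) {
    if (is.infinite(Rc)) cbind(t, 0, 0)
    else cbind(Rc * sin(t / Rc), 0, Rc * (1 - cos(t / Rc)))
  }
  cl_tan <- function(t) {
    if (is.infinite(Rc)) cbind(1, 0, 0)
    else cbind(cos(t / Rc), 0, sin(t / Rc))
  }
  verts <- matrix(0, n, 3)
  refs <- matrix(0, n, 3)
  verts[1, ] <- cl_pos(0); refs[1, ] <- cl_pos(min(r, L / 2))
  verts[n, ] <- cl_pos(L); refs[n, ] <- cl_pos(max(L - r, L / 2))
  ring_idx <- vector("list", m); ring_ang <- vector("list", m)
  with_seed(seed, phases <- runif(m, 0, 2 * pi))
  at <- 2L
  for (j in seq_len(m)) {
    nj <- counts[j]
    psi <- 2 * pi * (seq_len(nj) - 1) / nj + phases[j]
    ctr <- cl_pos(t_j[j]); tg <- cl_tan(t_j[j])
    # frame perpendicular to the tangent: in-plane normal and binormal (y)
    np <- c(-tg[3], 0, tg[1]); bn <- c(0, 1, 0)
    idx <- at:(at + nj - 1L)
    verts[idx, ] <- matrix(ctr, nj, 3, byrow = TRUE) +
      rho_j[j] * (cos(psi) %o% np + sin(psi) %o% bn)
    refs[idx, ] <- matrix(ctr, nj, 3, byrow = TRUE)
    ring_idx[[j]] <- idx; ring_ang[[j]] <- psi %% (2 * pi)
    at <- at + nj
  }
  faces <- apex_fan(1L, ring_idx[[1]], ring_ang[[1]])
  for (j in seq_len(m - 1))
    faces <- rbind(faces, stitch_loops(ring_ang[[j]], ring_idx[[j]],
                                       ring_ang[[j + 1]], ring_idx[[j + 1]]))
  faces <- rbind(faces, apex_fan(n, ring_idx[[m]], ring_ang[[m]]))

  # place in the head frame: long axis horizontal, arc opening downwards,
  # centroid at the requested depth below the cortical shell
  Rot <- rotation_about_axis(c(1, 0, 0), -90) %*%
         rotation_about_axis(c(0, 0, 1), 25)
  ctd <- colMeans(verts)
  if (!is.null(cortex_mesh)) {
    Rcx <- cortex_mesh$meta$sphere_radius %||% mean(row_norms(cortex_mesh$vertices))
    depth <- centroid_depth_mm %||% (0.5 * Rcx)
    dir <- unit(c(0.40, 0.15, 0.90))
    target <- dir * (Rcx - depth)
  } else {
    target <- c(0, 0, 0)
  }
  move <- function(p) sweep(sweep(p, 2, ctd) %*% t(Rot), 2, target, `+`)
  verts <- move(verts); refs <- move(refs)

  faces <- orient_faces(verts, faces, refs)
  mesh <- surface_mesh(verts, faces, structure_label = "hippocampal",
                       target_spacing_mm = spacing_mm, outward_ref = refs)
  mesh$meta <- list(tube_radius = r, axis_length_mm = L, bend_deg = bend_deg,
                    centroid = colMeans(verts), seed = seed,
                    apex_vertices = c(1L, n))
  if (!is.null(cortex_mesh)) {
    shell <- min(row_norms(cortex_mesh$vertices))
    over <- row_norms(mesh$vertices) - (shell - 1)
    if (any(over > bulge_allowance_mm))
      stop(sprintf("hippocampal tube protrudes %.1f mm beyond the cortical shell",
                   max(over)))
  }
  mesh
}

#' Smooth and decimate a mesh to a target mean edge spacing
#'
#' Iterative shortest-edge collapse (endpoints merged at their midpoint)
#' until the mean edge length reaches the target, followed by a few
#' shape-preserving Taubin smoothing passes. Graph connectivity is
#' preserved by construction.
#'
#' @param mesh a `surface_mesh` denser than the target.
#' @param target_spacing_mm desired mean edge length (mm); the result is
#'   within 5% of it.
#' @return a decimated `surface_mesh`.
#' @export
match_mesh_spacing <- function(mesh, target_spacing_mm) {
  stopifnot(inherits(mesh, "surface_mesh"), target_spacing_mm > 0)
  if (mean(edge_lengths(mesh)) >= 0.95 * target_spacing_mm)
    return(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  repeat {
    e <- cbind(pmin(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])[, 1],
                    rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])[, 2]),
               pmax(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])[, 1],
                    rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])[, 2]))
    e <- unique(e)
    len <- row_norms(v[e[, 1], , drop = FALSE] - v[e[, 2], , drop = FALSE])
    # stop slightly above target: the smoothing pass below contracts the
    # mean edge length by ~2%
    if (mean(len) >= 1.01 * target_spacing_mm) break
    if (nrow(v) <= 8L)
      stop("target spacing coarser than the mesh extent supports")
    k <- which.min(len)
    a <- e[k, 1]; b <- e[k, 2]
    v[a, ] <- (v[a, ] + v[b, ]) / 2
    f[f == b] <- a
    keep <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
    f <- f[keep, , drop = FALSE]
    used <- sort(unique(as.vector(f)))
    remap <- integer(nrow(v)); remap[used] <- seq_along(used)
    v <- v[used, , drop = FALSE]
    f <- matrix(remap[f], ncol = 3)
  }
  # Taubin lambda/mu smoothing: shape fairing without shrinkage
  adj <- lapply(seq_len(nrow(v)), function(i) integer(0))
  e <- unique(cbind(pmin(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])[, 1],
                         rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])[, 2]),
                    pmax(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])[, 1],
                         rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])[, 2])))
  for (i in seq_len(nrow(e))) {
    adj[[e[i, 1]]] <- c(adj[[e[i, 1]]], e[i, 2])
    adj[[e[i, 2]]] <- c(adj[[e[i, 2]]], e[i, 1])
  }
  lap <- function(vv) {
    d <- vv
    for (i in seq_len(nrow(vv)))
      d[i, ] <- colMeans(vv[adj[[i]], , drop = FALSE]) - vv[i, ]
    d
  }
  for (it in 1:5) {
    v <- v + 0.33 * lap(v)
    v <- v - 0.34 * lap(v)
  }
  out <- surface_mesh(v, f, structure_label = mesh$structure_label,
                      target_spacing_mm = target_spacing_mm,
                      outward_ref = matrix(colMeans(v), nrow(v), 3, byrow = TRUE))
  out$meta <- mesh$meta
  out
}

#' Gaussian geodesic patch weights
#'
#' Spatial profile of a locally coherent source patch: a Gaussian in
#' graph-geodesic distance from the seed vertex, `w(v) =
#' exp(-d(v)^2 / (2 sigma^2))` with `sigma = fwhm / sqrt(8 log 2)`.
#' Weights below `trunc` times the peak are truncated to zero, giving a
#' sparse support.
#'
#' @param mesh a `surface_mesh`.
#' @param seed_vertex patch centre (vertex index).
#' @param fwhm_mm spatial full-width half-maximum in mm.
#' @param trunc truncation threshold relative to the peak weight.
#' @return object of class `patch_weights`: list with `seed_vertex`,
#'   `weights` (full-length vector, zeros outside the support) and
#'   `fwhm_mm`.
#' @export
patch_weights <- function(mesh, seed_vertex, fwhm_mm, trunc = 1e-3) {
  stopifnot(inherits(mesh, "surface_mesh"))
  nv <- nrow(mesh$vertices)
  if (seed_vertex < 1 || seed_vertex > nv) stop("seed_vertex out of range")
  if (fwhm_mm <= 0) stop("fwhm_mm must be positive")
  d <- geodesic_distances(mesh, seed_vertex)[1, ]
  if (any(!is.finite(d)))
    warning("mesh is disconnected; patch confined to the seed's component")
  sigma <- fwhm_mm / sqrt(8 * log(2))
  w <- exp(-d^2 / (2 * sigma^2))
  w[!is.finite(d)] <- 0
  w[w < trunc * max(w)] <- 0
  structure(list(seed_vertex = as.integer(seed_vertex), weights = w,
                 fwhm_mm = fwhm_mm),
            class = "patch_weights")
}

## source spaces ------------------------------------------------------------

#' Assemble a source space from anatomical meshes
#'
#' A cortical source space holds the cortical mesh alone; a combined space
#' appends a hippocampal mesh after the identical cortical mesh, so the
#' cortical vertex block (and later the cortical lead-field block) is
#' bit-identical between the two anatomical models.
#'
#' @param cortex a cortical `surface_mesh`.
#' @param hippocampus optional hippocampal `surface_mesh`.
#' @return object of class `source_space` with fields `meshes`,
#'   `vertex_offset` (1-based start index of each mesh in the concatenated
#'   vertex list) and `anatomy_kind` (`"cortical"` or `"combined"`).
#' @export
build_source_space <- function(cortex, hippocampus = NULL) {
  stopifnot(inherits(cortex, "surface_mesh"),
            cortex$structure_label == "cortical")
  meshes <- list(cortex)
  if (!is.null(hippocampus)) {
    stopifnot(inherits(hippocampus, "surface_mesh"),
              hippocampus$structure_label == "hippocampal")
    meshes <- c(meshes, list(hippocampus))
  }
  nv <- vapply(meshes, function(m) nrow(m$vertices), integer(1))
  structure(list(meshes = meshes,
                 vertex_offset = cumsum(c(1L, nv))[seq_along(meshes)],
                 anatomy_kind = if (length(meshes) == 2L) "combined" else "cortical"),
            class = "source_space")
}

#' @export
print.source_space <- function(x, ...) {
  cat(sprintf("<source_space: %s, %d vertices (%s)>\n", x$anatomy_kind,
              n_sources(x),
              paste(vapply(x$meshes, function(m) nrow(m$vertices), integer(1)),
                    collapse = " + ")))
  invisible(x)
}

#' Total number of source vertices in a space
#' @param space a `source_space`.
#' @return integer count.
#' @export
n_sources <- function(space) {
  sum(vapply(space$meshes, function(m) nrow(m$vertices), integer(1)))
}

#' Concatenated vertex (and normal) arrays of a source space
#' @param space a `source_space`.
#' @return list with `vertices` and `normals` matrices (n_sources x 3).
#' @export
space_vertices <- function(space) {
  list(vertices = do.call(rbind, lapply(space$meshes, `[[`, "vertices")),
       normals = do.call(rbind, lapply(space$meshes, `[[`, "normals")))
}

#' Structure label of each concatenated source index
#' @param space a `source_space`.
#' @return character vector (`"cortical"`/`"hippocampal"`) of length
#'   `n_sources(space)`.
#' @export
source_structures <- function(space) {
  unlist(lapply(space$meshes, function(m)
    rep(m$structure_label, nrow(m$vertices))))
}

#' Map a hippocampal mesh vertex to its concatenated-space index
#' @param space a combined `source_space`.
#' @param vertex vertex index within the hippocampal mesh.
#' @return index into the concatenated source list.
#' @export
hippocampal_index <- function(space, vertex) {
  if (space$anatomy_kind != "combined") stop("requires a combined source space")
  space$vertex_offset[2] + as.integer(vertex) - 1L
}

#' Rigidly displace or rotate the hippocampal mesh of a combined space
#'
#' Control transform for mis-specified anatomical models: the cortical
#' portion is left untouched while the hippocampal vertices are shifted by
#' `shift_mm` or rotated by `rotation_deg` about the hippocampal centroid
#' (normals rotated consistently). Exactly one of `shift_mm` /
#' `rotation_deg` may be non-trivial.
#'
#' @param space a combined `source_space`.
#' @param shift_mm length-3 displacement in mm.
#' @param rotation_deg rotation angle in degrees.
#' @param axis rotation axis (default axial, i.e. the z axis).
#' @return a new combined `source_space`.
#' @export
transform_hippocampus <- function(space, shift_mm = c(0, 0, 0),
                                  rotation_deg = 0, axis = c(0, 0, 1)) {
  if (!inherits(space, "source_space") || space$anatomy_kind != "combined")
    stop("transform_hippocampus requires a combined source space")
  hip <- space$meshes[[2]]
  v <- hip$vertices
  nrm <- hip$normals
  if (abs(rotation_deg) > 0) {
    Rm <- rotation_about_axis(axis, rotation_deg)
    ctd <- colMeans(v)
    v <- sweep(sweep(v, 2, ctd) %*% t(Rm), 2, ctd, `+`)
    nrm <- nrm %*% t(Rm)
  }
  v <- sweep(v, 2, as.numeric(shift_mm), `+`)
  hip$vertices <- v
  hip$normals <- nrm
  if (!is.null(hip$meta$centroid)) hip$meta$centroid <- colMeans(v)
  out <- space
  out$meshes[[2]] <- hip
  out
}

#' The 24-model shifted-hippocampus battery
#'
#' All combinations of shift magnitude {5, 10, 15, 20} mm, axis {x, y, z}
#' and direction {+, -} applied to the hippocampal portion of a combined
#' space: 24 distinct mis-specified anatomical models.
#'
#' @param space a combined `source_space`.
#' @param magnitudes_mm shift magnitudes (default `c(5, 10, 15, 20)`).
#' @return named list of 24 `source_space` objects; names encode the shift
#'   (e.g. `"x+10"`).
#' @export
shifted_hippocampus_models <- function(space, magnitudes_mm = c(5, 10, 15, 20)) {
  out <- list()
  for (ax in 1:3) for (sg in c(1, -1)) for (mg in magnitudes_mm) {
    sh <- c(0, 0, 0); sh[ax] <- sg * mg
    nm <- sprintf("%s%s%g", c("x", "y", "z")[ax], ifelse(sg > 0, "+", "-"), mg)
    out[[nm]] <- transform_hippocampus(space, shift_mm = sh)
  }
  out
}

#' Euclidean-nearest cortical neighbour of each hippocampal vertex
#'
#' @param space a combined `source_space`.
#' @param hippocampal_vertices indices within the hippocampal mesh
#'   (default: all).
#' @return data.frame with `hippocampal_index`, `cortical_index` (indices
#'   within their respective meshes) and `distance_mm`.
#' @export
nearest_cortical_neighbours <- function(space, hippocampal_vertices = NULL) {
  if (space$anatomy_kind != "combined") stop("requires a combined source space")
  hv <- space$meshes[[2]]$vertices
  cv <- space$meshes[[1]]$vertices
  idx <- hippocampal_vertices %||% seq_len(nrow(hv))
  idx <- as.integer(idx)
  if (any(idx < 1 | idx > nrow(hv))) stop("hippocampal vertex index out of range")
  cn <- integer(length(idx)); dd <- numeric(length(idx))
  c2 <- rowSums(cv^2)
  for (k in seq_along(idx)) {
    p <- hv[idx[k], ]
    d2 <- c2 - 2 * as.vector(cv %*% p) + sum(p^2)
    j <- which.min(d2)
    cn[k] <- j
    dd[k] <- sqrt(max(d2[j], 0))
  }
  data.frame(hippocampal_index = idx, cortical_index = cn, distance_mm = dd)
}
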