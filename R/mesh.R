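# SurfaceMesh container and low-level triangulated-mesh machinery.
#
# Meshes are built from stacked rings of vertices (latitude rings on the
# hemisphere, cross-section rings along the hippocampal tube). Adjacent
# rings with arbitrary point counts are stitched by an angular merge that
# always yields a valid, connected triangle band.

#' Construct a SurfaceMesh
#'
#' @param vertices numeric matrix (n x 3), positions in mm, head frame.
#' @param faces integer matrix (m x 3), 1-based triangle vertex indices.
#' @param normals numeric matrix (n x 3) of unit vectors, or NULL to
#'   compute area-weighted vertex normals oriented by `outward_ref`.
#' @param structure_label `"cortical"` or `"hippocampal"`.
#' @param target_spacing_mm the edge-length scale the generator aimed for
#'   (used by the validity audit), or NA.
#' @param outward_ref per-vertex reference points (n x 3) such that the
#'   outward normal satisfies dot(normal, vertex - ref) > 0; defaults to
#'   the mesh centroid for every vertex.
#' @return object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, normals = NULL,
                         structure_label = c("cortical", "hippocampal"),
                         target_spacing_mm = NA_real_,
                         outward_ref = NULL) {
  structure_label <- match.arg(structure_label)
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3)
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range")
  if (is.null(normals)) {
    if (is.null(outward_ref)) {
      ctr <- colMeans(vertices)
      outward_ref <- matrix(ctr, nrow(vertices), 3, byrow = TRUE)
    }
    normals <- vertex_normals(vertices, faces, outward_ref)
  }
  structure(list(vertices = unname(vertices),
                 faces = unname(faces),
                 normals = unname(as.matrix(normals)),
                 structure_label = structure_label,
                 target_spacing_mm = target_spacing_mm),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh: %s, %d vertices, %d faces, mean edge %.2f mm>\n",
              x$structure_label, nrow(x$vertices), nrow(x$faces),
              mean(edge_lengths(x))))
  invisible(x)
}

#' Unique undirected edges of a mesh
#'
#' @param mesh a `surface_mesh`.
#' @return integer matrix (n_edges x 2), each row sorted.
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Lengths of all unique mesh edges (mm)
#'
#' @param mesh a `surface_mesh`.
#' @return numeric vector of edge lengths.
#' @export
edge_lengths <- function(mesh) {
  e <- mesh_edges(mesh)
  row_norms(mesh$vertices[e[, 1], , drop = FALSE] -
            mesh$vertices[e[, 2], , drop = FALSE])
}

# igraph over mesh connectivity, edges weighted by euclidean length
mesh_graph <- function(mesh) {
  e <- mesh_edges(mesh)
  w <- row_norms(mesh$vertices[e[, 1], , drop = FALSE] -
                 mesh$vertices[e[, 2], , drop = FALSE])
  g <- igraph::make_empty_graph(n = nrow(mesh$vertices), directed = FALSE)
  g <- igraph::add_edges(g, as.vector(t(e)))
  igraph::E(g)$weight <- w
  g
}

#' Graph-geodesic distances from seed vertices
#'
#' Shortest-path distance over the mesh edge graph with euclidean edge
#' weights; a cheap, standard stand-in for exact polyhedral geodesics that
#' is adequate at the 3-4 mm mesh spacing used here.
#'
#' @param mesh a `surface_mesh`.
#' @param from integer vector of seed vertex indices.
#' @return matrix (length(from) x n_vertices) of distances in mm.
#' @export
geodesic_distances <- function(mesh, from) {
  g <- mesh_graph(mesh)
  igraph::distances(g, v = from, algorithm = "dijkstra")
}

#' Audit the structural invariants of a SurfaceMesh
#'
#' Checks unit normals, face-index validity, graph connectivity, and
#' (when a target spacing is recorded) that the mean edge length is within
#' 15% of it. Stops with an informative error on the first violation.
#'
#' @param mesh a `surface_mesh`.
#' @return invisibly TRUE.
#' @export
validate_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  nv <- nrow(mesh$vertices)
  if (any(!is.finite(mesh$vertices))) stop("non-finite vertex coordinates")
  nn <- row_norms(mesh$normals)
  if (any(abs(1 - nn) >= 1e-9)) stop("normals are not unit length")
  if (min(mesh$faces) < 1L || max(mesh$faces) > nv)
    stop("face indices out of vertex range")
  g <- mesh_graph(mesh)
  if (igraph::components(g)$no != 1L) stop("mesh graph is not connected")
  if (is.finite(mesh$target_spacing_mm)) {
    me <- mean(edge_lengths(mesh))
    if (abs(me - mesh$target_spacing_mm) > 0.15 * mesh$target_spacing_mm)
      stop(sprintf("mean edge length %.2f mm deviates >15%% from target %.2f mm",
                   me, mesh$target_spacing_mm))
  }
  invisible(TRUE)
}

## ring stitching -----------------------------------------------------------

# Triangulate the band between two vertex loops given their angular
# parameters (radians, need not be sorted identically) and global vertex
# indices. Walks both loops monotonically in angle, always connecting to
# the nearer next point, producing length(a) + length(b) triangles.
stitch_loops <- function(ang_a, idx_a, ang_b, idx_b) {
  na <- length(ang_a); nb <- length(ang_b)
  oa <- order(ang_a); ob <- order(ang_b)
  ang_a <- ang_a[oa]; idx_a <- idx_a[oa]
  ang_b <- ang_b[ob]; idx_b <- idx_b[ob]
  # rotate loop b so its first point is angularly closest to a's first
  d <- (ang_b - ang_a[1]) %% (2 * pi)
  d <- pmin(d, 2 * pi - d)
  s <- which.min(d)
  if (s > 1) {
    ang_b <- c(ang_b[s:nb], ang_b[1:(s - 1)])
    idx_b <- c(idx_b[s:nb], idx_b[1:(s - 1)])
  }
  # sequential unwrap to strictly increasing angles; loop b may start up
  # to half a turn behind loop a
  seq_unwrap <- function(x, start) {
    u <- numeric(length(x))
    u[1] <- start
    if (length(x) > 1)
      u[2:length(x)] <- start + cumsum((diff(x) %% (2 * pi)))
    u
  }
  ua <- seq_unwrap(ang_a, ang_a[1])
  ub <- seq_unwrap(ang_b, ang_a[1] + ((ang_b[1] - ang_a[1] + pi) %% (2 * pi)) - pi)
  faces <- matrix(0L, na + nb, 3)
  a <- 1L; b <- 1L; k <- 0L
  next_a <- function(a) if (a < na) ua[a + 1L] else ua[1L] + 2 * pi
  next_b <- function(b) if (b < nb) ub[b + 1L] else ub[1L] + 2 * pi
  while (a <= na || b <= nb) {
    adv_a <- if (a > na) FALSE else if (b > nb) TRUE else next_a(a) <= next_b(b)
    k <- k + 1L
    cur_a <- idx_a[(a - 1L) %% na + 1L]
    cur_b <- idx_b[(b - 1L) %% nb + 1L]
    if (adv_a) {
      faces[k, ] <- c(cur_a, cur_b, idx_a[a %% na + 1L])
      a <- a + 1L
    } else {
      faces[k, ] <- c(cur_a, cur_b, idx_b[b %% nb + 1L])
      b <- b + 1L
    }
  }
  faces[seq_len(k), , drop = FALSE]
}

# Fan triangles from an apex vertex to a full loop.
apex_fan <- function(apex_idx, idx_loop, ang_loop, invert = FALSE) {
  o <- order(ang_loop)
  idx <- idx_loop[o]
  n <- length(idx)
  f <- cbind(apex_idx, idx, idx[c(2:n, 1)])
  if (invert) f <- f[, c(1, 3, 2)]
  f
}

# Area-weighted per-vertex normals, flipped to point away from outward_ref.
vertex_normals <- function(vertices, faces, outward_ref) {
  v1 <- vertices[faces[, 1], , drop = FALSE]
  v2 <- vertices[faces[, 2], , drop = FALSE]
  v3 <- vertices[faces[, 3], , drop = FALSE]
  e1 <- v2 - v1; e2 <- v3 - v1
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])  # 2*area-weighted
  n <- matrix(0, nrow(vertices), 3)
  for (j in 1:3) {
    for (ax in 1:3) {
      acc <- tapply(fn[, ax], faces[, j], sum)
      ii <- as.integer(names(acc))
      n[ii, ax] <- n[ii, ax] + acc
    }
  }
  # orient outward, then normalize
  s <- sign(rowSums(n * (vertices - outward_ref)))
  s[s == 0] <- 1
  n <- n * s
  nn <- row_norms(n)
  if (any(nn == 0)) stop("degenerate vertex normal")
  n / nn
}

# Integer ring counts summing exactly to `total`, proportional to the
# fractional targets `frac`, each >= 3. Deterministic largest-residual
# apportionment.
allocate_counts <- function(frac, total) {
  n <- length(frac)
  if (total < 3L * n) stop("too few vertices for the requested ring count")
  counts <- pmax(3L, as.integer(floor(frac)))
  while (sum(counts) != total) {
    resid <- frac - counts
    if (sum(counts) < total) {
      i <- order(-resid, seq_len(n))[1]
      counts[i] <- counts[i] + 1L
    } else {
      ok <- which(counts > 3L)
      if (!length(ok)) stop("cannot reduce ring counts further")
      i <- ok[order(resid[ok], ok)][1]
      counts[i] <- counts[i] - 1L
    }
  }
  counts
}
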