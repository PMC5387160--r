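# Plain-text interchange: Wavefront OBJ meshes (vertices in mm), a
# whitespace-delimited sensor table, YAML experiment configs and CSV
# results tables.

#' Write a mesh as Wavefront OBJ
#'
#' Vertices (`v x y z`, mm) and 1-based triangle faces (`f i j k`).
#' Normals are recomputed on read, so only geometry is stored.
#'
#' @param mesh a `surface_mesh`.
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_mesh_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# hippomeg surface_mesh: %s", mesh$structure_label), con)
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}

#' Read a Wavefront OBJ mesh
#'
#' Reads `v` and (triangular) `f` records; face entries of the form
#' `i/j/k` are truncated to the vertex index.
#'
#' @param path OBJ file.
#' @param structure_label structure to tag the mesh with.
#' @param target_spacing_mm optional spacing for the validity audit.
#' @return a `surface_mesh`.
#' @export
read_mesh_obj <- function(path, structure_label = "cortical",
                          target_spacing_mm = NA_real_) {
  ln <- readLines(path)
  vl <- ln[startsWith(ln, "v ")]
  fl <- ln[startsWith(ln, "f ")]
  if (!length(vl) || !length(fl)) stop("no vertices or faces in OBJ file")
  verts <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x)
    as.numeric(x[2:4])))
  faces <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x)
    as.integer(sub("/.*$", "", x[2:4]))))
  surface_mesh(verts, faces, structure_label = structure_label,
               target_spacing_mm = target_spacing_mm)
}

#' Write a sensor array as a whitespace-delimited table
#'
#' Columns: name, x, y, z (mm), ox, oy, oz (unit orientation).
#'
#' @param sensors a `sensor_array`.
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_sensor_table <- function(sensors, path) {
  stopifnot(inherits(sensors, "sensor_array"))
  df <- data.frame(name = sensors$channel_names,
                   x = sensors$positions[, 1], y = sensors$positions[, 2],
                   z = sensors$positions[, 3],
                   ox = sensors$orientations[, 1],
                   oy = sensors$orientations[, 2],
                   oz = sensors$orientations[, 3])
  utils::write.table(df, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sensor table written by [write_sensor_table()]
#' @param path sensor table file.
#' @return a `sensor_array`.
#' @export
read_sensor_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  sensor_array(as.matrix(df[, c("x", "y", "z")]),
               as.matrix(df[, c("ox", "oy", "oz")]),
               df$name)
}

#' Read an experiment configuration from YAML
#'
#' Recognized keys match the arguments of [experiment_config()]; missing
#' keys fall back to the defaults.
#'
#' @param path YAML file.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read config files")
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(experiment_config)))]
  do.call(experiment_config, args)
}

#' Write a results table as RFC-4180 CSV
#' @param results a results `data.frame`.
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_results_csv <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}
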