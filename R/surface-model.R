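#' Triangulated bone surface model
#'
#' Container for the known shape model (the pre-operative model that sparse
#' surface points are registered to): vertices, triangular faces, named
#' vertex-region labels and a distal-proximal axis.
#'
#' Region labels are vertex index sets. When both an `accessible` and an
#' `inaccessible` region are present they must partition the vertices, and
#' every region whose name starts with `pre_` (a pre-registration area) must
#' be a subset of `accessible`.
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param regions Named list of integer vertex-index vectors (may be empty).
#' @param axis Unit length-3 distal-proximal axis; computed by
#'   [principal_axis()] when `NULL`.
#' @param axis_point Point on the axis (mm); vertex centroid when `NULL`.
#' @return An object of class `surface_model`.
#' @export
surface_model <- function(vertices, faces, regions = list(), axis = NULL,
                          axis_point = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3) abort("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3) abort("faces must be an m x 3 matrix")
  if (nrow(vertices) < 4 || nrow(faces) < 4) {
    abort("a closed triangulated surface needs at least 4 vertices and 4 faces")
  }
  if (anyNA(vertices) || any(!is.finite(vertices))) {
    abort("vertex coordinates must be finite")
  }
  if (anyNA(faces) || min(faces) < 1 || max(faces) > nrow(vertices)) {
    abort("face indices must address existing vertices")
  }
  nv <- nrow(vertices)
  for (nm in names(regions)) {
    idx <- regions[[nm]]
    if (length(idx) > 0 && (min(idx) < 1 || max(idx) > nv)) {
      abort(paste0("region '", nm, "' indexes vertices outside the mesh"))
    }
    regions[[nm]] <- as.integer(sort(unique(idx)))
  }
  model <- structure(
    list(vertices = vertices, faces = faces, regions = regions,
         axis = NULL, axis_point = NULL, .cache = new.env(parent = emptyenv())),
    class = "surface_model")
  if (is.null(axis)) {
    pa <- principal_axis(model)
    axis <- pa$axis
    if (is.null(axis_point)) axis_point <- pa$axis_point
  }
  axis <- as.double(axis)
  n <- sqrt(sum(axis^2))
  if (abs(n - 1) > 1e-12) axis <- axis / n
  if (is.null(axis_point)) axis_point <- colMeans(vertices)
  model$axis <- axis
  model$axis_point <- as.double(axis_point)
  check_region_structure(model)
  model
}

check_region_structure <- function(model) {
  reg <- model$regions
  if (all(c("accessible", "inaccessible") %in% names(reg))) {
    nv <- nrow(model$vertices)
    if (length(intersect(reg$accessible, reg$inaccessible)) > 0 ||
        length(union(reg$accessible, reg$inaccessible)) != nv) {
      abort("'accessible' and 'inaccessible' must partition the vertices")
    }
    for (nm in grep("^pre_", names(reg), value = TRUE)) {
      if (!all(reg[[nm]] %in% reg$accessible)) {
        abort(paste0("pre-registration region '", nm,
                     "' must lie inside the accessible area"))
      }
    }
  }
  invisible(model)
}

#' @export
print.surface_model <- function(x, ...) {
  cat(sprintf("<surface_model> %d vertices, %d faces, %d labeled regions\n",
              nrow(x$vertices), nrow(x$faces), length(x$regions)))
  cat(sprintf("  axis (%.3f, %.3f, %.3f) through (%.1f, %.1f, %.1f) mm\n",
              x$axis[1], x$axis[2], x$axis[3],
              x$axis_point[1], x$axis_point[2], x$axis_point[3]))
  invisible(x)
}

# k-d tree over vertices, built lazily and cached (external pointers do not
# survive serialization, so rebuild when the pointer is stale).
vertex_tree <- function(model) {
  tr <- model$.cache$tree
  ok <- !is.null(tr) &&
    !inherits(try(cpp_kd_query(tr, model$vertices[1, , drop = FALSE]),
                  silent = TRUE), "try-error")
  if (!ok) {
    tr <- cpp_kd_build(model$vertices)
    model$.cache$tree <- tr
  }
  tr
}

#' Closest points on a surface model
#'
#' For each query point returns the closest point on the model, either the
#' nearest mesh vertex found through a k-d tree (`mode = "vertex"`, the
#' default, appropriate for dense meshes) or the exact nearest point on any
#' triangle (`mode = "triangle"`, unbiased on coarse meshes).
#'
#' @param model A [surface_model()].
#' @param points Query points: data frame with `x`, `y`, `z` or an n x 3
#'   matrix.
#' @param mode `"vertex"` or `"triangle"`.
#' @return A tibble with the query coordinates, the closest surface point
#'   (`cx`, `cy`, `cz`), the Euclidean `distance` (mm) and the vertex or
#'   face `index`.
#' @export
closest_points <- function(model, points, mode = c("vertex", "triangle")) {
  mode <- match.arg(mode)
  q <- as_point_matrix(points)
  res <- closest_points_mat(model, q, mode)
  tibble::tibble(x = q[, 1], y = q[, 2], z = q[, 3],
                 cx = res$point[, 1], cy = res$point[, 2], cz = res$point[, 3],
                 distance = res$distance, index = res$index)
}

# matrix fast path shared by the registration loops
closest_points_mat <- function(model, q, mode) {
  tr <- vertex_tree(model)
  if (mode == "vertex") {
    hit <- cpp_kd_query(tr, q)
    list(point = model$vertices[hit$index, , drop = FALSE],
         distance = hit$distance, index = hit$index)
  } else {
    hit <- cpp_closest_triangle(model$vertices, model$faces - 1L, q, tr)
    list(point = hit$point, distance = hit$distance, index = hit$face)
  }
}

#' Distal-proximal axis by principal component analysis
#'
#' The axis is the first principal component of the vertex cloud, with the
#' sign fixed so its z component is non-negative (if the z component is zero,
#' the x component is made non-negative). The axis point is the vertex
#' centroid.
#'
#' @param model A [surface_model()] (or any list with a `vertices` matrix).
#' @return A list with unit `axis` and `axis_point` (mm).
#' @export
principal_axis <- function(model) {
  v <- model$vertices
  ctr <- colMeans(v)
  vc <- sweep(v, 2, ctr)
  if (max(abs(vc)) < 1e-12) abort("degenerate mesh: all vertices coincide")
  ax <- svd(vc, nu = 0, nv = 1)$v[, 1]
  ax <- ax / sqrt(sum(ax^2))
  if (ax[3] < 0 || (ax[3] == 0 && ax[1] < 0) ||
      (ax[3] == 0 && ax[1] == 0 && ax[2] < 0)) {
    ax <- -ax
  }
  list(axis = ax, axis_point = ctr)
}

#' Centroid of a labeled region
#'
#' @param model A [surface_model()].
#' @param region Region name.
#' @return Length-3 centroid (mm) of the region's vertices.
#' @export
region_centroid <- function(model, region) {
  idx <- model$regions[[region]]
  if (is.null(idx) || length(idx) == 0) {
    abort(paste0("model has no vertices labeled '", region, "'"))
  }
  colMeans(model$vertices[idx, , drop = FALSE])
}

#' Read and write region-label sidecar files
#'
#' STL carries no labels, so region labels live in a sidecar JSON mapping
#' region name to 1-based vertex indices.
#'
#' @param model A [surface_model()].
#' @param path File path.
#' @return `read_labels` returns a named list of integer vectors.
#' @export
write_labels <- function(model, path) {
  jsonlite::write_json(model$regions, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  lapply(obj, as.integer)
}
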