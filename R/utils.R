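#' Coerce a point table to a numeric matrix
#'
#' Accepts any data frame with `x`, `y`, `z` columns (mm) or a bare 3-column
#' numeric matrix and returns an n x 3 matrix.
#'
#' @param points Data frame with columns `x`, `y`, `z`, or an n x 3 matrix.
#' @return An n x 3 numeric matrix.
#' @keywords internal
#' @noRd
as_point_matrix <- function(points) {
  if (is.matrix(points)) {
    if (ncol(points) != 3) abort("point matrix must have 3 columns")
    m <- points
  } else if (is.data.frame(points)) {
    miss <- setdiff(c("x", "y", "z"), names(points))
    if (length(miss) > 0) {
      abort(paste0("point table is missing column(s): ",
                   paste(miss, collapse = ", ")))
    }
    m <- cbind(points$x, points$y, points$z)
  } else {
    abort("points must be a data frame with x, y, z columns or an n x 3 matrix")
  }
  storage.mode(m) <- "double"
  if (anyNA(m) || any(!is.finite(m))) abort("point coordinates must be finite")
  dimnames(m) <- NULL
  m
}

# Rebuild a point tibble around new coordinates, carrying label/uple through.
rebuild_points <- function(points, coords) {
  out <- tibble::tibble(x = coords[, 1], y = coords[, 2], z = coords[, 3])
  if (is.data.frame(points)) {
    for (col in intersect(c("label", "uple"), names(points))) {
      out[[col]] <- points[[col]]
    }
  }
  out
}

#' Derive a reproducible trial seed from a master seed and counters
#'
#' Counter-based hashing (repeated LCG absorption of each counter) so that
#' adding new factor levels never perturbs the seeds of existing trials.
#' The result is a non-negative integer below 2^31 - 1.
#'
#' @param master_seed Integer master seed.
#' @param ... Integer counters (factor indices, repeat index, ...).
#' @return A single integer seed.
#' @export
derive_seed <- function(master_seed, ...) {
  vals <- c(master_seed, ...)
  if (any(!is.finite(vals))) abort("seed counters must be finite")
  m <- 2147483647  # 2^31 - 1
  h <- 17
  for (v in vals) {
    v <- as.double(v) %% m
    h <- (h * 48271 + v + 1) %% m
    h <- (h * 69621 + 7) %% m
  }
  as.integer(h)
}

deg2rad <- function(deg) deg * pi / 180
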