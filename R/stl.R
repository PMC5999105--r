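#' Read a surface model from an STL file
#'
#' Both binary and ASCII STL dialects are detected and parsed. STL stores a
#' triangle soup; duplicate vertices are merged by exact coordinate match so
#' the result is an indexed mesh. Labels, if present, are read from a sidecar
#' JSON next to the file (see [write_labels()]).
#'
#' @param path Path to the STL file.
#' @param labels Optional path to a region-label sidecar JSON; defaults to
#'   `<path>.labels.json` when that file exists.
#' @return A [surface_model()].
#' @export
read_stl <- function(path, labels = NULL) {
  if (!file.exists(path)) abort(paste0("STL file not found: ", path))
  raw <- readBin(path, "raw", n = file.size(path))
  soup <- if (is_ascii_stl(raw)) parse_stl_ascii(raw, path) else
    parse_stl_binary(raw, path)
  mesh <- index_triangle_soup(soup)
  if (is.null(labels)) {
    cand <- paste0(path, ".labels.json")
    if (file.exists(cand)) labels <- cand
  }
  regions <- if (!is.null(labels)) read_labels(labels) else list()
  surface_model(mesh$vertices, mesh$faces, regions = regions)
}

#' Write a surface model to an STL file
#'
#' @param model A [surface_model()].
#' @param path Output path.
#' @param ascii Write the ASCII dialect instead of binary.
#' @param labels Optional path for the region-label sidecar JSON; labels are
#'   written whenever the model has any.
#' @return `path`, invisibly.
#' @export
write_stl <- function(model, path, ascii = FALSE, labels = NULL) {
  stopifnot(inherits(model, "surface_model"))
  v <- model$vertices
  f <- model$faces
  tri <- array(0, dim = c(nrow(f), 3, 3))
  for (k in 1:3) tri[, k, ] <- v[f[, k], ]
  normals <- facet_normals(tri)
  if (ascii) write_stl_ascii(tri, normals, path) else
    write_stl_binary(tri, normals, path)
  if (length(model$regions) > 0) {
    if (is.null(labels)) labels <- paste0(path, ".labels.json")
    write_labels(model, labels)
  }
  invisible(path)
}

facet_normals <- function(tri) {
  e1 <- tri[, 2, ] - tri[, 1, ]
  e2 <- tri[, 3, ] - tri[, 1, ]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

# A file is ASCII STL if it starts with "solid" AND contains "facet" early
# on; binary files may also begin with "solid" in their 80-byte header.
is_ascii_stl <- function(raw) {
  head_raw <- raw[seq_len(min(512, length(raw)))]
  if (any(head_raw == as.raw(0))) return(FALSE)  # NUL bytes: binary dialect
  head_txt <- rawToChar(head_raw)
  Encoding(head_txt) <- "latin1"
  startsWith(trimws(head_txt), "solid") && grepl("facet", head_txt, fixed = TRUE)
}

parse_stl_binary <- function(raw, path) {
  if (length(raw) < 84) {
    abort(paste0("malformed binary STL '", path, "': file ends at byte ",
                 length(raw), ", header needs 84"))
  }
  n_tri <- readBin(raw[81:84], "integer", size = 4, endian = "little")
  need <- 84 + 50 * as.double(n_tri)
  if (length(raw) < need) {
    abort(paste0("malformed binary STL '", path, "': ", n_tri,
                 " facets declared need ", need, " bytes, file ends at byte ",
                 length(raw)))
  }
  if (n_tri == 0) abort(paste0("empty mesh in '", path, "'"))
  # each 50-byte record: 12 floats (normal + 3 vertices) + uint16 attribute
  body <- raw[85:need]
  rec <- matrix(body, nrow = 50)
  floats <- readBin(as.raw(rec[1:48, ]), "double", size = 4,
                    n = 12 * n_tri, endian = "little")
  fm <- matrix(floats, ncol = 12, byrow = TRUE)
  tri <- array(0, dim = c(n_tri, 3, 3))
  for (k in 1:3) tri[, k, ] <- fm[, (3 * k + 1):(3 * k + 3), drop = FALSE]
  tri
}

parse_stl_ascii <- function(raw, path) {
  txt <- rawToChar(raw)
  Encoding(txt) <- "latin1"
  lines <- strsplit(txt, "\r?\n")[[1]]
  vlines <- grep("^\\s*vertex\\s", lines)
  if (length(vlines) == 0) abort(paste0("empty mesh in '", path, "'"))
  if (length(vlines) %% 3 != 0) {
    abort(paste0("malformed ASCII STL '", path, "': ", length(vlines),
                 " vertex lines (not a multiple of 3), near line ",
                 vlines[length(vlines)]))
  }
  coords <- t(vapply(lines[vlines], function(l) {
    parts <- strsplit(trimws(l), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(parts[2:4]))
    if (anyNA(vals)) abort(paste0("malformed ASCII STL '", path,
                                  "': unparsable vertex line '", l, "'"))
    vals
  }, numeric(3), USE.NAMES = FALSE))
  n_tri <- nrow(coords) / 3
  tri <- array(0, dim = c(n_tri, 3, 3))
  for (k in 1:3) tri[, k, ] <- coords[seq(k, by = 3, length.out = n_tri), ]
  tri
}

# Merge exactly-coincident corners of the triangle soup into an indexed mesh.
index_triangle_soup <- function(tri) {
  n_tri <- dim(tri)[1]
  corners <- rbind(tri[, 1, ], tri[, 2, ], tri[, 3, ])
  key <- paste(sprintf("%a", corners[, 1]), sprintf("%a", corners[, 2]),
               sprintf("%a", corners[, 3]))
  uid <- match(key, unique(key))
  first <- !duplicated(uid)
  vertices <- corners[first, , drop = FALSE]
  faces <- matrix(uid, ncol = 3)  # columns are corners 1..3
  list(vertices = vertices, faces = faces)
}

write_stl_binary <- function(tri, normals, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "binary STL written by icpps"))
  writeBin(header[1:80], con)
  n_tri <- dim(tri)[1]
  writeBin(as.integer(n_tri), con, size = 4, endian = "little")
  rec <- matrix(0, nrow = 12, ncol = n_tri)
  rec[1:3, ] <- t(normals)
  for (k in 1:3) rec[(3 * k + 1):(3 * k + 3), ] <- t(matrix(tri[, k, ], ncol = 3))
  floats <- writeBin(as.vector(rec), raw(), size = 4, endian = "little")
  body <- matrix(as.raw(0), nrow = 50, ncol = n_tri)
  body[1:48, ] <- matrix(floats, nrow = 48)
  writeBin(as.vector(body), con)
  invisible(path)
}

write_stl_ascii <- function(tri, normals, path) {
  n_tri <- dim(tri)[1]
  out <- character(2 + 7 * n_tri)
  out[1] <- "solid icpps"
  pos <- 2
  fmt <- function(v) sprintf("%.9g %.9g %.9g", v[1], v[2], v[3])
  for (i in seq_len(n_tri)) {
    out[pos:(pos + 6)] <- c(
      paste0("  facet normal ", fmt(normals[i, ])),
      "    outer loop",
      paste0("      vertex ", fmt(tri[i, 1, ])),
      paste0("      vertex ", fmt(tri[i, 2, ])),
      paste0("      vertex ", fmt(tri[i, 3, ])),
      "    endloop",
      "  endfacet")
    pos <- pos + 7
  }
  out[pos] <- "endsolid icpps"
  writeLines(out, path)
  invisible(path)
}

#' Read and write point tables as CSV
#'
#' Point CSVs have columns `x,y,z` and optionally `label` and `uple` (mm).
#' Comment lines starting with `#` are ignored on read and may be supplied
#' on write (used by the CLI to embed the resolved configuration).
#'
#' @param path File path.
#' @param points Data frame with `x`, `y`, `z` and optional `label`, `uple`.
#' @param comments Character vector written as leading `#` lines.
#' @return `read_points` returns a tibble.
#' @export
read_points <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(c("x", "y", "z"), names(df))
  if (length(miss) > 0) {
    abort(paste0("point CSV is missing column(s): ", paste(miss, collapse = ", ")))
  }
  tibble::as_tibble(df)
}

#' @rdname read_points
#' @export
write_points <- function(points, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments) > 0) writeLines(paste0("# ", comments), con)
  utils::write.csv(points, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
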