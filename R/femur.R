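#' Parameters of the procedural synthetic femur
#'
#' The generator emulates the gross geometry of an adult femur as a closed
#' surface of revolution with angular modulation: a long, slightly waisted
#' shaft along z, an offset spherical head and a greater-trochanter bump
#' proximally, and two condylar bulges distally. Defaults are at typical
#' adult-femur scale so millimetre-scale thresholds elsewhere in the package
#' stay meaningful.
#'
#' @param shaft_length Shaft length (mm).
#' @param shaft_radius Mid-shaft radius (mm).
#' @param head_radius Femoral-head radius (mm); controls the proximal bulge.
#' @param neck_offset Medial offset of the head center (mm).
#' @param condyle_radius Radius of each distal condylar bulge (mm).
#' @param bow Anterior bow of the shaft center line (mm of mid-shaft
#'   offset); femoral shafts curve anteriorly.
#' @param vertex_density Target vertex density (vertices per mm^2). The
#'   default of 1 reproduces the ~1 mm vertex spacing of a CT-derived
#'   femur surface model (tens of thousands of vertices), the regime the
#'   vertex-mode closest-point search is designed for.
#' @param seed Integer seed for the small surface jitter that breaks exact
#'   rotational symmetry.
#' @return A list of class `femur_params`.
#' @export
femur_params <- function(shaft_length = 400, shaft_radius = 15,
                         head_radius = 24, neck_offset = 10,
                         condyle_radius = 22, bow = 6, vertex_density = 1,
                         seed = 1L) {
  p <- list(shaft_length = shaft_length, shaft_radius = shaft_radius,
            head_radius = head_radius, neck_offset = neck_offset,
            condyle_radius = condyle_radius, bow = bow,
            vertex_density = vertex_density, seed = as.integer(seed))
  lens <- unlist(p[c(1:5, 7)])
  if (!is.finite(p$bow) || p$bow < 0) abort("bow must be non-negative")
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    abort("all femur parameters must be positive and finite")
  }
  structure(p, class = "femur_params")
}

# Radius profile r(z, theta) of the star-shaped femur surface.
# Orientation convention: z distal (0) -> proximal (L); theta = 0 is lateral
# (+x), pi/2 anterior (+y), pi medial (-x), 3*pi/2 posterior (-y).
femur_radius <- function(z, theta, p) {
  L <- p$shaft_length
  r0 <- p$shaft_radius
  # gently waisted shaft: narrowest at mid-shaft, flaring toward both ends
  r <- r0 * (1 + 0.12 * ((z - L / 2) / (L / 2))^2)
  bump <- function(amp, z0, th0, sz, sth) {
    dth <- atan2(sin(theta - th0), cos(theta - th0))
    amp * exp(-0.5 * ((z - z0) / sz)^2 - 0.5 * (dth / sth)^2)
  }
  # distal condyles (lateral and medial)
  ca <- p$condyle_radius - r0
  r <- r + bump(ca, 8, 0, 14, 0.7) + bump(ca, 8, pi, 14, 0.7)
  # femoral head: offset medially and proximally
  ha <- p$head_radius - r0 + p$neck_offset
  r <- r + bump(ha, L - 6, pi * 0.9, 16, 0.9)
  # greater trochanter: lateral, just below the head
  r <- r + bump(9, L - 30, 0, 12, 0.6)
  r
}

#' Generate a labeled synthetic femur surface
#'
#' Builds a watertight, consistently wound triangulated femur-like mesh (see
#' [femur_params()]) with the region labels a registration protocol needs:
#'
#' * `accessible` / `inaccessible`: the posterior shaft sector and the
#'   articular surfaces (distal condylar surface, femoral-head top) are
#'   inaccessible to an ultrasound probe; everything else is accessible.
#' * `pre_greater_trochanter` (30 mm diameter), `pre_medial_epicondyle` and
#'   `pre_lateral_epicondyle` (20 mm each): pre-registration disks of
#'   surface vertices around anatomical anchor points, always carved out of
#'   the accessible area.
#' * `shaft_lateral`, `shaft_medial`, `shaft_anterior`, `shaft_posterior`:
#'   optional 20 mm mid-shaft disks for sampling protocols.
#'
#' Disk membership uses Euclidean (chord) distance from the anchor vertex.
#' The same seed and parameters always produce the identical mesh.
#'
#' @param params A [femur_params()] object.
#' @return A [surface_model()] with the regions above and the distal-proximal
#'   axis close to (0, 0, 1).
#' @examples
#' fem <- generate_synthetic_femur(femur_params(vertex_density = 0.12))
#' fem
#' @export
generate_synthetic_femur <- function(params = femur_params()) {
  if (!inherits(params, "femur_params")) params <- do.call(femur_params, params)
  p <- params
  L <- p$shaft_length
  spacing <- 1 / sqrt(p$vertex_density)
  n_z <- max(24L, as.integer(round(L / spacing)) + 1L)
  n_th <- max(16L, as.integer(round(2 * pi * p$shaft_radius / spacing)))
  zs <- seq(0, L, length.out = n_z)
  ths <- seq(0, 2 * pi, length.out = n_th + 1)[seq_len(n_th)]

  grid <- expand.grid(th = ths, z = zs)  # theta fastest: ring-major layout

  # Sample the smooth surface at jittered lattice positions: a regular
  # lattice would create coherent rings of vertices (an artifact CT-derived
  # surface meshes do not have) whose discretization error oscillates in
  # phase and distorts the point-to-surface distance landscape. Jittering
  # the parameter positions keeps the lattice topology (watertight) while
  # making the vertex distribution irregular like a segmented CT surface.
  # Runs in a private RNG scope so generation never disturbs the caller's
  # random stream.
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(p$seed)
  dz <- zs[2] - zs[1]
  dth <- ths[2] - ths[1]
  n_lat <- nrow(grid)
  interior <- grid$z > 0 & grid$z < L  # end rings stay planar for the caps
  grid$z[interior] <- grid$z[interior] +
    runif(sum(interior), -0.45 * dz, 0.45 * dz)
  grid$th <- grid$th + runif(n_lat, -0.45 * dth, 0.45 * dth)
  r <- femur_radius(grid$z, grid$th, p) + runif(n_lat, -0.02, 0.02)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())

  # anterior (+y) bow of the shaft center line, zero at both ends
  bow_y <- p$bow * sin(pi * grid$z / L)
  verts <- cbind(r * cos(grid$th), r * sin(grid$th) + bow_y, grid$z)

  # two pole vertices close the tube into a watertight genus-0 surface
  pole_d <- c(0, 0, -0.4 * p$shaft_radius)
  pole_p <- c(0, 0, L + 0.4 * p$shaft_radius)
  verts <- rbind(verts, pole_d, pole_p)
  i_pole_d <- nrow(verts) - 1L
  i_pole_p <- nrow(verts)

  ring <- function(i) (i - 1L) * n_th + seq_len(n_th)  # vertex ids of ring i
  faces <- vector("list", n_z + 1L)
  for (i in seq_len(n_z - 1L)) {
    a <- ring(i)
    b <- ring(i + 1L)
    a2 <- c(a[-1], a[1])
    b2 <- c(b[-1], b[1])
    # outward winding (counter-clockwise seen from outside)
    faces[[i]] <- rbind(cbind(a, a2, b), cbind(a2, b2, b))
  }
  r1 <- ring(1L)
  rn <- ring(n_z)
  faces[[n_z]] <- cbind(r1, i_pole_d, c(r1[-1], r1[1]))
  faces[[n_z + 1L]] <- cbind(rn, c(rn[-1], rn[1]), i_pole_p)
  faces <- do.call(rbind, faces)
  dimnames(faces) <- NULL

  regions <- femur_regions(verts, grid, p, n_th, n_z,
                           c(i_pole_d, i_pole_p))
  surface_model(verts, faces, regions = regions)
}

disk_vertices <- function(verts, anchor_idx, radius) {
  d2 <- rowSums(sweep(verts, 2, verts[anchor_idx, ])^2)
  which(d2 <= radius^2)
}

# vertex index on the lattice closest to a target (z0, th0) surface location
anchor_index <- function(grid, z0, th0) {
  dth <- atan2(sin(grid$th - th0), cos(grid$th - th0))
  which.min((grid$z - z0)^2 + (20 * dth)^2)
}

femur_regions <- function(verts, grid, p, n_th, n_z, pole_idx) {
  L <- p$shaft_length
  nv <- nrow(verts)
  lattice <- seq_len(nv - 2L)

  anchors <- list(
    pre_greater_trochanter = anchor_index(grid, L - 30, 0),
    pre_medial_epicondyle  = anchor_index(grid, 18, pi),
    pre_lateral_epicondyle = anchor_index(grid, 18, 0),
    shaft_lateral   = anchor_index(grid, L / 2, 0),
    shaft_anterior  = anchor_index(grid, L / 2, pi / 2),
    shaft_medial    = anchor_index(grid, L / 2, pi),
    shaft_posterior = anchor_index(grid, L / 2, 3 * pi / 2)
  )
  radii <- c(15, 10, 10, 10, 10, 10, 10)  # 30 mm trochanter disk, 20 mm others
  disks <- Map(function(a, rad) disk_vertices(verts, a, rad), anchors, radii)

  for (nm in grep("^pre_", names(disks), value = TRUE)) {
    if (length(disks[[nm]]) < 10) {
      abort(paste0("vertex density too low: pre-registration region '", nm,
                   "' has fewer than 10 vertices"))
    }
  }

  # inaccessible: posterior sector of the surface + articular surfaces + poles,
  # minus the pre-registration disks (which must stay accessible)
  dpost <- atan2(sin(grid$th - 3 * pi / 2), cos(grid$th - 3 * pi / 2))
  posterior <- lattice[abs(dpost) < pi / 3]
  articular <- lattice[grid$z < 6 | grid$z > L - 10]
  inacc <- union(union(posterior, articular), pole_idx)
  pre_all <- unique(unlist(disks[grep("^pre_", names(disks))]))
  inacc <- setdiff(inacc, pre_all)
  acc <- setdiff(seq_len(nv), inacc)

  c(list(accessible = acc, inaccessible = inacc), disks)
}
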