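# Fixtures are built in code; the expensive default femur is generated once
# per session and shared across test files.

fixture_env <- new.env(parent = emptyenv())

default_femur <- function() {
  if (is.null(fixture_env$femur)) {
    fixture_env$femur <- generate_synthetic_femur(femur_params())
  }
  fixture_env$femur
}

coarse_femur <- function() {
  if (is.null(fixture_env$coarse)) {
    fixture_env$coarse <- generate_synthetic_femur(
      femur_params(vertex_density = 0.12, seed = 2))
  }
  fixture_env$coarse
}

make_tetrahedron <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  surface_model(v, f)
}

# Open-ended tube capped with cones: an independent cylinder-like mesh for
# closest-point and local-minimum tests (deliberately not the femur code).
make_cylinder_model <- function(radius = 10, length = 100, n_th = 24,
                                n_z = 30, jitter = 0, seed = 1) {
  zs <- seq(0, length, length.out = n_z)
  ths <- seq(0, 2 * pi, length.out = n_th + 1)[seq_len(n_th)]
  g <- expand.grid(th = ths, z = zs)
  if (jitter > 0) {
    set.seed(seed)
    g$th <- g$th + runif(nrow(g), -jitter, jitter) * (ths[2] - ths[1])
    keep <- g$z > 0 & g$z < length
    g$z[keep] <- g$z[keep] + runif(sum(keep), -jitter, jitter) * (zs[2] - zs[1])
  }
  v <- cbind(radius * cos(g$th), radius * sin(g$th), g$z)
  v <- rbind(v, c(0, 0, -radius), c(0, 0, length + radius))
  pd <- nrow(v) - 1L
  pp <- nrow(v)
  ring <- function(i) (i - 1L) * n_th + seq_len(n_th)
  faces <- list()
  for (i in seq_len(n_z - 1L)) {
    a <- ring(i); b <- ring(i + 1L)
    a2 <- c(a[-1], a[1]); b2 <- c(b[-1], b[1])
    faces[[i]] <- rbind(cbind(a, a2, b), cbind(a2, b2, b))
  }
  r1 <- ring(1L); rn <- ring(n_z)
  faces[[n_z]] <- cbind(r1, pd, c(r1[-1], r1[1]))
  faces[[n_z + 1L]] <- cbind(rn, c(rn[-1], rn[1]), pp)
  surface_model(v, do.call(rbind, faces))
}

# Dense flat square patch in the z = 0 plane, plus a far-away box closing the
# surface enough to satisfy the face-count invariant.
make_flat_patch <- function(half = 10, n = 21) {
  xs <- seq(-half, half, length.out = n)
  g <- expand.grid(x = xs, y = xs)
  v <- cbind(g$x, g$y, 0)
  idx <- function(i, j) (j - 1L) * n + i
  faces <- list()
  k <- 1
  for (j in seq_len(n - 1)) {
    for (i in seq_len(n - 1)) {
      faces[[k]] <- rbind(c(idx(i, j), idx(i + 1, j), idx(i, j + 1)),
                          c(idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1)))
      k <- k + 1
    }
  }
  surface_model(v, do.call(rbind, faces))
}

# Plain-R linear-scan closest-vertex oracle, independent of the C++ k-d tree.
brute_force_closest_vertex <- function(model, queries) {
  q <- as.matrix(queries)
  v <- model$vertices
  idx <- integer(nrow(q))
  dist <- numeric(nrow(q))
  for (i in seq_len(nrow(q))) {
    d2 <- (v[, 1] - q[i, 1])^2 + (v[, 2] - q[i, 2])^2 + (v[, 3] - q[i, 3])^2
    idx[i] <- which.min(d2)
    dist[i] <- sqrt(d2[idx[i]])
  }
  list(index = idx, distance = dist)
}

# Random well-spread point clouds and transforms for property loops.
random_cloud <- function(n, scale = 50) {
  tibble::tibble(x = runif(n, -scale, scale), y = runif(n, -scale, scale),
                 z = runif(n, -scale, scale))
}

expect_transform_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a$rotation - b$rotation)), tol)
  expect_lt(max(abs(a$translation - b$translation)), tol)
}
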