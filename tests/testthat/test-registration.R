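test_that("PSD matches hand computations and the linear-scan oracle", {
  cyl <- make_cylinder_model(n_th = 12, n_z = 10, jitter = 0.2, seed = 2)
  v <- cyl$vertices

  on_surface <- tibble::tibble(x = v[1:5, 1], y = v[1:5, 2], z = v[1:5, 3])
  expect_equal(compute_psd(on_surface, cyl), 0)

  # one point exactly 2 mm outward from a known nearest vertex
  far_v <- v[30, ]
  dir <- c(far_v[1], far_v[2], 0)
  dir <- dir / sqrt(sum(dir^2))
  one <- tibble::tibble(x = far_v[1] + 2 * dir[1], y = far_v[2] + 2 * dir[2],
                        z = far_v[3])
  bf <- brute_force_closest_vertex(cyl, as.matrix(one))
  expect_equal(compute_psd(one, cyl), bf$distance^2, tolerance = 1e-12)
  expect_equal(compute_psd(one, cyl), 4, tolerance = 0.2)  # outward jitter

  set.seed(8)
  cloud <- random_cloud(40, scale = 30)
  expect_equal(compute_psd(cloud, cyl),
               mean(brute_force_closest_vertex(cyl, as.matrix(cloud))$distance^2),
               tolerance = 1e-12)
  expect_error(compute_psd(cloud[0, ], cyl), "empty")
})

test_that("pre-registration fits labeled points to area centroids", {
  fem <- coarse_femur()
  pre_names <- sort(grep("^pre_", names(fem$regions), value = TRUE))
  cents <- t(vapply(pre_names, function(nm) region_centroid(fem, nm),
                    numeric(3)))
  six <- tibble::tibble(x = rep(cents[, 1], each = 2),
                        y = rep(cents[, 2], each = 2),
                        z = rep(cents[, 3], each = 2),
                        label = rep(pre_names, each = 2))

  expect_transform_equal(preregister(six, fem), transform_identity())

  set.seed(44)
  truth <- random_rigid_transform(15, 25)
  displaced <- transform_apply(truth, six)
  expect_transform_equal(preregister(displaced, fem),
                         transform_invert(truth), tol = 1e-9)

  expect_error(preregister(six[1:5, ], fem), "at least 6")
  bad <- six
  bad$label[1] <- "pre_nonexistent"
  expect_error(preregister(bad, fem), "pre-registration areas|no region")
  unlabeled <- six[, c("x", "y", "z")]
  expect_error(preregister(unlabeled, fem), "label")
})

test_that("ICP converges on-surface immediately and fixes normal offsets", {
  cyl <- make_cylinder_model(n_th = 16, n_z = 14, jitter = 0.25, seed = 5)
  idx <- seq(5, 200, by = 13)
  gt <- tibble::tibble(x = cyl$vertices[idx, 1], y = cyl$vertices[idx, 2],
                       z = cyl$vertices[idx, 3])
  res <- run_icp(gt, cyl)
  expect_equal(res$trace$psd_mm2[nrow(res$trace)], 0)
  expect_true(res$converged)
  expect_lte(sum(res$trace$stage == "iteration"), 1)

  patch <- make_flat_patch(half = 10, n = 15)
  pts <- tibble::tibble(x = patch$vertices[50:90, 1],
                        y = patch$vertices[50:90, 2],
                        z = patch$vertices[50:90, 3] + 1)  # 1 mm off-plane
  res2 <- run_icp(pts, patch)
  expect_lt(res2$trace$psd_mm2[nrow(res2$trace)], 1e-6)

  expect_error(run_icp(gt[1:2, ], cyl), "at least 3")
})

test_that("ICP PSD trace is non-increasing across random trials", {
  cyl <- make_cylinder_model(n_th = 16, n_z = 14, jitter = 0.25, seed = 5)
  set.seed(77)
  for (i in 1:100) {
    idx <- sample(nrow(cyl$vertices) - 2, 12)
    gt <- tibble::tibble(x = cyl$vertices[idx, 1], y = cyl$vertices[idx, 2],
                         z = cyl$vertices[idx, 3])
    ssp <- transform_apply(random_rigid_transform(8, 6), gt)
    tr <- run_icp(ssp, cyl)$trace
    expect_true(all(diff(tr$psd_mm2) <= 1e-12))
  }
})

test_that("perturbation grid enumerates inclusive endpoint combinations", {
  g <- build_perturbation_grid(c(0, 0, 1), c(0, 0, 0))
  expect_equal(nrow(g$candidates), 143)
  expect_length(g$rotations_deg, 11)
  expect_length(g$translations_mm, 13)
  expect_equal(g$candidates$rot_deg[1:13], rep(-5, 13))  # rotation-major

  single <- build_perturbation_grid(c(0, 0, 1), c(0, 0, 0), 0, 0, 1, 0, 0, 1)
  expect_equal(nrow(single$candidates), 1)
  expect_transform_equal(single$candidates$transform[[1]],
                         transform_identity())

  nine <- build_perturbation_grid(c(0, 0, 1), c(0, 0, 0), -1, 1, 1,
                                  -0.5, 0.5, 0.5)
  expect_equal(nrow(nine$candidates), 9)
  expect_true(any(nine$candidates$rot_deg == 0 & nine$candidates$trans_mm == 0))

  for (steps in list(c(2, 0.5), c(1, 0.25))) {
    gg <- build_perturbation_grid(c(0, 0, 1), c(0, 0, 0),
                                  -4, 4, steps[1], -2, 2, steps[2])
    expect_equal(nrow(gg$candidates),
                 (1 + 8 / steps[1]) * (1 + 4 / steps[2]))
  }
  expect_error(build_perturbation_grid(c(0, 0, 1), c(0, 0, 0), rot_step = 0),
               "positive")
  expect_error(build_perturbation_grid(c(0, 0, 1), c(0, 0, 0), rot_min = 2,
                                       rot_max = -2), "minimum")
})

test_that("perturbation search equals exhaustive grid minimization", {
  cyl <- make_cylinder_model(radius = 10, length = 100, n_th = 20, n_z = 34,
                             jitter = 0.3, seed = 6)
  grid <- build_perturbation_grid(c(0, 0, 1), c(0, 0, 50))
  set.seed(55)
  idx <- sample(600, 15)
  ssp <- tibble::tibble(x = cyl$vertices[idx, 1], y = cyl$vertices[idx, 2],
                        z = cyl$vertices[idx, 3])
  incoming <- axis_transform(c(0, 0, 1), c(0, 0, 50), 1.3, 0.8)
  res <- perturbation_search(ssp, cyl, incoming, grid)

  # independent exhaustive evaluation through the public API
  registered <- transform_apply(incoming, ssp)
  psds <- vapply(seq_len(nrow(grid$candidates)), function(i) {
    compute_psd(transform_apply(grid$candidates$transform[[i]], registered), cyl)
  }, numeric(1))
  expect_equal(res$psd, min(min(psds), compute_psd(registered, cyl)),
               tolerance = 1e-12)
  if (res$improved) {
    best <- which(psds == min(psds))
    chosen <- best[order(grid$candidates$magnitude[best], best)][1]
    expect_equal(res$candidate, chosen)
  }
})

test_that("perturbation search undoes an axial slide and respects optima", {
  cyl <- make_cylinder_model(radius = 10, length = 100, n_th = 20, n_z = 34,
                             jitter = 0.3, seed = 6)
  grid <- build_perturbation_grid(c(0, 0, 1), c(0, 0, 50))
  set.seed(66)
  idx <- sample(nrow(cyl$vertices) - 2, 20)
  ssp <- tibble::tibble(x = cyl$vertices[idx, 1], y = cyl$vertices[idx, 2],
                        z = cyl$vertices[idx, 3])

  slide <- axis_transform(c(0, 0, 1), c(0, 0, 50), 0, 2)  # +2 mm axial
  res <- perturbation_search(ssp, cyl, slide, grid)
  expect_true(res$improved)
  expect_lt(res$psd, compute_psd(transform_apply(slide, ssp), cyl))
  expect_equal(grid$candidates$trans_mm[res$candidate], -2)

  # already optimal: points on vertices, identity incoming -> unchanged
  opt <- perturbation_search(ssp, cyl, transform_identity(), grid)
  expect_false(opt$improved)
  expect_transform_equal(opt$transform, transform_identity())
  expect_equal(opt$psd, 0)
})

test_that("full ICP-PS pipeline never ends worse than its first ICP pass", {
  fem <- default_femur()
  finals <- numeric(15)
  for (s in seq_along(finals)) {
    cfg <- trial_config(n_points = 12, uple_interval = c(0, 1),
                        seed = 3000 + s, method = "icp-ps")
    rec <- run_trial(fem, cfg)
    psd2 <- rec$psd_mm2[rec$step == 2]
    psd4 <- rec$psd_mm2[rec$step == 4]
    expect_lte(psd4, psd2 + 1e-12)

    set.seed(cfg$seed)
    gt <- select_gt_ssp(fem, 12)
    truth <- random_rigid_transform(10, 20)
    ssp <- add_uple_noise(transform_apply(truth, gt), c(0, 1))
    res <- register_icp_ps(ssp, fem)
    expect_lte(res$n_feedback_rounds, 5)
    expect_true(all(is.finite(res$trace$psd_mm2)))
    expect_true(all(res$trace$psd_mm2 >= 0))
    icp_rows <- which(res$trace$step == "icp")
    expect_lte(res$trace$psd_mm2[nrow(res$trace)],
               res$trace$psd_mm2[icp_rows[length(icp_rows)]] + 1e-12)
  }
})

test_that("zero-noise registration of well-spread points is near perfect", {
  fem <- default_femur()
  hits <- logical(100)
  for (s in seq_along(hits)) {
    cfg <- trial_config(n_points = 25, uple_interval = c(0, 0),
                        seed = 4000 + s, method = "icp-ps")
    rec <- run_trial(fem, cfg)
    hits[s] <- rec$rmse_mm[rec$step == 4] < 0.5
  }
  expect_gte(mean(hits), 0.8)
})
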