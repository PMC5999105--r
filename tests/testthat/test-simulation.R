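test_that("ground-truth selection follows the two-step protocol", {
  fem <- coarse_femur()
  set.seed(91)
  six <- select_gt_ssp(fem, 6)
  expect_equal(nrow(six), 6)
  expect_equal(as.vector(table(six$label)), rep(2L, 3))
  expect_setequal(unique(six$label),
                  grep("^pre_", names(fem$regions), value = TRUE))
  # labeled points really lie in their labeled region
  for (i in 1:6) {
    reg_idx <- fem$regions[[six$label[i]]]
    d <- brute_force_closest_vertex(fem, as.matrix(six[i, c("x", "y", "z")]))
    expect_true(d$index %in% reg_idx)
    expect_equal(d$distance, 0)
  }

  set.seed(92)
  p25 <- select_gt_ssp(fem, 25)
  expect_equal(sum(p25$label == "accessible"), 19)
  acc_v <- fem$vertices[fem$regions$accessible, , drop = FALSE]
  rest <- as.matrix(p25[p25$label == "accessible", c("x", "y", "z")])
  for (i in seq_len(nrow(rest))) {
    expect_true(any(abs(acc_v[, 1] - rest[i, 1]) +
                    abs(acc_v[, 2] - rest[i, 2]) +
                    abs(acc_v[, 3] - rest[i, 3]) < 1e-12))
  }

  set.seed(93)
  a <- select_gt_ssp(fem, 15)
  set.seed(93)
  b <- select_gt_ssp(fem, 15)
  expect_identical(a, b)
  expect_error(select_gt_ssp(fem, 5), "at least 6")
})

test_that("localization noise respects its interval and isotropy", {
  p <- tibble::tibble(x = 1, y = 2, z = 3)

  set.seed(1)
  expect_equal(as.matrix(add_uple_noise(p, c(0, 0))[, 1:3]), as.matrix(p))

  set.seed(2)
  many <- add_uple_noise(p[rep(1, 10000), ], c(1, 2))
  expect_true(all(many$uple >= 1 & many$uple <= 2))
  shift <- cbind(many$x - 1, many$y - 2, many$z - 3)
  mags <- sqrt(rowSums(shift^2))
  expect_equal(mags, many$uple, tolerance = 1e-12)
  # mean displacement vector ~ 0 within 3 standard errors
  se <- apply(shift, 2, sd) / sqrt(10000)
  expect_true(all(abs(colMeans(shift)) < 3 * se))
  # mean magnitude ~ midpoint of the interval
  expect_equal(mean(mags), 1.5, tolerance = 3 * sd(mags) / sqrt(10000))

  expect_error(add_uple_noise(p, c(-1, 2)), "0 <= a <= b")
  expect_error(add_uple_noise(p, c(2, 1)), "0 <= a <= b")
})

test_that("bone-to-bone RMSE matches analytic and brute-force values", {
  fem <- coarse_femur()
  set.seed(13)
  truth <- random_rigid_transform(10, 20)

  expect_equal(rmse_bone_to_bone(truth, transform_invert(truth), fem), 0,
               tolerance = 1e-9)
  resid <- rigid_transform(diag(3), c(1, 0, 0))
  est <- transform_compose(resid, transform_invert(truth))
  expect_equal(rmse_bone_to_bone(truth, est, fem), 1, tolerance = 1e-12)

  # small rotation about the centroid: explicit per-vertex evaluation
  rot <- axis_transform(c(0, 1, 0), colMeans(fem$vertices), angle_deg = 0.7)
  est2 <- transform_compose(rot, transform_invert(truth))
  v <- fem$vertices
  moved <- v %*% t(rot$rotation) +
    matrix(rot$translation, nrow(v), 3, byrow = TRUE)
  expect_equal(rmse_bone_to_bone(truth, est2, fem),
               sqrt(mean(rowSums((moved - v)^2))), tolerance = 1e-12)
})

test_that("trials are reproducible and near-exact without noise", {
  fem <- default_femur()
  # Zero displacement, zero noise: the mandatory coarse pre-registration
  # moves a perfectly aligned point set to the area centroids, so plain ICP
  # ends in a nearby minimum; the perturbation feedback recovers the exact
  # registration.
  cfg <- trial_config(n_points = 25, uple_interval = c(0, 0),
                      displacement = c(0, 0), seed = 12, method = "icp")
  rec <- run_trial(fem, cfg)
  expect_lt(rec$rmse_mm[rec$step == 2], rec$rmse_mm[rec$step == 1])
  cfg_ps <- trial_config(n_points = 25, uple_interval = c(0, 0),
                         displacement = c(0, 0), seed = 12, method = "icp-ps")
  rec_ps <- run_trial(fem, cfg_ps)
  expect_lt(rec_ps$rmse_mm[rec_ps$step == 4], 1e-6)

  cfg2 <- trial_config(n_points = 10, uple_interval = c(0, 1), seed = 77,
                       method = "icp-ps")
  a <- run_trial(fem, cfg2)
  b <- run_trial(fem, cfg2)
  expect_equal(a$rmse_mm, b$rmse_mm, tolerance = 0)
  expect_equal(a$psd_mm2, b$psd_mm2, tolerance = 0)
  expect_equal(a$step, 1:4)
  expect_equal(a$step_name,
               c("preregistration", "icp", "perturbation", "feedback"))
})

test_that("the factorial design enumerates trials with stable seeds", {
  d <- experiment_design(n_points = 6:25,
                         uple_intervals = list(c(0, 0), c(0, 1), c(1, 2)),
                         repeats = 100, methods = "icp-ps", master_seed = 9)
  expect_equal(nrow(d), 6000)
  expect_equal(length(unique(d$trial_id)), 6000)
  expect_true(all(d$seed >= 0 & d$seed < 2^31))

  one <- experiment_design(n_points = 10, uple_intervals = list(c(0, 0)),
                           repeats = 1, methods = "icp", master_seed = 9)
  expect_equal(nrow(one), 1)

  # adding factor levels leaves existing trial seeds untouched
  bigger <- experiment_design(n_points = 6:30,
                              uple_intervals = list(c(0, 0), c(0, 1),
                                                    c(1, 2), c(2, 3)),
                              repeats = 100, methods = "icp-ps",
                              master_seed = 9)
  key <- function(t) paste(t$n_points, t$uple_lo, t$uple_hi, t$rep)
  m <- match(key(d), key(bigger))
  expect_equal(d$seed, bigger$seed[m])

  # both methods share seeds so they see identical trials
  two <- experiment_design(n_points = 8, uple_intervals = list(c(0, 1)),
                           repeats = 3, methods = c("icp", "icp-ps"),
                           master_seed = 4)
  expect_equal(nrow(two), 6)
  expect_equal(as.vector(unique(tapply(two$seed, two$rep,
                                       function(s) length(unique(s))))), 1L)
  expect_error(experiment_design(integer(0)), "non-empty")
})

test_that("small experiments run, aggregate, and replay from the master seed", {
  fem <- default_femur()
  rec <- run_experiment(fem, n_points = c(8, 12), uple_intervals = list(c(0, 0)),
                        repeats = 2, methods = c("icp", "icp-ps"),
                        master_seed = 3)
  expect_equal(length(unique(rec$trial_id)), 8)
  expect_equal(sum(rec$method == "icp" & rec$step == 2), 4)
  expect_equal(sum(rec$method == "icp-ps" & rec$step == 4), 4)

  s <- summarize_experiment(rec)
  expect_equal(unique(s$n_trials), 2L)
  hand <- mean(rec$rmse_mm[rec$method == "icp-ps" & rec$step == 4 &
                           rec$n_points == 8])
  expect_equal(s$mean_rmse_mm[s$method == "icp-ps" & s$step == 4 &
                              s$n_points == 8], hand)

  rec2 <- run_experiment(fem, n_points = c(8, 12),
                         uple_intervals = list(c(0, 0)), repeats = 2,
                         methods = c("icp", "icp-ps"), master_seed = 3)
  expect_equal(rec$rmse_mm, rec2$rmse_mm, tolerance = 0)
})

test_that("noise level stochastically degrades accuracy at fixed n", {
  fem <- default_femur()
  rec <- run_experiment(fem, n_points = 25,
                        uple_intervals = list(c(0, 0), c(1, 2)),
                        repeats = 8, methods = "icp-ps", master_seed = 6)
  s <- summarize_experiment(rec)
  clean <- s$mean_rmse_mm[s$step == 4 & s$uple_hi == 0]
  noisy <- s$mean_rmse_mm[s$step == 4 & s$uple_hi == 2]
  expect_lt(clean, noisy)
})

test_that("incremental evaluation sorts and registers by descending error", {
  fem <- default_femur()
  res <- incremental_uple_evaluation(fem, n_areas = 12, repeats_per_area = 10,
                                     selection = "closest", seed = 21)
  sel <- attr(res, "selected")
  meas <- attr(res, "measurements")
  expect_equal(nrow(sel), 12)
  expect_equal(nrow(meas), 120)
  # per-area pick is the measurement with the minimal stored error
  mins <- tapply(meas$uple, meas$area, min)
  expect_equal(as.numeric(mins[as.character(sel$area)]), sel$uple)
  # emitted ordering is non-increasing in the localization error
  expect_true(all(diff(sel$uple) <= 0))
  # counts span 6..n_areas for both methods
  expect_setequal(res$n_points, 6:12)
  expect_setequal(res$method, c("icp", "icp-ps"))
  expect_true(all(is.finite(res$rmse_mm)))

  far <- incremental_uple_evaluation(fem, n_areas = 12, repeats_per_area = 10,
                                     selection = "farthest", seed = 21)
  fsel <- attr(far, "selected")
  maxs <- tapply(attr(far, "measurements")$uple, attr(far, "measurements")$area,
                 max)
  expect_equal(as.numeric(maxs[as.character(fsel$area)]), fsel$uple)
  expect_gte(mean(fsel$uple), mean(sel$uple))
})
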