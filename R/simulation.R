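#' Sample ground-truth surface points from a labeled model
#'
#' Two-step selection protocol: the first six points are two vertices drawn
#' uniformly without replacement from each of the three pre-registration
#' areas (rows labeled with the area name); the remaining `n_points - 6` are
#' drawn uniformly without replacement from the accessible area. Uses the R
#' RNG, so results are deterministic after `set.seed()`.
#'
#' @param model A labeled [surface_model()] with three `pre_*` regions and
#'   an `accessible` region.
#' @param n_points Total number of points (>= 6).
#' @return A tibble of ground-truth sample points with a `label` column
#'   (`pre_*` for the first six, `accessible` for the rest).
#' @export
select_gt_ssp <- function(model, n_points) {
  if (n_points < 6) abort("the selection protocol needs at least 6 points")
  pre <- grep("^pre_", names(model$regions), value = TRUE)
  if (length(pre) != 3) {
    abort("model must carry exactly three pre-registration ('pre_*') regions")
  }
  if (is.null(model$regions$accessible)) {
    abort("model must carry an 'accessible' region")
  }
  picked <- integer(0)
  labels <- character(0)
  for (nm in sort(pre)) {
    idx <- model$regions[[nm]]
    if (length(idx) < 2) abort(paste0("region '", nm, "' is too small to sample"))
    take <- sample(idx, 2)
    picked <- c(picked, take)
    labels <- c(labels, rep(nm, 2))
  }
  n_rest <- n_points - 6L
  if (n_rest > 0) {
    pool <- setdiff(model$regions$accessible, picked)
    if (length(pool) < n_rest) abort("accessible area too small to sample")
    take <- sample(pool, n_rest)
    picked <- c(picked, take)
    labels <- c(labels, rep("accessible", n_rest))
  }
  v <- model$vertices[picked, , drop = FALSE]
  tibble::tibble(x = v[, 1], y = v[, 2], z = v[, 3], label = labels)
}

#' Add isotropic point localization noise
#'
#' Each point is displaced by `m * d` where `d` is a direction uniform on
#' the unit sphere and the magnitude `m` is uniform on `interval` (mm). The
#' drawn magnitude is stored per point in the `uple` column. This is the
#' isotropic model of the ultrasound point localization error (UPLE).
#'
#' @param points Point table.
#' @param interval Length-2 magnitude interval `[a, b]` mm, `0 <= a <= b`.
#' @return The displaced tibble with a `uple` column.
#' @export
add_uple_noise <- function(points, interval) {
  interval <- as.double(interval)
  if (length(interval) != 2 || interval[1] < 0 || interval[2] < interval[1]) {
    abort("noise interval must satisfy 0 <= a <= b")
  }
  m <- as_point_matrix(points)
  n <- nrow(m)
  dir <- matrix(rnorm(3 * n), ncol = 3)
  bad <- rowSums(dir^2) == 0
  while (any(bad)) {
    dir[bad, ] <- rnorm(3 * sum(bad))
    bad <- rowSums(dir^2) == 0
  }
  dir <- dir / sqrt(rowSums(dir^2))
  mag <- runif(n, interval[1], interval[2])
  out <- rebuild_points(points, m + dir * mag)
  out$uple <- mag
  out
}

#' Bone-to-bone registration error
#'
#' The residual motion left after registration is the estimated registration
#' composed with the true displacement; applied to every model vertex it
#' measures how far the registered bone is from the ground-truth bone. The
#' returned value is the root mean square of the per-vertex displacement
#' norms (mm), 0 exactly when the registration inverts the displacement.
#'
#' @param true_displacement `rigid_transform` that moved the bone (mapped
#'   ground-truth points to measured positions).
#' @param estimated_registration `rigid_transform` returned by registration
#'   (maps measured positions back onto the model).
#' @param model A [surface_model()]; all its vertices enter the metric.
#' @return RMSE in mm.
#' @export
rmse_bone_to_bone <- function(true_displacement, estimated_registration,
                              model) {
  residual <- transform_compose(estimated_registration, true_displacement)
  v <- model$vertices
  moved <- transform_apply_mat(residual, v)
  sqrt(mean(rowSums((moved - v)^2)))
}

#' Configuration of a single simulated registration trial
#'
#' @param n_points Number of sample points (>= 6; the study design uses
#'   6 to 25).
#' @param uple_interval Noise magnitude interval `[a, b]` mm.
#' @param displacement `c(max_rotation_deg, max_translation_mm)` bounds of
#'   the random rigid displacement.
#' @param seed Integer RNG seed for the trial.
#' @param method `"icp-ps"` (four-step) or `"icp"` (steps 1-2).
#' @param mode Closest-point mode.
#' @return A list of class `trial_config`.
#' @export
trial_config <- function(n_points = 25, uple_interval = c(0, 0),
                         displacement = c(10, 20), seed = 1L,
                         method = c("icp-ps", "icp"),
                         mode = c("vertex", "triangle")) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  if (n_points < 6) abort("n_points must be at least 6")
  if (length(uple_interval) != 2 || uple_interval[1] < 0 ||
      uple_interval[2] < uple_interval[1]) {
    abort("uple_interval must satisfy 0 <= a <= b")
  }
  structure(list(n_points = as.integer(n_points),
                 uple_interval = as.double(uple_interval),
                 displacement = as.double(displacement),
                 seed = as.integer(seed), method = method, mode = mode),
            class = "trial_config")
}

# trace -> the per-step transforms scored in the study design:
# step 2 = after the (first) ICP pass, step 3 = after the first perturbation
# pass, step 4 = final result of the feedback loop.
step_transforms <- function(result) {
  tr <- result$trace
  out <- list()
  pre <- which(tr$step == "preregistration")
  if (length(pre) > 0) out$preregistration <- tr$transform[[pre[1]]]
  icp <- which(tr$step == "icp")
  if (length(icp) > 0) {
    out$icp <- tr$transform[[icp[length(icp)]]]
  }
  pert <- which(tr$step == "perturbation")
  if (length(pert) > 0) out$perturbation <- tr$transform[[pert[1]]]
  if (any(tr$step %in% c("perturbation", "feedback_icp"))) {
    out$feedback <- result$transform
  }
  out
}

step_index <- c(preregistration = 1L, icp = 2L, perturbation = 3L,
                feedback = 4L)

#' Run one simulated registration trial
#'
#' Samples ground-truth points from the model, displaces them by a random
#' rigid motion, adds localization noise, registers them back with the
#' configured method, and scores the bone-to-bone RMSE of the intermediate
#' and final transforms. Fully reproducible from `config$seed`.
#'
#' @param model A labeled [surface_model()].
#' @param config A [trial_config()].
#' @return A tibble with one row per registration step: `method`, `step`,
#'   `step_name`, `n_points`, `uple_lo`, `uple_hi`, `seed`, `psd_mm2`,
#'   `rmse_mm`, and list columns `transform` / `true_transform`.
#' @export
run_trial <- function(model, config) {
  stopifnot(inherits(config, "trial_config"))
  set.seed(config$seed)
  gt <- select_gt_ssp(model, config$n_points)
  t_true <- random_rigid_transform(config$displacement[1],
                                   config$displacement[2])
  ssp <- transform_apply(t_true, gt)
  ssp <- add_uple_noise(ssp, config$uple_interval)

  result <- if (config$method == "icp-ps") {
    register_icp_ps(ssp, model, mode = config$mode)
  } else {
    register_icp(ssp, model, mode = config$mode)
  }

  steps <- step_transforms(result)
  src <- as_point_matrix(ssp)
  rows <- purrr::imap(steps, function(tr, nm) {
    tibble::tibble(
      method = config$method,
      step = step_index[[nm]],
      step_name = nm,
      n_points = config$n_points,
      uple_lo = config$uple_interval[1],
      uple_hi = config$uple_interval[2],
      seed = config$seed,
      psd_mm2 = mean(closest_points_mat(
        model, transform_apply_mat(tr, src), config$mode)$distance^2),
      rmse_mm = rmse_bone_to_bone(t_true, tr, model),
      transform = list(tr),
      true_transform = list(t_true))
  })
  dplyr::bind_rows(rows)
}

#' Enumerate the factorial simulation design
#'
#' Crosses point counts, noise intervals, repeats and methods into one row
#' per trial, with the per-trial seed derived from the master seed by
#' counter-based hashing ([derive_seed()]) so that adding factor levels
#' never changes existing trials. The full study design (20 point counts x
#' 3 intervals x 100 repeats x 1 method) enumerates 6000 trials.
#'
#' @param n_points Integer vector of point counts.
#' @param uple_intervals List of length-2 noise intervals (mm).
#' @param repeats Repeats per design cell.
#' @param methods Character vector, subset of `c("icp-ps", "icp")`.
#' @param master_seed Integer master seed.
#' @return A tibble with one row per trial: factor columns, `rep`, `seed`,
#'   `trial_id`.
#' @export
experiment_design <- function(n_points = 6:25,
                              uple_intervals = list(c(0, 0), c(0, 1), c(1, 2)),
                              repeats = 100, methods = "icp-ps",
                              master_seed = 1L) {
  if (length(n_points) == 0 || length(uple_intervals) == 0 ||
      length(methods) == 0 || repeats < 1) {
    abort("all design factors must be non-empty")
  }
  grid <- tidyr::expand_grid(
    i_n = seq_along(n_points),
    i_u = seq_along(uple_intervals),
    rep = seq_len(repeats),
    method = methods)
  grid$n_points <- n_points[grid$i_n]
  grid$uple_lo <- vapply(grid$i_u, function(i) uple_intervals[[i]][1], 0)
  grid$uple_hi <- vapply(grid$i_u, function(i) uple_intervals[[i]][2], 0)
  # seed shared across methods (methods are compared on identical trials) and
  # hashed from the factor values, so inserting design levels never changes
  # the seeds of existing trials
  grid$seed <- mapply(function(n, lo, hi, r) {
    derive_seed(master_seed, n, round(1000 * lo), round(1000 * hi), r)
  }, grid$n_points, grid$uple_lo, grid$uple_hi, grid$rep)
  grid$trial_id <- seq_len(nrow(grid))
  dplyr::select(grid, "trial_id", "method", "n_points", "uple_lo", "uple_hi",
                "rep", "seed")
}

#' Run the Monte-Carlo registration experiment
#'
#' Executes [run_trial()] for every row of the factorial design and binds
#' the per-step records into one tidy table (one row per trial x step). The
#' companion [summarize_experiment()] yields the mean-RMSE curves per step.
#'
#' @inheritParams experiment_design
#' @param model A labeled [surface_model()].
#' @param displacement Displacement bounds passed to every trial.
#' @param mode Closest-point mode.
#' @param progress Print a progress line every 50 trials.
#' @return A tibble of per-step trial records (see [run_trial()]) with
#'   `trial_id` and `rep` columns.
#' @export
run_experiment <- function(model, n_points = 6:25,
                           uple_intervals = list(c(0, 0), c(0, 1), c(1, 2)),
                           repeats = 100, methods = "icp-ps",
                           master_seed = 1L, displacement = c(10, 20),
                           mode = c("vertex", "triangle"), progress = FALSE) {
  mode <- match.arg(mode)
  design <- experiment_design(n_points, uple_intervals, repeats, methods,
                              master_seed)
  records <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    cfg <- trial_config(n_points = row$n_points,
                        uple_interval = c(row$uple_lo, row$uple_hi),
                        seed = row$seed, method = row$method, mode = mode)
    rec <- run_trial(model, cfg)
    rec$trial_id <- row$trial_id
    rec$rep <- row$rep
    records[[i]] <- rec
    if (progress && i %% 50 == 0) {
      message(sprintf("trial %d / %d", i, nrow(design)))
    }
  }
  dplyr::bind_rows(records)
}

#' Aggregate an experiment into mean-RMSE curves
#'
#' @param records Output of [run_experiment()].
#' @return A tibble of mean RMSE and PSD by method, step, point count and
#'   noise interval.
#' @export
summarize_experiment <- function(records) {
  dplyr::summarise(
    dplyr::group_by(records, .data$method, .data$step, .data$step_name,
                    .data$n_points, .data$uple_lo, .data$uple_hi),
    mean_rmse_mm = mean(.data$rmse_mm),
    sd_rmse_mm = stats::sd(.data$rmse_mm),
    mean_psd_mm2 = mean(.data$psd_mm2),
    n_trials = dplyr::n(),
    .groups = "drop")
}

#' Incremental evaluation under descending localization error
#'
#' Emulates a repeated-measurement protocol on simulated data: each of
#' `n_areas` anatomical areas (the three pre-registration areas contribute
#' two areas' worth of labeled points; the rest are accessible-area picks)
#' is measured `repeats_per_area` times with noise, and per area only the
#' measurement with the minimal (`"closest"`) or maximal (`"farthest"`)
#' localization error is kept. The kept points are sorted by descending
#' error, and registration is run cumulatively from 6 points up to
#' `n_areas` points with both standard ICP and ICP-PS: each subset is the
#' six pre-registration points plus the largest-error remaining points, so
#' points join in descending error order.
#'
#' @param model A labeled [surface_model()].
#' @param n_areas Number of anatomical areas (>= 6, default 25).
#' @param repeats_per_area Measurements per area (default 10).
#' @param selection `"closest"` or `"farthest"`.
#' @param uple_interval Noise magnitude interval per measurement (mm).
#' @param displacement Random displacement bounds.
#' @param seed RNG seed.
#' @param mode Closest-point mode.
#' @return A tibble of `n_points` x method RMSE/PSD results; the per-area
#'   selected points (sorted by descending `uple`) are attached as
#'   attribute `"selected"` and the full area x measurement table as
#'   attribute `"measurements"`.
#' @export
incremental_uple_evaluation <- function(model, n_areas = 25,
                                        repeats_per_area = 10,
                                        selection = c("closest", "farthest"),
                                        uple_interval = c(0, 2),
                                        displacement = c(10, 20), seed = 1L,
                                        mode = c("vertex", "triangle")) {
  selection <- match.arg(selection)
  mode <- match.arg(mode)
  if (n_areas < 6) abort("need at least 6 areas (the pre-registration points)")
  set.seed(seed)
  gt <- select_gt_ssp(model, n_areas)
  t_true <- random_rigid_transform(displacement[1], displacement[2])
  displaced <- transform_apply(t_true, gt)

  picked <- vector("list", n_areas)
  measurements <- vector("list", n_areas)
  for (i in seq_len(n_areas)) {
    reps <- add_uple_noise(displaced[rep(i, repeats_per_area), ],
                           uple_interval)
    reps$area <- i
    reps$measurement <- seq_len(repeats_per_area)
    measurements[[i]] <- reps
    j <- if (selection == "closest") which.min(reps$uple) else
      which.max(reps$uple)
    picked[[i]] <- reps[j, ]
  }
  measurements <- dplyr::bind_rows(measurements)
  picked <- dplyr::bind_rows(picked)
  picked$area <- seq_len(n_areas)
  is_pre <- startsWith(picked$label, "pre_")

  pre_pts <- picked[is_pre, ][order(-picked$uple[is_pre]), ]
  rest <- picked[!is_pre, ][order(-picked$uple[!is_pre]), ]
  selected <- dplyr::bind_rows(pre_pts, rest)
  selected <- selected[order(-selected$uple), ]

  out <- vector("list", 0)
  for (n in 6:n_areas) {
    pts <- dplyr::bind_rows(pre_pts, head(rest, n - 6L))
    for (method in c("icp", "icp-ps")) {
      res <- if (method == "icp-ps") {
        register_icp_ps(pts, model, mode = mode)
      } else {
        register_icp(pts, model, mode = mode)
      }
      out[[length(out) + 1]] <- tibble::tibble(
        selection = selection, n_points = n, method = method,
        rmse_mm = rmse_bone_to_bone(t_true, res$transform, model),
        psd_mm2 = res$trace$psd_mm2[nrow(res$trace)],
        max_uple = max(pts$uple), seed = seed)
    }
  }
  out <- dplyr::bind_rows(out)
  attr(out, "selected") <- selected
  attr(out, "measurements") <- measurements
  out
}
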