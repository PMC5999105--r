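#' Mean squared point-to-surface distance (PSD)
#'
#' For each point the closest point on the model surface is found (see
#' [closest_points()]); the PSD is the mean of the squared closest-point
#' distances, in mm^2. This is the quantity the perturbation search and the
#' feedback loop minimize and compare.
#'
#' @param points Data frame of points (`x`, `y`, `z`, mm) or n x 3 matrix.
#' @param model A [surface_model()].
#' @param mode Closest-point mode, `"vertex"` (default) or `"triangle"`.
#' @return Mean squared distance (mm^2).
#' @export
compute_psd <- function(points, model, mode = c("vertex", "triangle")) {
  mode <- match.arg(mode)
  q <- as_point_matrix(points)
  if (nrow(q) == 0) abort("PSD of an empty point set is undefined")
  mean(closest_points_mat(model, q, mode)$distance^2)
}

#' Coarse pre-registration on labeled anatomical areas
#'
#' The first six sample points must carry pre-registration area labels (two
#' per area). Each labeled point is paired with the centroid of its area's
#' labeled vertices on the model, and the closed-form rigid fit
#' ([fit_rigid()]) of those six correspondences is returned. This puts the
#' sample points within the capture range of ICP without any surface search.
#'
#' @param ssp Sample point table whose first 6 rows are labeled with the
#'   model's `pre_*` region names, two rows per region.
#' @param model A [surface_model()] carrying the three `pre_*` regions.
#' @return A `rigid_transform` mapping sample coordinates into model
#'   coordinates.
#' @export
preregister <- function(ssp, model) {
  if (!is.data.frame(ssp) || nrow(ssp) < 6) {
    abort("pre-registration needs at least 6 sample points")
  }
  if (!"label" %in% names(ssp)) {
    abort("pre-registration points must carry area labels")
  }
  lab <- as.character(ssp$label[1:6])
  if (anyNA(lab) || any(lab == "")) {
    abort("the first 6 sample points must all be labeled")
  }
  counts <- table(lab)
  if (length(counts) != 3 || any(counts != 2)) {
    abort("expected exactly two labeled points in each of three pre-registration areas")
  }
  for (nm in names(counts)) {
    if (is.null(model$regions[[nm]])) {
      abort(paste0("model has no region '", nm, "' matching the point labels"))
    }
  }
  centroids <- t(vapply(lab, function(nm) region_centroid(model, nm),
                        numeric(3)))
  src <- as_point_matrix(ssp[1:6, c("x", "y", "z")])
  fit_rigid(src, centroids)
}

new_registration_result <- function(transform, trace, converged,
                                    n_feedback_rounds, mode) {
  structure(list(transform = transform, trace = trace, converged = converged,
                 n_feedback_rounds = n_feedback_rounds, mode = mode),
            class = "registration_result")
}

trace_row <- function(step, stage, iteration, psd, transform) {
  tibble::tibble(step = step, stage = stage, iteration = iteration,
                 psd_mm2 = psd, rms_mm = sqrt(psd),
                 transform = list(transform))
}

#' @export
print.registration_result <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  cat(sprintf(
    "<registration_result> %d trace steps, final PSD %.6g mm^2 (%s)\n",
    nrow(x$trace), last$psd_mm2,
    if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Iterative closest point registration to a surface model
#'
#' Standard ICP: in each iteration the closest model points of all sample
#' points define correspondence pairs, and the closed-form rigid fit of
#' those pairs updates the pose. Iterations stop at `max_iter` or when the
#' PSD improves by less than `tol`.
#'
#' @param ssp Sample point table (>= 3 non-collinear points).
#' @param model A [surface_model()].
#' @param init Initial `rigid_transform` (e.g. from [preregister()]).
#' @param max_iter Maximum number of iterations (default 30).
#' @param tol Stop when the PSD improvement drops below this (mm^2).
#' @param mode Closest-point mode (see [closest_points()]).
#' @return A `registration_result`: final `transform`, per-iteration `trace`
#'   (tibble of step, stage, PSD, transform), `converged` flag.
#' @export
run_icp <- function(ssp, model, init = transform_identity(), max_iter = 30,
                    tol = 1e-6, mode = c("vertex", "triangle")) {
  mode <- match.arg(mode)
  src <- as_point_matrix(ssp)
  if (nrow(src) < 3) abort("ICP needs at least 3 sample points")
  current <- init
  pts <- transform_apply_mat(current, src)
  psd <- mean(closest_points_mat(model, pts, mode)$distance^2)
  trace <- list(trace_row("icp", "init", 0L, psd, current))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    corr <- closest_points_mat(model, pts, mode)
    step_fit <- fit_rigid(pts, corr$point)
    cand <- transform_compose(step_fit, current)
    cand_pts <- transform_apply_mat(cand, src)
    cand_psd <- mean(closest_points_mat(model, cand_pts, mode)$distance^2)
    if (cand_psd <= psd) {
      current <- cand
      pts <- cand_pts
      improvement <- psd - cand_psd
      psd <- cand_psd
    } else {
      improvement <- 0  # fit did not help (already at a fixed point)
    }
    trace[[it + 1L]] <- trace_row("icp", "iteration", it, psd, current)
    if (improvement < tol) {
      converged <- TRUE
      break
    }
  }
  new_registration_result(current, dplyr::bind_rows(trace), converged, 0L, mode)
}

#' Axis-constrained perturbation grid
#'
#' Enumerates all combinations of rotations about, and translations along,
#' the distal-proximal axis (through `axis_point`), endpoints included,
#' rotation-major order. With the default ranges (-5..5 degrees in 1 degree
#' steps, -3..3 mm in 0.5 mm steps) this is the 11 x 13 = 143 candidate
#' curved grid used to escape axial local minima of ICP on cylinder-like
#' bones.
#'
#' @param axis Unit axis direction.
#' @param axis_point Point on the axis (mm).
#' @param rot_min,rot_max,rot_step Rotation range and step (degrees).
#' @param trans_min,trans_max,trans_step Translation range and step (mm).
#' @return A `perturbation_grid`: tibble of candidates (`rot_deg`,
#'   `trans_mm`, `magnitude`, `transform`) plus the axis fields.
#' @export
build_perturbation_grid <- function(axis, axis_point,
                                    rot_min = -5, rot_max = 5, rot_step = 1,
                                    trans_min = -3, trans_max = 3,
                                    trans_step = 0.5) {
  if (rot_step <= 0 || trans_step <= 0) abort("grid steps must be positive")
  if (rot_min > rot_max || trans_min > trans_max) {
    abort("grid range minimum exceeds maximum")
  }
  rots <- seq(rot_min, rot_max, by = rot_step)
  trans <- seq(trans_min, trans_max, by = trans_step)
  combos <- expand.grid(trans_mm = trans, rot_deg = rots)[, 2:1]  # rotation-major
  candidates <- tibble::as_tibble(combos)
  candidates$magnitude <- sqrt(candidates$rot_deg^2 + candidates$trans_mm^2)
  candidates$transform <- purrr::map2(
    candidates$rot_deg, candidates$trans_mm,
    function(r, s) axis_transform(axis, axis_point, angle_deg = r, shift_mm = s))
  structure(list(axis = axis / sqrt(sum(axis^2)), axis_point = axis_point,
                 rotations_deg = rots, translations_mm = trans,
                 candidates = candidates),
            class = "perturbation_grid")
}

#' @export
print.perturbation_grid <- function(x, ...) {
  cat(sprintf("<perturbation_grid> %d candidates (%d rotations x %d translations)\n",
              nrow(x$candidates), length(x$rotations_deg),
              length(x$translations_mm)))
  invisible(x)
}

#' Perturbation search around a registered position
#'
#' Evaluates the PSD of the registered sample points under every candidate
#' of the perturbation grid and returns the best candidate composed with the
#' incoming transform. A candidate is accepted only if it strictly lowers
#' the PSD; otherwise the incoming state is returned unchanged. Equal-PSD
#' candidates are resolved by the smaller perturbation magnitude
#' (`sqrt(rot_deg^2 + trans_mm^2)`; the identity candidate first), then by
#' enumeration order.
#'
#' @param ssp Sample point table in its original (unregistered) coordinates.
#' @param model A [surface_model()].
#' @param transform Incoming registration (`rigid_transform`).
#' @param grid A [build_perturbation_grid()] result.
#' @param mode Closest-point mode.
#' @return List with `transform` (possibly improved), `psd` (its PSD),
#'   `improved` flag and the grid `candidate` row index chosen (NA when
#'   unchanged).
#' @export
perturbation_search <- function(ssp, model, transform, grid,
                                mode = c("vertex", "triangle")) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "perturbation_grid"))
  src <- as_point_matrix(ssp)
  registered <- transform_apply_mat(transform, src)
  base_psd <- mean(closest_points_mat(model, registered, mode)$distance^2)
  cand <- grid$candidates
  psds <- vapply(cand$transform, function(tr) {
    mean(closest_points_mat(model, transform_apply_mat(tr, registered),
                            mode)$distance^2)
  }, numeric(1))
  ord <- order(psds, cand$magnitude, seq_len(nrow(cand)))
  best <- ord[1]
  if (psds[best] < base_psd) {
    list(transform = transform_compose(cand$transform[[best]], transform),
         psd = psds[best], improved = TRUE, candidate = best)
  } else {
    list(transform = transform, psd = base_psd, improved = FALSE,
         candidate = NA_integer_)
  }
}

#' Four-step ICP-PS registration
#'
#' Runs the full registration pipeline for sparse labeled surface points:
#'
#' 1. pre-registration of the six labeled points to the area centroids,
#' 2. ICP from the pre-registered pose,
#' 3. axis-constrained perturbation search around the ICP solution,
#' 4. feedback: if the perturbation improved the PSD, ICP is re-run from the
#'    perturbed pose, and perturbation + ICP repeat until the PSD improves
#'    by less than `feedback_tol` (default 1e-5 mm^2), with at most
#'    `max_feedback` (default 5) repetitions.
#'
#' Perturbations are only ever accepted when they strictly lower the PSD and
#' ICP never increases it, so the final PSD is never worse than after the
#' first ICP pass.
#'
#' @param ssp Sample point table; the first 6 rows must carry `pre_*` labels
#'   (see [preregister()]).
#' @param model A labeled [surface_model()].
#' @param grid Optional [build_perturbation_grid()]; defaults to the
#'   standard grid on the model's distal-proximal axis.
#' @param max_iter,tol ICP controls (see [run_icp()]).
#' @param feedback_tol PSD-improvement threshold ending the feedback loop
#'   (mm^2).
#' @param max_feedback Maximum number of perturbation + ICP repetitions.
#' @param mode Closest-point mode.
#' @return A `registration_result` whose `trace` records every stage
#'   (pre-registration, each ICP iteration, each perturbation pass) and
#'   whose `n_feedback_rounds` counts perturbation + ICP repetitions.
#' @examples
#' \donttest{
#' fem <- generate_synthetic_femur(femur_params(vertex_density = 0.12))
#' set.seed(7)
#' gt <- select_gt_ssp(fem, 25)
#' ssp <- transform_apply(random_rigid_transform(10, 20), gt)
#' res <- register_icp_ps(ssp, fem)
#' glance(res)
#' }
#' @export
register_icp_ps <- function(ssp, model, grid = NULL, max_iter = 30,
                            tol = 1e-6, feedback_tol = 1e-5, max_feedback = 5,
                            mode = c("vertex", "triangle")) {
  mode <- match.arg(mode)
  if (is.null(grid)) {
    grid <- build_perturbation_grid(model$axis, model$axis_point)
  }
  src <- as_point_matrix(ssp)

  pre <- preregister(ssp, model)
  pre_psd <- mean(closest_points_mat(
    model, transform_apply_mat(pre, src), mode)$distance^2)
  trace <- list(trace_row("preregistration", "fit", 0L, pre_psd, pre))

  icp1 <- run_icp(ssp, model, init = pre, max_iter = max_iter, tol = tol,
                  mode = mode)
  trace <- c(trace, list(icp1$trace))
  current <- icp1$transform
  psd <- icp1$trace$psd_mm2[nrow(icp1$trace)]

  rounds <- 0L
  converged <- FALSE
  while (rounds < max_feedback) {
    ps <- perturbation_search(ssp, model, current, grid, mode = mode)
    trace <- c(trace, list(
      trace_row("perturbation", if (ps$improved) "accepted" else "rejected",
                rounds + 1L, ps$psd, ps$transform)))
    if (!ps$improved) {
      converged <- TRUE
      break
    }
    rounds <- rounds + 1L
    icp_k <- run_icp(ssp, model, init = ps$transform, max_iter = max_iter,
                     tol = tol, mode = mode)
    tr_k <- icp_k$trace
    tr_k$step <- "feedback_icp"
    tr_k$iteration <- tr_k$iteration + 100L * rounds  # keep iterations unique
    trace <- c(trace, list(tr_k))
    new_psd <- tr_k$psd_mm2[nrow(tr_k)]
    improvement <- psd - new_psd
    # ICP from an accepted (strictly better) perturbation can only lower PSD
    current <- icp_k$transform
    psd <- new_psd
    if (improvement < feedback_tol) {
      converged <- TRUE
      break
    }
  }
  new_registration_result(current, dplyr::bind_rows(trace), converged,
                          rounds, mode)
}

#' Standard-ICP counterpart of [register_icp_ps()]
#'
#' Pre-registration followed by a single ICP pass (steps 1-2 only), for
#' head-to-head comparison with the perturbation-search pipeline.
#'
#' @inheritParams register_icp_ps
#' @return A `registration_result`.
#' @export
register_icp <- function(ssp, model, max_iter = 30, tol = 1e-6,
                         mode = c("vertex", "triangle")) {
  mode <- match.arg(mode)
  src <- as_point_matrix(ssp)
  pre <- preregister(ssp, model)
  pre_psd <- mean(closest_points_mat(
    model, transform_apply_mat(pre, src), mode)$distance^2)
  icp <- run_icp(ssp, model, init = pre, max_iter = max_iter, tol = tol,
                 mode = mode)
  trace <- dplyr::bind_rows(
    trace_row("preregistration", "fit", 0L, pre_psd, pre), icp$trace)
  new_registration_result(icp$transform, trace, icp$converged, 0L, mode)
}
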