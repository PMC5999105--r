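#' Tidy a registration result
#'
#' One row per recorded stage of the registration (pre-registration, each
#' ICP iteration, each perturbation pass), with the PSD in mm^2 and its
#' root in mm.
#'
#' @param x A `registration_result`.
#' @param ... Unused.
#' @return A tibble with columns `step`, `stage`, `iteration`, `psd_mm2`,
#'   `rms_mm`.
#' @exportS3Method generics::tidy
tidy.registration_result <- function(x, ...) {
  dplyr::select(x$trace, "step", "stage", "iteration", "psd_mm2", "rms_mm")
}

#' Glance at a registration result
#'
#' @param x A `registration_result`.
#' @param ... Unused.
#' @return A one-row tibble: final PSD (mm^2) and RMS (mm), PSD after the
#'   first ICP pass, number of feedback rounds, convergence flag, rotation
#'   angle and translation norm of the final transform.
#' @exportS3Method generics::glance
glance.registration_result <- function(x, ...) {
  tr <- x$trace
  icp <- which(tr$step == "icp")
  icp_psd <- if (length(icp) > 0) tr$psd_mm2[icp[length(icp)]] else NA_real_
  final <- tr$psd_mm2[nrow(tr)]
  tibble::tibble(
    final_psd_mm2 = final,
    final_rms_mm = sqrt(final),
    icp_psd_mm2 = icp_psd,
    n_feedback_rounds = x$n_feedback_rounds,
    converged = x$converged,
    rotation_deg = rotation_angle_deg(x$transform),
    translation_mm = sqrt(sum(x$transform$translation^2)))
}

#' Plot the PSD convergence trace of a registration
#'
#' @param object A `registration_result`.
#' @param ... Unused.
#' @return A ggplot: PSD (log scale) against trace position, colored by
#'   pipeline step.
#' @exportS3Method ggplot2::autoplot
autoplot.registration_result <- function(object, ...) {
  df <- tidy(object)
  df$order <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$order, y = .data$psd_mm2,
                                   color = .data$step)) +
    ggplot2::geom_line(ggplot2::aes(group = 1), color = "grey60") +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "pipeline stage", y = "PSD (mm²)",
                  color = "step",
                  title = "Point-to-surface distance along the registration") +
    ggplot2::theme_minimal()
}

#' Mean-RMSE curves of a simulation experiment
#'
#' Reproduces the study's summary view: mean bone-to-bone RMSE against the
#' number of sample points, one panel per noise interval, one curve per
#' registration step/method.
#'
#' @param records Output of [run_experiment()] (or an already summarized
#'   table from [summarize_experiment()]).
#' @return A ggplot.
#' @export
plot_rmse_curves <- function(records) {
  summ <- if ("mean_rmse_mm" %in% names(records)) records else
    summarize_experiment(records)
  summ$curve <- paste0(summ$method, " step ", summ$step)
  summ$uple <- sprintf("UPLE [%g, %g] mm", summ$uple_lo, summ$uple_hi)
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$n_points,
                                     y = .data$mean_rmse_mm,
                                     color = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~uple) +
    ggplot2::labs(x = "number of sample points", y = "mean RMSE (mm)",
                  color = NULL,
                  title = "Registration accuracy vs point count") +
    ggplot2::theme_minimal()
}
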