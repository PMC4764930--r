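#' Plot composite-index trajectories of a scan set
#'
#' One panel per scanned time-point; each line is one Pareto solution's
#' composite index across all sampling times. A pre-disease candidate shows
#' lines that spike at the scanned time and stay flat before it.
#'
#' @param object A `dnb_scan_set` from [scan_timepoints()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dnb_scan_set
#' @export
autoplot.dnb_scan_set <- function(object, ...) {
  traj <- dplyr::bind_rows(lapply(object, function(s) {
    dplyr::mutate(s$trajectories, scanned = sprintf("scan at %g h", s$time_hours))
  }))
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$time_hours, y = .data$index,
                                     group = .data$solution_id)) +
    ggplot2::geom_line(alpha = 0.35) +
    ggplot2::facet_wrap(~scanned) +
    ggplot2::labs(x = "time (h)", y = "composite index I",
                  title = "Pareto-solution dynamics per scanned time-point") +
    ggplot2::theme_minimal()
}

#' Plot a Pareto front in objective space
#'
#' @param object A `dnb_pareto` tibble from [run_nsga2()].
#' @param ... Unused.
#' @return A ggplot object with the ideal point at the origin.
#' @method autoplot dnb_pareto
#' @export
autoplot.dnb_pareto <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$f1, y = .data$f2)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$size), alpha = 0.7) +
    ggplot2::annotate("point", x = 0, y = 0, shape = 4, size = 3) +
    ggplot2::labs(x = expression(f[1] == 1 / (1 + I[t])),
                  y = expression(f[2] == I[t - 1]),
                  size = "genes",
                  title = "Pareto front (ideal point at the origin)") +
    ggplot2::theme_minimal()
}

#' Plot the selected biomarker's trajectory and the per-time significance
#'
#' Left: composite-index trajectories of the chosen scan's solutions with
#' the selected biomarker highlighted. Right: per-time Wilcoxon-Mann-Whitney
#' p-values with the chosen time marked.
#'
#' @param object A `dnb_report` from [run_full()].
#' @param ... Unused.
#' @return A ggplot object (two facets).
#' @method autoplot dnb_report
#' @export
autoplot.dnb_report <- function(object, ...) {
  traj <- dplyr::mutate(object$trajectories,
                        selected = .data$solution_id == object$selected_solution_id,
                        panel = "composite-index trajectories")
  pv <- dplyr::mutate(object$per_time, panel = "Pareto-set significance")
  ggplot2::ggplot() +
    ggplot2::geom_line(data = traj,
                       ggplot2::aes(x = .data$time_hours, y = .data$index,
                                    group = .data$solution_id,
                                    color = .data$selected,
                                    linewidth = .data$selected),
                       show.legend = FALSE) +
    ggplot2::geom_point(data = pv,
                        ggplot2::aes(x = .data$time_hours, y = .data$wmw_p)) +
    ggplot2::geom_line(data = pv,
                       ggplot2::aes(x = .data$time_hours, y = .data$wmw_p),
                       linetype = 2) +
    ggplot2::geom_vline(xintercept = object$predisease_time_hours,
                        linetype = 3) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60",
                                           `TRUE` = "#D55E00")) +
    ggplot2::scale_linewidth_manual(values = c(`FALSE` = 0.4, `TRUE` = 1.1)) +
    ggplot2::labs(x = "time (h)", y = NULL) +
    ggplot2::theme_minimal()
}
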