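#' Plot allele-frequency trajectories
#'
#' One line per tracked mutation over calendar months, faceted by patient.
#' Open points mark draws where the mutation was not detected (AF below the
#' plasma criteria); dashed and dotted vertical lines mark treatment end
#' and imaging-detected recurrence when provided.
#'
#' @param trajectories output of [track_patient()] (possibly several
#'   patients row-bound)
#' @param treatment_end_month optional month of treatment end
#' @param imaging_month optional month of imaging-detected recurrence
#' @return a `ggplot` object
#' @export
plot_trajectories <- function(trajectories, treatment_end_month = NULL,
                              imaging_month = NULL) {
  p <- ggplot2::ggplot(trajectories,
                       ggplot2::aes(x = month, y = af, colour = mutation,
                                    group = mutation)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = detected), size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::labs(x = "month", y = "cfDNA allele frequency",
                  colour = "mutation", shape = "detected") +
    ggplot2::theme_minimal()
  if (length(unique(trajectories$patient)) > 1L)
    p <- p + ggplot2::facet_wrap(~patient, scales = "free_y")
  if (!is.null(treatment_end_month) && !is.na(treatment_end_month))
    p <- p + ggplot2::geom_vline(xintercept = treatment_end_month,
                                 linetype = "dashed")
  if (!is.null(imaging_month) && !is.na(imaging_month))
    p <- p + ggplot2::geom_vline(xintercept = imaging_month,
                                 linetype = "dotted")
  p
}
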