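#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_boxplot
#'   geom_jitter geom_col geom_abline geom_hline labs theme_minimal autoplot
NULL

#' ROC curve plot
#'
#' @inheritParams auc
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_roc <- function(scores, labels, title = NULL) {
  pts <- roc_points(scores, labels)
  ggplot(pts, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_line(colour = "#2C7FB8") +
    labs(x = "false positive rate", y = "true positive rate",
         title = title %||% sprintf("ROC (AUC = %.3f)", auc(scores, labels))) +
    theme_minimal()
}

#' @describeIn calibrate_all_lengths Per-length cutoffs and AUCs as a
#'   two-panel bar chart.
#' @param object A `threshold_table`.
#' @param ... Unused.
#' @export
autoplot.threshold_table <- function(object, ...) {
  long <- as_tibble(object) %>%
    select("length", "threshold", "auc") %>%
    tidyr::pivot_longer(c("threshold", "auc"), names_to = "metric")
  ggplot(long, aes(x = factor(.data$length), y = .data$value)) +
    geom_col(fill = "#2C7FB8", width = 0.7) +
    ggplot2::facet_wrap(~ .data$metric, ncol = 1L) +
    labs(x = "CDR3 length (aa)", y = NULL,
         title = "Per-length calibrated cutoffs and validation AUC") +
    theme_minimal()
}

#' Cohort LCRI distribution plot
#'
#' Boxplots of per-sample LCRI by cohort group with jittered points, the
#' standard presentation of risk-index stratification; optionally draws a
#' decision cutoff.
#'
#' @param lcri Tibble from [lcri_cohort()] (needs `lcri` and `group`).
#' @param cutoff Optional horizontal cutoff line.
#' @return A ggplot object.
#' @export
plot_lcri <- function(lcri, cutoff = NULL) {
  p <- ggplot(lcri, aes(x = .data$group, y = .data$lcri,
                        colour = .data$group)) +
    geom_boxplot(outlier.shape = NA) +
    geom_jitter(width = 0.15, alpha = 0.6) +
    labs(x = NULL, y = "LCRI", title = "Lung Cancer Risk Index by group") +
    theme_minimal() +
    ggplot2::theme(legend.position = "none")
  if (!is.null(cutoff)) {
    p <- p + geom_hline(yintercept = cutoff, linetype = "dashed",
                        colour = "red")
  }
  p
}

#' Longitudinal LCRI trajectory plot
#'
#' Paired pre/post lines per patient coloured by trajectory subtype.
#'
#' @param trajectories Tibble from [classify_trajectory()].
#' @return A ggplot object.
#' @export
plot_trajectories <- function(trajectories) {
  long <- trajectories %>%
    tidyr::pivot_longer(c("pre", "post"), names_to = "timepoint",
                        values_to = "lcri") %>%
    mutate(timepoint = factor(.data$timepoint, levels = c("pre", "post")))
  ggplot(long, aes(x = .data$timepoint, y = .data$lcri,
                   group = .data$patient_id, colour = .data$subtype)) +
    geom_line() +
    geom_point() +
    labs(x = NULL, y = "LCRI", colour = "subtype",
         title = "Pre/post treatment LCRI trajectories") +
    theme_minimal()
}
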