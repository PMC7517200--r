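#' Plot the overlap trajectory of a production trial
#'
#' Target syllables are drawn as solid colored lines (by serial position),
#' all other stored patterns in light grey; the lexicon word's overlap, when
#' present, as a black dashed line.
#'
#' @param object a [run_production()] record
#' @param min_overlap hide patterns whose overlap never exceeds this value
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.potts_trial <- function(object, min_overlap = 0.2, ...) {
  traj <- object$trajectory
  keep <- dplyr::group_by(traj, .data$pattern)
  keep <- dplyr::filter(keep, max(.data$overlap) >= min_overlap |
                          .data$pattern[1] %in% object$target)
  keep <- dplyr::ungroup(keep)
  keep$role <- ifelse(keep$pattern %in% object$target,
                      paste0("syllable ", match(keep$pattern, object$target)),
                      "other")
  p <- ggplot2::ggplot(keep, ggplot2::aes(.data$t, .data$overlap,
                                          group = .data$pattern)) +
    ggplot2::geom_line(data = keep[keep$role == "other", ],
                       color = "grey80", linewidth = 0.3) +
    ggplot2::geom_line(data = keep[keep$role != "other", ],
                       ggplot2::aes(color = .data$role), linewidth = 0.7)
  if (!is.null(object$word_overlap)) {
    p <- p + ggplot2::geom_line(
      data = object$word_overlap,
      ggplot2::aes(.data$t, .data$overlap),
      inherit.aes = FALSE, linetype = "dashed", color = "black"
    )
  }
  p +
    ggplot2::labs(x = "time (update units)", y = "overlap",
                  color = NULL,
                  title = sprintf("item %d: %s", object$item_id, object$label)) +
    ggplot2::theme_minimal()
}

#' Bar chart of a batch's error distribution
#'
#' Reproduces the usual error-taxonomy summary: one bar per category with
#' across-batch standard errors.
#'
#' @param object a [run_batch()] result
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.pob_batch <- function(object, ...) {
  d <- object$summary
  ggplot2::ggplot(d, ggplot2::aes(.data$category, .data$percent)) +
    ggplot2::geom_col(fill = "firebrick3", alpha = 0.85) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$percent - .data$sem,
                   ymax = .data$percent + .data$sem),
      width = 0.25
    ) +
    ggplot2::labs(x = NULL, y = "% of trials",
                  title = object$config$profile_name) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}

#' Normalized-activity traces of the three target syllables
#'
#' @param record a [run_production()] record
#' @return a ggplot of the state-blind activity per serial position
#' @export
plot_syllable_activity <- function(record) {
  stopifnot(inherits(record, "potts_trial"), !is.null(record$activity))
  ggplot2::ggplot(record$activity,
                  ggplot2::aes(.data$t, .data$activity,
                               color = factor(.data$position))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (update units)", y = "proportion of active units",
                  color = "syllable") +
    ggplot2::theme_minimal()
}
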