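#' Tidy a production batch into the error distribution
#'
#' One row per error category with the percentage of trials and its standard
#' error (across batches when several were run).
#'
#' @param x a [run_batch()] result
#' @param ... unused
#' @return a tibble with columns `category`, `percent`, `sem`
#' @export
tidy.pob_batch <- function(x, ...) {
  x$summary
}

#' One-row summary of a production batch
#'
#' @param x a [run_batch()] result
#' @param ... unused
#' @return a tibble with the correct fraction, dominant error, trial counts
#'   and the trisyllabic-production rate
#' @export
glance.pob_batch <- function(x, ...) {
  tr <- x$trials
  errs <- x$summary[x$summary$category != "correct", ]
  tibble::tibble(
    profile = x$config$profile_name,
    n_trials = nrow(tr),
    n_batches = length(x$seeds),
    correct_fraction = mean(tr$label == "correct"),
    dominant_error = as.character(errs$category[which.max(errs$percent)]),
    trisyllabic_fraction = mean(tr$n_utterances >= 3),
    keeps_speaking_fraction = mean(tr$keeps_speaking)
  )
}

#' Tidy a mixed sign/word batch
#' @param x a [run_sob_batch()] result
#' @param ... unused
#' @return per-kind correctness and intrusion counts
#' @export
tidy.sob_batch <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$trials, .data$kind),
    n = dplyr::n(),
    correct_fraction = mean(.data$correct),
    gesture_intrusions = sum(.data$gesture_intrusion, na.rm = TRUE),
    syllable_intrusions = sum(.data$syllable_intrusion, na.rm = TRUE),
    .groups = "drop"
  )
}

#' First-error-position breakdown of a batch
#'
#' Frequency of the serial position (1-3) at which the first wrong utterance
#' occurred, per error category.
#'
#' @param x a [run_batch()] result
#' @return a tibble with `category`, `first_error_position`, `n`, `percent`
#' @export
first_error_positions <- function(x) {
  stopifnot(inherits(x, "pob_batch"))
  tr <- x$trials[x$trials$label != "correct", ]
  out <- dplyr::count(tr, .data$label, .data$first_error_position)
  dplyr::mutate(
    dplyr::rename(out, category = "label"),
    percent = 100 * .data$n / nrow(x$trials)
  )
}
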