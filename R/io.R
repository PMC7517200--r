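#' Write the outputs of a batch run to disk
#'
#' Emits, under `dir`: the per-trial table (`trials.csv`), the
#' error-distribution table (`error_distribution.csv`), a machine-readable
#' summary (`summary.json`, including the config echo and seeds), and the
#' first-error-position breakdown. All floating point values are serialized
#' at full precision, so re-reading reproduces the aggregates exactly.
#'
#' @param x a [run_batch()] (or [run_sob_batch()]) result
#' @param dir output directory (created if missing)
#' @return invisibly, the paths written
#' @export
write_outputs <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(obj, name) {
    p <- file.path(dir, name)
    utils::write.csv(obj, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (inherits(x, "pob_batch")) {
    wr(x$trials, "trials.csv")
    wr(x$summary, "error_distribution.csv")
    wr(first_error_positions(x), "first_error_positions.csv")
    summary <- list(
      profile = x$config$profile_name,
      seeds = x$seeds,
      n_trials = nrow(x$trials),
      correct_fraction = mean(x$trials$label == "correct"),
      config = unclass(x$config)
    )
  } else if (inherits(x, "sob_batch")) {
    wr(x$trials, "trials.csv")
    wr(tidy(x), "summary_by_kind.csv")
    summary <- list(
      profile = x$exp$config$profile_name,
      seeds = x$seed,
      n_trials = nrow(x$trials),
      correct_fraction = mean(x$trials$correct),
      config = unclass(x$exp$config)
    )
  } else {
    stop("write_outputs() expects a pob_batch or sob_batch", call. = FALSE)
  }
  p <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, p, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
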