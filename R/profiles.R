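KNOWN_KEYS <- list(
  top = c("kind", "pol", "pob", "net", "sob", "coupling", "protocol"),
  net = c("N", "C_m", "p", "w", "tau1", "tau2_fast", "tau2_slow",
          "gamma2_fast", "tau_A", "tau_B", "gamma_A", "S", "a", "beta", "U",
          "dynamic_threshold", "threshold_scale", "tau_U"),
  coupling = c("C_m_het", "lambda_word", "lambda_sign", "gain", "g_cascade"),
  protocol = c("n_words", "n_batches", "cue_strength", "cue_duration",
               "T_max", "dt", "record_dt", "theta_on", "theta_off", "d_min",
               "overtake_margin", "inter_cue_interval"),
  sob = c("n_clusters", "a_sign", "n_gestures", "n_syllables", "n_signs",
          "n_words", "b_fast", "b_slow")
)

PROTOCOL_DEFAULTS <- list(
  n_words = 50, n_batches = 3, cue_strength = 1.0, cue_duration = 110,
  T_max = 300, dt = 0.25, record_dt = 2, theta_on = 0.5, theta_off = 0.35,
  d_min = 10, overtake_margin = 0.1, inter_cue_interval = 150
)

#' List the experiment profiles shipped with the package
#' @return character vector of profile names
#' @export
list_profiles <- function() {
  sub("\\.yaml$", "", dir(system.file("profiles", package = "pottsbuffer"),
                          pattern = "\\.yaml$"))
}

#' Load an experiment configuration
#'
#' Reads one of the named profiles shipped in `inst/profiles` (or a YAML file
#' path) into a validated `experiment_config`. Unknown keys raise an error so
#' that typos never pass silently; missing protocol keys are filled from the
#' documented defaults with a message.
#'
#' @param name profile name (see [list_profiles()]) or path to a YAML file
#' @param quiet suppress the filled-defaults message
#' @return an `experiment_config` list with elements `kind`, network
#'   parameter blocks, `coupling` and `protocol`
#' @export
#' @examples
#' cfg <- load_profile("pob_step4")
#' cfg$pob$N
load_profile <- function(name, quiet = FALSE) {
  path <- if (file.exists(name)) {
    name
  } else {
    system.file("profiles", paste0(name, ".yaml"), package = "pottsbuffer")
  }
  assert_that(nzchar(path) && file.exists(path),
              sprintf("unknown profile '%s'", name))
  raw <- yaml::read_yaml(path)

  check_keys <- function(block, allowed, where) {
    bad <- setdiff(names(block), allowed)
    assert_that(length(bad) == 0,
                sprintf("unknown key(s) in %s: %s", where,
                        paste(bad, collapse = ", ")))
  }
  check_keys(raw, KNOWN_KEYS$top, "profile")
  for (blk in intersect(c("pol", "pob", "net"), names(raw))) {
    check_keys(raw[[blk]], KNOWN_KEYS$net, blk)
  }
  if (!is.null(raw$coupling)) check_keys(raw$coupling, KNOWN_KEYS$coupling, "coupling")
  if (!is.null(raw$protocol)) check_keys(raw$protocol, KNOWN_KEYS$protocol, "protocol")
  if (!is.null(raw$sob)) check_keys(raw$sob, KNOWN_KEYS$sob, "sob")

  filled <- setdiff(names(PROTOCOL_DEFAULTS), names(raw$protocol))
  raw$protocol <- utils::modifyList(PROTOCOL_DEFAULTS, raw$protocol %||% list())
  if (length(filled) && !quiet) {
    message("protocol defaults used for: ", paste(filled, collapse = ", "))
  }
  raw$profile_name <- sub("\\.yaml$", "", basename(path))
  structure(raw, class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("<experiment_config> %s (kind: %s)\n", x$profile_name, x$kind))
  invisible(x)
}

#' Apply an ablation flag to a configuration
#'
#' @param config an [load_profile()] configuration
#' @param flag one of `"no_slow_adaptation"`, `"no_dynamic_threshold"`,
#'   `"no_fast_local_inhibition"`
#' @return the modified configuration
#' @export
apply_ablation <- function(config, flag) {
  stopifnot(inherits(config, "experiment_config"))
  switch(flag,
    no_slow_adaptation = {
      config$pob$gamma2_fast <- 1.0
    },
    no_dynamic_threshold = {
      config$pob$dynamic_threshold <- FALSE
      config$pob$U <- 0.216
    },
    no_fast_local_inhibition = {
      config$pob$gamma_A <- 0.0
    },
    stop(sprintf("unknown ablation flag '%s'", flag), call. = FALSE)
  )
  config$profile_name <- paste0(config$profile_name, "+", flag)
  config
}

params_from_block <- function(block, dt) {
  network_params(
    N = block$N, S = block$S %||% 7, a = block$a %||% 0.25, C_m = block$C_m,
    beta = block$beta %||% 12.5, U = block$U %||% 0.1, w = block$w,
    tau1 = block$tau1 %||% 3.33,
    tau2_fast = block$tau2_fast, tau2_slow = block$tau2_slow %||% block$tau2_fast,
    gamma2_fast = block$gamma2_fast %||% 1,
    tau_A = block$tau_A %||% 2, tau_B = block$tau_B %||% 1e6,
    gamma_A = block$gamma_A %||% 0,
    dynamic_threshold = block$dynamic_threshold %||% FALSE,
    threshold_scale = block$threshold_scale %||% 0.55,
    tau_U = block$tau_U %||% 2,
    dt = dt
  )
}
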