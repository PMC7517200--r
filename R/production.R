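#' Assemble a two-network word-production experiment
#'
#' Generates patterns for the lexicon and buffer networks, samples the
#' connectivities, builds the 50-word positionally balanced lexicon, and
#' stores all weights, for one pattern-set realization ("batch"). All
#' randomness is derived from `seed` through named sub-seeds.
#'
#' @param config an [load_profile()] configuration (kind `"pob"`)
#' @param seed master seed for this realization
#' @return a `pob_experiment` object
#' @export
build_experiment <- function(config, seed) {
  stopifnot(inherits(config, "experiment_config"))
  assert_that(identical(config$kind, "pob"), "config must be a pob profile")
  dt <- config$protocol$dt
  pol_par <- params_from_block(config$pol, dt)
  pob_par <- params_from_block(config$pob, dt)

  pol_ps <- generate_random_patterns(pol_par$N, pol_par$S, pol_par$a,
                                     config$pol$p, seed_for(seed, "patterns_pol"))
  pob_ps <- generate_random_patterns(pob_par$N, pob_par$S, pob_par$a,
                                     config$pob$p, seed_for(seed, "patterns_pob"))
  lexicon <- build_word_lexicon(
    config$protocol$n_words, pob_ps, seed_for(seed, "lexicon"),
    p_lexicon = config$pol$p,
    g_cascade = unlist(config$coupling$g_cascade),
    lambda_word = config$coupling$lambda_word
  )
  conn_pol <- build_connectivity(pol_par$N, pol_par$N, pol_par$C_m,
                                 seed = seed_for(seed, "conn_pol"))
  conn_pob <- build_connectivity(pob_par$N, pob_par$N, pob_par$C_m,
                                 seed = seed_for(seed, "conn_pob"))
  conn_het <- build_connectivity(pob_par$N, pol_par$N, config$coupling$C_m_het,
                                 self_allowed = TRUE,
                                 seed = seed_for(seed, "conn_het"))
  structure(
    list(
      config = config, seed = seed,
      pol_params = pol_par, pob_params = pob_par,
      pol_patterns = pol_ps, pob_patterns = pob_ps,
      lexicon = lexicon,
      J_pol = store_autoassociative(pol_ps, conn_pol, pol_par$S, pol_par$a),
      J_pob = store_autoassociative(pob_ps, conn_pob, pob_par$S, pob_par$a),
      J_het = store_heteroassociative(pol_ps, pob_ps, lexicon, conn_het,
                                      gain = config$coupling$gain %||% 1,
                                      S = pob_par$S, a = pob_par$a)
    ),
    class = "pob_experiment"
  )
}

#' @export
print.pob_experiment <- function(x, ...) {
  cat(sprintf("<pob_experiment> %s, seed %d: POL %d units / POB %d units, %d items\n",
              x$config$profile_name, x$seed, x$pol_params$N, x$pob_params$N,
              nrow(x$lexicon$items)))
  invisible(x)
}

simulate_items <- function(exp, item_ids, early_stop = TRUE) {
  cfg <- exp$config
  n <- length(item_ids)
  items <- exp$lexicon$items[match(item_ids, exp$lexicon$items$item_id), ]
  cues <- data.frame(
    trial = seq_len(n),
    pattern = items$lexicon_pattern,
    onset = 0,
    duration = cfg$protocol$cue_duration,
    strength = cfg$protocol$cue_strength
  )
  watch <- t(as.matrix(items[, c("c1", "c2", "c3")]))
  storage.mode(watch) <- "integer"
  buffer <- net_for_engine(exp$pob_params, exp$J_pob$conn, exp$J_pob,
                           hetero = list(adj = exp$J_het$conn$idx,
                                         J = exp$J_het$values))
  source <- net_for_engine(exp$pol_params, exp$J_pol$conn, exp$J_pol)
  run_engine(buffer, source, cues, exp$pob_patterns$states,
             exp$pol_patterns$states, n, cfg$protocol,
             watch = watch,
             src_watch = matrix(items$lexicon_pattern, 1, n),
             early_stop = early_stop)
}

#' Produce a single lexicon item
#'
#' Cues one item and co-simulates the lexicon and buffer networks until the
#' horizon (or both return to quiescence), then extracts the utterance
#' sequence and classifies it against the target triple.
#'
#' @param config a profile name or [load_profile()] configuration
#' @param item_id lexicon item to cue
#' @param seed master seed (patterns, connectivity, lexicon)
#' @return a `potts_trial` production record with the overlap trajectory,
#'   extracted utterances, error label and first-error position
#' @export
#' @examples
#' \donttest{
#' rec <- run_production("pob_step4", item_id = 1, seed = 1)
#' rec$label
#' autoplot(rec)
#' }
run_production <- function(config, item_id, seed) {
  if (is.character(config)) config <- load_profile(config, quiet = TRUE)
  exp <- build_experiment(config, seed)
  sim <- simulate_items(exp, item_id)
  trial_record(exp, sim, trial = 1, item_id = item_id)
}

trial_record <- function(exp, sim, trial, item_id) {
  cfg <- exp$config
  target <- item_components(exp$lexicon, item_id)
  utt <- extract_utterances(
    trajectory_tbl(sim, trial),
    theta_on = cfg$protocol$theta_on, theta_off = cfg$protocol$theta_off,
    d_min = cfg$protocol$d_min, overtake_margin = cfg$protocol$overtake_margin
  )
  lab <- classify_error(utt, target)
  structure(
    list(
      item_id = item_id, target = target,
      utterances = utt, label = lab$category,
      first_error_position = lab$first_error_position,
      keeps_speaking = nrow(utt) > 3,
      trajectory = trajectory_tbl(sim, trial),
      word_overlap = if (!is.null(sim$overlap_source)) {
        tibble::tibble(t = sim$t, overlap = sim$overlap_source[trial, , 1])
      },
      activity = if (!is.null(sim$activity)) {
        tibble::tibble(
          t = rep(sim$t, 3),
          position = rep(1:3, each = length(sim$t)),
          activity = c(sim$activity[trial, , 1], sim$activity[trial, , 2],
                       sim$activity[trial, , 3])
        )
      }
    ),
    class = "potts_trial"
  )
}

#' @export
print.potts_trial <- function(x, ...) {
  cat(sprintf("<potts_trial> item %d: %s (targets %s; uttered %s)\n",
              x$item_id, x$label, paste(x$target, collapse = ","),
              paste(x$utterances$pattern, collapse = ",")))
  invisible(x)
}

#' Run production batches over whole lexica
#'
#' For each seed, builds a fresh pattern-set realization (patterns,
#' connectivity and lexicon all re-drawn) and cues every word once (or a
#' subsample), then aggregates the error taxonomy over all trials.
#'
#' @param config profile name or [load_profile()] configuration
#' @param seeds one master seed per batch (the default design is 3
#'   batches; each batch re-draws all patterns)
#' @param words_per_batch optionally subsample this many words per batch
#' @return a `pob_batch` object; see [tidy.pob_batch()], [glance.pob_batch()]
#'   and [autoplot.pob_batch()]
#' @export
run_batch <- function(config, seeds, words_per_batch = NULL) {
  if (is.character(config)) config <- load_profile(config, quiet = TRUE)
  trials <- purrr::map_dfr(seq_along(seeds), function(b) {
    exp <- build_experiment(config, seeds[b])
    ids <- exp$lexicon$items$item_id
    if (!is.null(words_per_batch) && words_per_batch < length(ids)) {
      ids <- with_seed(seed_for(seeds[b], "word_subsample"),
                       safe_sample(ids, words_per_batch))
    }
    sim <- simulate_items(exp, ids)
    purrr::map_dfr(seq_along(ids), function(tr) {
      rec <- trial_record(exp, sim, tr, ids[tr])
      tibble::tibble(
        batch = b, seed = seeds[b], item_id = rec$item_id,
        label = rec$label,
        first_error_position = rec$first_error_position,
        n_utterances = nrow(rec$utterances),
        keeps_speaking = rec$keeps_speaking
      )
    })
  })
  structure(
    list(trials = trials, config = config, seeds = seeds,
         summary = aggregate_errors(trials)),
    class = "pob_batch"
  )
}

#' @export
print.pob_batch <- function(x, ...) {
  cat(sprintf("<pob_batch> %s: %d trials in %d batch(es)\n",
              x$config$profile_name, nrow(x$trials), length(x$seeds)))
  print(x$summary)
  invisible(x)
}

#' Run an ablated variant of the complete model
#'
#' @param config profile name or configuration of the complete model
#' @param flag ablation flag, see [apply_ablation()]
#' @param seeds per-batch seeds
#' @param words_per_batch optional subsampling
#' @return a `pob_batch`
#' @export
run_ablation <- function(config, flag, seeds, words_per_batch = NULL) {
  if (is.character(config)) config <- load_profile(config, quiet = TRUE)
  run_batch(apply_ablation(config, flag), seeds, words_per_batch)
}

#' Cue an item into the lexicon network (reference dynamics)
#'
#' Applies the external cue field for `cue_duration` time units to a
#' stand-alone lexicon network using the plain-R stepper, and returns the
#' final state. Mainly useful for inspecting cue convergence on small
#' networks; full experiments use the batch engine.
#'
#' @param state a [init_network_state()] state of the lexicon network
#' @param params the lexicon [network_params()]
#' @param weights its autoassociative weights
#' @param patterns its [pattern_set()]
#' @param item_pattern index of the pattern to cue
#' @param cue_strength,cue_duration cue field magnitude and duration (time
#'   units)
#' @param extra_steps additional steps to run after cue offset
#' @return the final `network_state`
#' @export
cue_item <- function(state, params, weights, patterns, item_pattern,
                     cue_strength = 1, cue_duration = 10, extra_steps = 0) {
  assert_that(item_pattern >= 1 && item_pattern <= nrow(patterns$states),
              "unknown item pattern")
  xi <- patterns$states[item_pattern, ]
  ext <- matrix(0, params$N, params$S)
  on <- which(xi > 0)
  ext[cbind(on, xi[on])] <- cue_strength
  n_cue <- round(cue_duration / params$dt)
  for (s in seq_len(n_cue)) {
    state <- step_dynamics(state, weights, params, external = ext)
  }
  for (s in seq_len(extra_steps)) {
    state <- step_dynamics(state, weights, params)
  }
  state
}
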