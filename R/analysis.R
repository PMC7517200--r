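#' Overlap of an activation configuration with a stored pattern
#'
#' The standard mean-subtracted Potts order parameter,
#' \deqn{m^\mu = \frac{1}{N_s a (1 - a/S)} \sum_{i \in scope} \sum_{k \ge 1}
#'   (\delta_{\xi_i^\mu k} - a/S)\, \sigma_i^k,}
#' equal to 1 at perfect retrieval and ~0 in the null state or on an
#' unrelated pattern. For cluster-confined patterns pass the cluster's unit
#' range as `scope`.
#'
#' @param sigma `[N x S]` active-state activations (or a `network_state`)
#' @param xi integer pattern row (length `N`, entries `0..S`)
#' @param a pattern sparsity within its scope
#' @param S number of active states
#' @param scope unit indices over which the pattern is defined (default all)
#' @return scalar overlap
#' @export
compute_overlap <- function(sigma, xi, a, S, scope = NULL) {
  if (inherits(sigma, "network_state")) sigma <- sigma$sigma
  scope <- scope %||% seq_along(xi)
  abar <- a / S
  on <- scope[xi[scope] > 0L]
  sig_match <- sum(sigma[cbind(on, xi[on])])
  tot <- sum(sigma[scope, ])
  (sig_match - abar * tot) / (length(scope) * a * (1 - abar))
}

#' State-blind normalized activity of a pattern's units
#'
#' Mean activation (any active state) of the units the pattern recruits:
#' `(1/(aN)) sum_i (1 - sigma_i^0) [xi_i > 0]`. Equals 1 when all recruited
#' units are fully active in any state, ~0 in the null state.
#'
#' @inheritParams compute_overlap
#' @param sigma0 length-`N` quiescent components (or pass a `network_state`
#'   as `sigma`)
#' @return scalar in `[0, 1]`
#' @export
normalized_activity <- function(sigma, xi, sigma0 = NULL) {
  if (inherits(sigma, "network_state")) {
    sigma0 <- sigma$sigma0
  }
  assert_that(!is.null(sigma0), "sigma0 required")
  on <- which(xi > 0L)
  mean(1 - sigma0[on])
}

# long-form trajectory of one trial of a batch simulation
trajectory_tbl <- function(sim, trial) {
  p <- dim(sim$overlap)[3]
  tibble::tibble(
    t = rep(sim$t, each = p),
    pattern = rep(seq_len(p), length(sim$t)),
    overlap = as.vector(t(sim$overlap[trial, , ]))
  )
}

#' Extract the utterance sequence from an overlap trajectory
#'
#' Scans the per-pattern overlap traces and opens an utterance when a pattern
#' crosses `theta_on` while being the dominant pattern; the utterance closes
#' when its overlap falls below `theta_off`, or when another pattern exceeds
#' `theta_on` and leads by at least `overtake_margin`. Episodes shorter than
#' `d_min` time units are discarded. Separate episodes of the same pattern
#' are separate utterances, so perseverations remain observable.
#'
#' @param trajectory tibble with columns `t`, `pattern`, `overlap` (long
#'   form, as produced by the simulators)
#' @param theta_on,theta_off opening/closing thresholds (hysteresis)
#' @param d_min minimum episode duration (time units)
#' @param overtake_margin dominance margin required for a takeover
#' @return tibble with columns `pattern`, `onset`, `offset`, `peak`, ordered
#'   by onset
#' @export
extract_utterances <- function(trajectory, theta_on = 0.5, theta_off = 0.35,
                               d_min = 10, overtake_margin = 0.1) {
  assert_that(theta_on > theta_off, "theta_on must exceed theta_off")
  tt <- sort(unique(trajectory$t))
  pats <- sort(unique(trajectory$pattern))
  M <- matrix(trajectory$overlap[order(trajectory$pattern, trajectory$t)],
              nrow = length(tt), ncol = length(pats))
  cur <- 0L; onset <- 0; peak <- 0
  out <- list()
  close_utt <- function(ti) {
    if (tt[ti] - onset >= d_min) {
      out[[length(out) + 1L]] <<- c(pats[cur], onset, tt[ti], peak)
    }
  }
  for (ti in seq_along(tt)) {
    x <- M[ti, ]
    top <- which.max(x)
    if (cur > 0L) {
      peak <- max(peak, x[cur])
      if (x[cur] < theta_off ||
          (top != cur && x[top] >= theta_on &&
           x[top] > x[cur] + overtake_margin)) {
        close_utt(ti)
        cur <- 0L
      }
    }
    if (cur == 0L && x[top] >= theta_on) {
      cur <- top; onset <- tt[ti]; peak <- x[top]
    }
  }
  if (cur > 0L) close_utt(length(tt))
  if (length(out) == 0) {
    return(tibble::tibble(pattern = integer(0), onset = numeric(0),
                          offset = numeric(0), peak = numeric(0)))
  }
  res <- do.call(rbind, out)
  tibble::tibble(pattern = as.integer(res[, 1]), onset = res[, 2],
                 offset = res[, 3], peak = res[, 4])
}

#' Classify a produced sequence against its target
#'
#' Applies the speech-error taxonomy to the first three utterances:
#' \enumerate{
#'   \item any utterance outside the target set: `wrong_syllable` (insertion)
#'   \item any target uttered more than once: `repetition` (perseveration)
#'   \item fewer than three utterances: `shorter_sequence` (omission)
#'   \item all three targets present but out of order: `wrong_order`
#'     (transposition)
#'   \item otherwise `correct`.
#' }
#' `first_error_position` is the serial position (1-3) of the first utterance
#' deviating from the target order (for omissions, the first missing
#' position), `NA` for correct productions.
#'
#' @param utterances tibble from [extract_utterances()] (or an integer vector
#'   of produced pattern ids)
#' @param target ordered integer triple of target components
#' @return list with `category` and `first_error_position`
#' @export
classify_error <- function(utterances, target) {
  assert_that(length(target) == 3, "target must be a triple")
  produced <- if (is.data.frame(utterances)) utterances$pattern else utterances
  f3 <- utils::head(produced, 3)
  first_dev <- function() {
    d <- which(f3 != target[seq_along(f3)])
    if (length(d)) d[1] else min(length(f3) + 1L, 3L)
  }
  if (length(f3) == 0) {
    return(list(category = "shorter_sequence", first_error_position = 1L))
  }
  if (any(!f3 %in% target)) {
    return(list(category = "wrong_syllable", first_error_position = first_dev()))
  }
  if (anyDuplicated(f3)) {
    return(list(category = "repetition", first_error_position = first_dev()))
  }
  if (length(produced) < 3) {
    return(list(category = "shorter_sequence",
                first_error_position = min(length(produced) + 1L, 3L)))
  }
  if (!all(f3 == target)) {
    return(list(category = "wrong_order", first_error_position = first_dev()))
  }
  list(category = "correct", first_error_position = NA_integer_)
}

ERROR_LEVELS <- c("correct", "wrong_order", "repetition", "shorter_sequence",
                  "wrong_syllable")

#' Aggregate trial labels into an error distribution
#'
#' Per-category percentages with the standard error of the mean across
#' batches (when more than one batch is present) or the binomial SEM across
#' trials otherwise.
#'
#' @param trials tibble with columns `label` and optionally `batch`
#' @return tibble with `category`, `percent`, `sem`
#' @export
aggregate_errors <- function(trials) {
  n <- nrow(trials)
  base <- tibble::tibble(category = factor(ERROR_LEVELS, ERROR_LEVELS))
  pct <- prop.table(table(factor(trials$label, ERROR_LEVELS))) * 100
  has_batch <- "batch" %in% names(trials)
  sems <- if (has_batch && length(unique(trials$batch)) > 1) {
    per_b <- vapply(ERROR_LEVELS, function(lv) {
      x <- tapply(trials$label == lv, trials$batch, mean) * 100
      stats::sd(x) / sqrt(length(x))
    }, numeric(1))
    per_b
  } else {
    p <- as.numeric(pct) / 100
    100 * sqrt(p * (1 - p) / n)
  }
  dplyr::mutate(base, percent = as.numeric(pct), sem = as.numeric(sems))
}

#' Classify the latching regime of a batch of trajectories
#'
#' A batch latches not at all if on average at most ~1.5 patterns are ever
#' well retrieved (pure retrieval of the cue); it latches indefinitely if
#' most runs are still visiting patterns at the horizon; otherwise the
#' sequences are finite.
#'
#' @param sims list of per-trial utterance tibbles (from
#'   [extract_utterances()] with a low `theta_on` if desired) or a
#'   `latching_scan` row's stored measures
#' @param horizon trajectory horizon (time units)
#' @param well_retrieved_peak peak overlap needed to count a pattern as well
#'   retrieved
#' @return one of `"no_latching"`, `"finite"`, `"infinite"`
#' @export
classify_latching_regime <- function(sims, horizon,
                                     well_retrieved_peak = 0.7) {
  assert_that(length(sims) >= 10, "need at least 10 trajectories")
  n_well <- vapply(sims, function(u) {
    length(unique(u$pattern[u$peak >= well_retrieved_peak]))
  }, numeric(1))
  at_horizon <- vapply(sims, function(u) {
    nrow(u) > 0 && max(u$offset) >= 0.95 * horizon
  }, logical(1))
  if (mean(n_well) <= 1.5) return("no_latching")
  if (mean(at_horizon) >= 0.8) return("infinite")
  "finite"
}

#' Pattern-load scan of the latching regimes
#'
#' Runs a stand-alone adaptive network at several pattern loads `p`, cueing
#' one random stored pattern per trial, and summarizes each load by the mean
#' number of well-retrieved patterns per trajectory, the mean retrieval
#' quality (mean peak overlap of visited patterns), sequence persistence and
#' the classified regime.
#'
#' @param p_values pattern loads to scan
#' @param n_trials trajectories per load
#' @param seed master seed
#' @param config single-network profile (defaults to the latching-scan
#'   profile; `N` may be scaled down for speed)
#' @param N override the profile's network size
#' @return a `latching_scan` tibble, one row per load
#' @export
run_latching_scan <- function(p_values = c(50, 90, 200), n_trials = 10, seed = 1,
                              config = load_profile("fig_latching_scan",
                                                    quiet = TRUE),
                              N = NULL) {
  if (is.character(config)) config <- load_profile(config, quiet = TRUE)
  if (!is.null(N)) config$net$N <- N
  dt <- config$protocol$dt
  par <- params_from_block(config$net, dt)
  purrr::map_dfr(p_values, function(p) {
    ps <- generate_random_patterns(par$N, par$S, par$a, p,
                                   seed_for(seed, sprintf("patterns_p%d", p)))
    conn <- build_connectivity(par$N, par$N, par$C_m,
                               seed = seed_for(seed, sprintf("conn_p%d", p)))
    J <- store_autoassociative(ps, conn, par$S, par$a)
    cued <- with_seed(seed_for(seed, sprintf("cues_p%d", p)),
                      sample.int(p, n_trials, replace = p < n_trials))
    cues <- data.frame(trial = seq_len(n_trials), pattern = cued, onset = 0,
                       duration = config$protocol$cue_duration,
                       strength = config$protocol$cue_strength)
    buffer <- net_for_engine(par, conn, J)
    sim <- run_engine(buffer, NULL, cues, ps$states, NULL, n_trials,
                      config$protocol, early_stop = FALSE)
    utts <- lapply(seq_len(n_trials), function(tr) {
      extract_utterances(trajectory_tbl(sim, tr),
                         theta_on = config$protocol$theta_on,
                         theta_off = config$protocol$theta_off,
                         d_min = config$protocol$d_min,
                         overtake_margin = config$protocol$overtake_margin)
    })
    n_well <- vapply(utts, function(u) {
      length(unique(u$pattern[u$peak >= 0.7]))
    }, numeric(1))
    quality <- vapply(utts, function(u) {
      if (nrow(u) == 0) NA_real_ else mean(u$peak)
    }, numeric(1))
    seq_len_mean <- vapply(utts, nrow, numeric(1))
    tibble::tibble(
      p = p,
      mean_well_retrieved = mean(n_well),
      mean_sequence_length = mean(seq_len_mean),
      mean_quality = mean(quality, na.rm = TRUE),
      regime = classify_latching_regime(utts, config$protocol$T_max)
    )
  })
}

#' Co-activation diagnostic of the three target syllables
#'
#' During word production the units of the three target syllables can stay
#' simultaneously active instead of taking turns. Two readings of this
#' co-activation are computed per trial, both over the production window
#' (first utterance onset to last utterance offset, or the cue window when
#' nothing is produced):
#' \describe{
#'   \item{`min_activity`}{minimum over time of the smallest per-syllable
#'     state-blind normalized activity (the units each syllable recruits);}
#'   \item{`min_shared`}{minimum over time of the smallest pairwise mean
#'     activation of the units two target syllables share.}
#' }
#'
#' @param config profile name or configuration (typically the intermediate
#'   model with fast inhibition and constant threshold)
#' @param seeds per-batch seeds
#' @param words_per_batch optional subsampling
#' @return tibble with one row per trial and the two readings
#' @export
coactivation_diagnostic <- function(config, seeds, words_per_batch = NULL) {
  if (is.character(config)) config <- load_profile(config, quiet = TRUE)
  purrr::map_dfr(seq_along(seeds), function(b) {
    exp <- build_experiment(config, seeds[b])
    ids <- exp$lexicon$items$item_id
    if (!is.null(words_per_batch) && words_per_batch < length(ids)) {
      ids <- with_seed(seed_for(seeds[b], "word_subsample"),
                       safe_sample(ids, words_per_batch))
    }
    sim <- simulate_items(exp, ids)
    purrr::map_dfr(seq_along(ids), function(tr) {
      utt <- extract_utterances(
        trajectory_tbl(sim, tr),
        theta_on = config$protocol$theta_on,
        theta_off = config$protocol$theta_off,
        d_min = config$protocol$d_min,
        overtake_margin = config$protocol$overtake_margin
      )
      window <- if (nrow(utt) > 0) {
        c(min(utt$onset), max(utt$offset))
      } else {
        c(0, config$protocol$cue_duration)
      }
      sel <- sim$t >= window[1] & sim$t <= window[2]
      act <- matrix(sim$activity[tr, sel, ], ncol = 3)
      shr <- matrix(sim$shared[tr, sel, ], ncol = 3)
      tibble::tibble(
        batch = b, item_id = ids[tr],
        min_activity = min(apply(act, 1, min)),
        min_shared = min(apply(shr, 1, min))
      )
    })
  })
}

#' Working-memory kick experiment
#'
#' Temporarily lowers the adaptive thresholds of the states belonging to `M`
#' patterns held in working memory, cues one of them, lets the network latch
#' freely, and measures which fraction of the subsequent well-retrieved
#' transitions land on working-memory patterns.
#'
#' @param M number of patterns held in working memory
#' @param delta_theta kick magnitude(s) to test
#' @param n_trials trajectories per kick magnitude
#' @param seed master seed
#' @param config single-network latching profile
#' @param N,p network size and pattern load
#' @return tibble with one row per `delta_theta`: the selectivity (fraction
#'   of transitions landing on WM patterns) and the transition count
#' @export
run_wm_kick_experiment <- function(M, delta_theta, n_trials = 10, seed = 1,
                                   config = load_profile("fig_latching_scan",
                                                         quiet = TRUE),
                                   N = 400, p = 200) {
  if (is.character(config)) config <- load_profile(config, quiet = TRUE)
  config$net$N <- N
  par <- params_from_block(config$net, config$protocol$dt)
  ps <- generate_random_patterns(par$N, par$S, par$a, p,
                                 seed_for(seed, "wm_patterns"))
  conn <- build_connectivity(par$N, par$N, par$C_m,
                             seed = seed_for(seed, "wm_conn"))
  J <- store_autoassociative(ps, conn, par$S, par$a)
  wm_ids <- with_seed(seed_for(seed, "wm_set"), sample.int(p, M))
  cued <- with_seed(seed_for(seed, "wm_cues"),
                    safe_sample(wm_ids, n_trials, replace = M < n_trials))
  purrr::map_dfr(delta_theta, function(dth) {
    kick <- apply_wm_kick(ps, wm_ids, dth)
    cues <- data.frame(trial = seq_len(n_trials), pattern = cued, onset = 0,
                       duration = config$protocol$cue_duration,
                       strength = config$protocol$cue_strength)
    buffer <- net_for_engine(par, conn, J)
    sim <- run_engine(buffer, NULL, cues, ps$states, NULL, n_trials,
                      config$protocol, early_stop = FALSE, kick = kick)
    landed <- unlist(lapply(seq_len(n_trials), function(tr) {
      u <- extract_utterances(trajectory_tbl(sim, tr),
                              theta_on = config$protocol$theta_on,
                              theta_off = config$protocol$theta_off,
                              d_min = config$protocol$d_min,
                              overtake_margin = config$protocol$overtake_margin)
      u <- u[u$peak >= 0.7, ]
      # transitions: every well-retrieved utterance after the cued one
      if (nrow(u) > 1) u$pattern[-1] else integer(0)
    }))
    tibble::tibble(
      M = M, delta_theta = dth,
      n_transitions = length(landed),
      selectivity = if (length(landed)) mean(landed %in% wm_ids) else NA_real_
    )
  })
}
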