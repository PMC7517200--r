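#' Per-(unit, state) adaptation maps for the mixed sign/word buffer
#'
#' Sign elements are retrieved by sustained, simultaneous activation and must
#' not fatigue quickly, so the fast-adaptation share of a (unit, state) pair
#' depends on who recruits it: 0 if only gesture elements do, `0.5 *
#' n_syll / (n_sign + n_syll)` if both kinds do, and 0.5 otherwise. The
#' adaptation rates themselves are randomized across (unit, state) pairs:
#' `1/tau2_fast ~ N(b_fast, b_slow/4)` and `1/tau2_slow ~ N(b_slow,
#' b_slow/4)`, truncated to keep the rates positive.
#'
#' @param gestures clustered gesture-element [pattern_set()]
#' @param syllables syllable [pattern_set()] on the same units
#' @param b_fast,b_slow mean adaptation rates (inverse timescales)
#' @param seed RNG seed for the rate draws
#' @return list with `[N x S]` matrices `gamma2_fast`, `tau2_fast`,
#'   `tau2_slow`
#' @export
build_sob_adaptation_profile <- function(gestures, syllables,
                                         b_fast = 0.09, b_slow = 0.03, seed) {
  N <- ncol(gestures$states); S <- gestures$S
  n_sign <- matrix(0L, N, S)
  n_syll <- matrix(0L, N, S)
  count_into <- function(m, states) {
    for (mu in seq_len(nrow(states))) {
      on <- which(states[mu, ] > 0L)
      m[cbind(on, states[mu, on])] <- m[cbind(on, states[mu, on])] + 1L
    }
    m
  }
  n_sign <- count_into(n_sign, gestures$states)
  n_syll <- count_into(n_syll, syllables$states)

  g2f <- matrix(0.5, N, S)
  only_sign <- n_sign > 0L & n_syll == 0L
  both <- n_sign > 0L & n_syll > 0L
  g2f[only_sign] <- 0
  g2f[both] <- 0.5 * n_syll[both] / (n_sign[both] + n_syll[both])

  rates <- with_seed(seed, {
    rf <- stats::rnorm(N * S, b_fast, b_slow / 4)
    rs <- stats::rnorm(N * S, b_slow, b_slow / 4)
    list(rf = pmax(rf, 1e-4), rs = pmax(rs, 1e-4))
  })
  list(
    gamma2_fast = g2f,
    tau2_fast = matrix(1 / rates$rf, N, S),
    tau2_slow = matrix(1 / rates$rs, N, S)
  )
}

#' Assemble a mixed sign/word production experiment
#'
#' The buffer stores gesture elements (confined to three equal unit
#' clusters), syllables (whole-network) and random distractor patterns, all
#' in one autoassociative weight tensor; the lexicon stores word/sign
#' patterns and couples to the buffer through the instruction matrix. The
#' dynamic threshold is cluster-wise: each cluster carries its own
#' activity-dependent threshold component.
#'
#' @param config an [load_profile()] configuration of kind `"sob"`
#' @param seed master seed
#' @return a `sob_experiment` object
#' @export
build_sob_experiment <- function(config, seed) {
  stopifnot(inherits(config, "experiment_config"))
  assert_that(identical(config$kind, "sob"), "config must be an sob profile")
  dt <- config$protocol$dt
  pol_par <- params_from_block(config$pol, dt)
  pob_par <- params_from_block(config$pob, dt)
  sb <- config$sob

  gestures <- generate_cluster_patterns(
    pob_par$N, sb$n_clusters, sb$a_sign, sb$n_gestures,
    seed_for(seed, "gestures"), S = pob_par$S
  )
  syllables <- generate_random_patterns(
    pob_par$N, pob_par$S, pob_par$a, sb$n_syllables,
    seed_for(seed, "syllables")
  )
  n_structured <- sb$n_gestures + sb$n_syllables
  distractors <- generate_random_patterns(
    pob_par$N, pob_par$S, pob_par$a, config$pob$p - n_structured,
    seed_for(seed, "distractors")
  )
  states <- rbind(gestures$states, syllables$states, distractors$states)
  buf_ps <- pattern_set(states, a = pob_par$a, S = pob_par$S,
                        cluster_bounds = gestures$cluster_bounds,
                        cluster_of = c(gestures$cluster_of,
                                       rep(0L, nrow(states) - sb$n_gestures)))

  pol_ps <- generate_random_patterns(pol_par$N, pol_par$S, pol_par$a,
                                     config$pol$p, seed_for(seed, "patterns_pol"))
  lexicon <- compose_mixed_lexicon(
    gestures, syllables, sb$n_signs, sb$n_words,
    seed_for(seed, "lexicon"), p_lexicon = config$pol$p,
    g_cascade = unlist(config$coupling$g_cascade),
    lambda_word = config$coupling$lambda_word,
    lambda_sign = config$coupling$lambda_sign
  )

  conn_pol <- build_connectivity(pol_par$N, pol_par$N, pol_par$C_m,
                                 seed = seed_for(seed, "conn_pol"))
  conn_pob <- build_connectivity(pob_par$N, pob_par$N, pob_par$C_m,
                                 seed = seed_for(seed, "conn_pob"))
  conn_het <- build_connectivity(pob_par$N, pol_par$N, config$coupling$C_m_het,
                                 self_allowed = TRUE,
                                 seed = seed_for(seed, "conn_het"))
  adapt <- build_sob_adaptation_profile(gestures, syllables, sb$b_fast,
                                        sb$b_slow, seed_for(seed, "adaptation"))
  pob_par$gamma2_fast <- adapt$gamma2_fast
  pob_par$tau2_fast <- adapt$tau2_fast
  pob_par$tau2_slow <- adapt$tau2_slow

  n_c <- pob_par$N %/% sb$n_clusters
  cluster_of_unit <- rep(seq_len(sb$n_clusters), each = n_c)

  structure(
    list(
      config = config, seed = seed,
      pol_params = pol_par, pob_params = pob_par,
      gestures = gestures, syllables = syllables,
      pol_patterns = pol_ps, pob_patterns = buf_ps,
      lexicon = lexicon,
      cluster_of_unit = as.integer(cluster_of_unit),
      gesture_ids = seq_len(sb$n_gestures),
      syllable_ids = sb$n_gestures + seq_len(sb$n_syllables),
      J_pol = store_autoassociative(pol_ps, conn_pol, pol_par$S, pol_par$a),
      J_pob = store_autoassociative(buf_ps, conn_pob, pob_par$S, pob_par$a),
      J_het = store_heteroassociative(pol_ps, buf_ps, lexicon, conn_het,
                                      gain = config$coupling$gain %||% 1,
                                      S = pob_par$S, a = pob_par$a)
    ),
    class = "sob_experiment"
  )
}

#' @export
print.sob_experiment <- function(x, ...) {
  cat(sprintf("<sob_experiment> %s, seed %d: %d gestures + %d syllables, %d items\n",
              x$config$profile_name, x$seed, length(x$gesture_ids),
              length(x$syllable_ids), nrow(x$lexicon$items)))
  invisible(x)
}

sob_measure <- function(exp) {
  par <- exp$pob_params
  sb <- exp$config$sob
  p <- nrow(exp$pob_patterns$states)
  n_c <- par$N %/% sb$n_clusters
  cluster_of_pattern <- exp$pob_patterns$cluster_of
  norm <- ifelse(cluster_of_pattern > 0,
                 1 / (n_c * sb$a_sign * (1 - sb$a_sign / par$S)),
                 1 / (par$N * par$a * (1 - par$a / par$S)))
  abar <- ifelse(cluster_of_pattern > 0, sb$a_sign / par$S, par$a / par$S)
  list(
    norm = norm, abar = abar, scope = as.integer(cluster_of_pattern),
    cluster_of_unit = exp$cluster_of_unit,
    n_clusters = as.integer(sb$n_clusters)
  )
}

sob_engine_nets <- function(exp) {
  sb <- exp$config$sob
  n_c <- exp$pob_params$N %/% sb$n_clusters
  buffer <- net_for_engine(
    exp$pob_params, exp$J_pob$conn, exp$J_pob,
    hetero = list(adj = exp$J_het$conn$idx, J = exp$J_het$values),
    dyn_scope = exp$cluster_of_unit,
    dyn_norm = rep(exp$pob_params$threshold_scale * n_c, sb$n_clusters)
  )
  source <- net_for_engine(exp$pol_params, exp$J_pol$conn, exp$J_pol)
  list(buffer = buffer, source = source)
}

#' Produce a sequence of signs and words
#'
#' Cues the listed lexicon items one after another at a fixed inter-cue
#' interval within a single simulation, and scores each item: a sign is
#' correctly retrieved when its three gesture elements are simultaneously
#' sustained (each dominant within its own cluster); a word is scored by
#' sequential utterance extraction over the syllable and distractor patterns
#' as in the spoken buffer.
#'
#' @param config profile name or configuration of kind `"sob"`
#' @param items integer vector of lexicon item ids to cue, in order
#' @param inter_cue_interval time between successive cue onsets (time units)
#' @param seed master seed
#' @param exp optionally a prebuilt [build_sob_experiment()] (overrides
#'   `config`/`seed`)
#' @return a `sob_sequence` object with one record per cued item
#' @export
run_sob_sequence <- function(config, items, inter_cue_interval = NULL, seed = 1,
                             exp = NULL) {
  if (is.null(exp)) {
    if (is.character(config)) config <- load_profile(config, quiet = TRUE)
    exp <- build_sob_experiment(config, seed)
  }
  cfg <- exp$config
  ici <- inter_cue_interval %||% cfg$protocol$inter_cue_interval
  n_items <- length(items)
  if (n_items == 0) {
    return(structure(list(records = list(), items = integer(0)),
                     class = "sob_sequence"))
  }
  it <- exp$lexicon$items[match(items, exp$lexicon$items$item_id), ]
  cues <- data.frame(
    trial = 1L, pattern = it$lexicon_pattern,
    onset = (seq_len(n_items) - 1) * ici,
    duration = cfg$protocol$cue_duration,
    strength = cfg$protocol$cue_strength
  )
  protocol <- cfg$protocol
  protocol$T_max <- (n_items - 1) * ici + protocol$T_max
  nets <- sob_engine_nets(exp)
  sim <- run_engine(nets$buffer, nets$source, cues, exp$pob_patterns$states,
                    exp$pol_patterns$states, 1L, protocol,
                    measure = sob_measure(exp),
                    src_watch = matrix(it$lexicon_pattern, ncol = 1),
                    early_stop = FALSE)
  records <- lapply(seq_len(n_items), function(ii) {
    window <- c((ii - 1) * ici, (ii - 1) * ici + ici)
    score_sob_item(exp, sim, trial = 1, item = it[ii, ], window = window)
  })
  structure(list(records = records, items = items, sim = sim, exp = exp),
            class = "sob_sequence")
}

# score one cued item within its time window
score_sob_item <- function(exp, sim, trial, item, window) {
  cfg <- exp$config
  target <- c(item$c1, item$c2, item$c3)
  sel <- sim$t >= window[1] & sim$t < window[2]
  if (item$item_kind == "sign") {
    # simultaneity: all three elements above threshold at once, each the
    # dominant element within its own cluster
    ok_t <- rep(TRUE, sum(sel))
    act <- matrix(NA_real_, sum(sel), 3)
    for (ci in 1:3) {
      el <- target[ci]
      cl <- exp$pob_patterns$cluster_of[el]
      rivals <- setdiff(which(exp$pob_patterns$cluster_of == cl), el)
      m_el <- sim$overlap[trial, sel, el]
      riv_ov <- matrix(sim$overlap[trial, sel, rivals], ncol = length(rivals))
      m_riv <- apply(riv_ov, 1, max)
      act[, ci] <- m_el
      ok_t <- ok_t & (m_el > 0.5) & (m_el >= m_riv)
    }
    need <- ceiling(50 / cfg$protocol$record_dt)
    runs <- rle(ok_t)
    sustained <- any(runs$lengths[runs$values] >= need)
    list(item_id = item$item_id, kind = "sign", target = target,
         correct = isTRUE(sustained),
         label = if (isTRUE(sustained)) "correct" else "sign_failure",
         min_element_overlap = suppressWarnings(min(apply(act, 2, max))))
  } else {
    traj <- tibble::tibble(
      t = rep(sim$t[sel], each = dim(sim$overlap)[3]),
      pattern = rep(seq_len(dim(sim$overlap)[3]), sum(sel)),
      overlap = as.vector(t(sim$overlap[trial, sel, ]))
    )
    utt <- extract_utterances(traj, cfg$protocol$theta_on,
                              cfg$protocol$theta_off, cfg$protocol$d_min,
                              cfg$protocol$overtake_margin)
    lab <- classify_error(utt, target)
    gesture_intrusion <- any(utt$pattern %in% exp$gesture_ids)
    list(item_id = item$item_id, kind = "word", target = target,
         correct = lab$category == "correct", label = lab$category,
         utterances = utt, gesture_intrusion = gesture_intrusion)
  }
}

#' Cue every stored sign and word once
#'
#' Runs one independent trial per lexicon item (batched in a single engine
#' call) and tabulates correctness and cross-class intrusions: gesture
#' elements retrieved during word trials or syllables retrieved during sign
#' trials.
#'
#' @param config profile name or configuration of kind `"sob"`
#' @param seed master seed
#' @return a `sob_batch` object with `$trials` and intrusion counts
#' @export
run_sob_batch <- function(config, seed = 1) {
  if (is.character(config)) config <- load_profile(config, quiet = TRUE)
  exp <- build_sob_experiment(config, seed)
  cfg <- exp$config
  it <- exp$lexicon$items
  n <- nrow(it)
  cues <- data.frame(
    trial = seq_len(n), pattern = it$lexicon_pattern, onset = 0,
    duration = cfg$protocol$cue_duration, strength = cfg$protocol$cue_strength
  )
  nets <- sob_engine_nets(exp)
  sim <- run_engine(nets$buffer, nets$source, cues, exp$pob_patterns$states,
                    exp$pol_patterns$states, n, cfg$protocol,
                    measure = sob_measure(exp),
                    src_watch = matrix(it$lexicon_pattern, 1, n))
  # production episode: the cue window plus a settling margin; spontaneous
  # latching long after the episode is tracked separately, not as intrusion
  horizon <- c(0, cfg$protocol$cue_duration + 50)
  trials <- purrr::map_dfr(seq_len(n), function(tr) {
    rec <- score_sob_item(exp, sim, tr, it[tr, ], horizon)
    syll_intrusion <- if (rec$kind == "sign") {
      # any non-gesture pattern extracted as an utterance during a sign trial
      traj <- trajectory_tbl(sim, tr)
      traj <- traj[traj$t >= horizon[1] & traj$t < horizon[2], ]
      utt <- extract_utterances(traj, cfg$protocol$theta_on,
                                cfg$protocol$theta_off, cfg$protocol$d_min,
                                cfg$protocol$overtake_margin)
      any(!utt$pattern %in% exp$gesture_ids)
    } else {
      NA
    }
    tibble::tibble(
      item_id = rec$item_id, kind = rec$kind, correct = rec$correct,
      label = rec$label,
      gesture_intrusion = rec$gesture_intrusion %||% NA,
      syllable_intrusion = syll_intrusion
    )
  })
  structure(list(trials = trials, exp = exp, seed = seed), class = "sob_batch")
}

#' @export
print.sob_batch <- function(x, ...) {
  tr <- x$trials
  cat(sprintf("<sob_batch> %d trials: signs %d/%d correct, words %d/%d correct\n",
              nrow(tr),
              sum(tr$correct[tr$kind == "sign"]), sum(tr$kind == "sign"),
              sum(tr$correct[tr$kind == "word"]), sum(tr$kind == "word")))
  cat(sprintf("  gesture intrusions in word trials: %d; syllable intrusions in sign trials: %d\n",
              sum(tr$gesture_intrusion, na.rm = TRUE),
              sum(tr$syllable_intrusion, na.rm = TRUE)))
  invisible(x)
}
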