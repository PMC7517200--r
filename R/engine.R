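# Internal bridge between the R-level objects and the compiled batch engine.

net_for_engine <- function(params, conn, weights, hetero = NULL,
                           dyn_scope = NULL, dyn_norm = NULL) {
  lst <- list(
    N = params$N, S = params$S, a = params$a, w = params$w,
    beta = params$beta, U = params$U, tau1 = params$tau1,
    tau_A = params$tau_A, tau_B = params$tau_B, gamma_A = params$gamma_A,
    dt = params$dt, tau_U = params$tau_U,
    adj = conn$idx, J = weights$values,
    tau2_fast = params$tau2_fast, tau2_slow = params$tau2_slow,
    gamma2_fast = params$gamma2_fast,
    dynamic_threshold = params$dynamic_threshold,
    het = hetero
  )
  if (params$dynamic_threshold) {
    lst$dyn_scope <- dyn_scope %||% rep(1L, params$N)
    lst$dyn_norm <- dyn_norm %||%
      (params$threshold_scale * tabulate(lst$dyn_scope, max(lst$dyn_scope)))
  }
  lst
}

# Run a batch of independent trials (or one multi-cue trial per column).
# cues: data.frame(trial, pattern, onset, duration, strength) -- onsets and
# durations in time units; converted to steps here.
run_engine <- function(buffer, source = NULL, cues, xi_buf, xi_src = NULL,
                       n_trials, protocol,
                       watch = NULL, src_watch = NULL,
                       measure = NULL, early_stop = TRUE, kick = NULL) {
  dt <- protocol$dt
  steps <- function(x) as.integer(round(x / dt))
  cue_schedule <- list(
    trial = as.integer(cues$trial),
    pattern = as.integer(cues$pattern),
    onset = steps(cues$onset),
    duration = steps(cues$duration),
    strength = as.numeric(cues$strength)
  )
  if (!is.null(kick)) buffer$kick <- kick

  p_buf <- nrow(xi_buf)
  if (is.null(measure)) {
    S <- buffer$S; a <- buffer$a; N <- buffer$N
    measure <- list(
      norm = rep(1 / (N * a * (1 - a / S)), p_buf),
      abar = rep(a / S, p_buf),
      scope = rep(0L, p_buf),
      cluster_of_unit = rep(0L, N),
      n_clusters = 0L
    )
  }
  measure$watch <- watch %||% matrix(0L, 0, n_trials)
  measure$src_watch <- src_watch %||% matrix(0L, 0, n_trials)

  control <- list(
    n_trials = as.integer(n_trials),
    T_max = steps(protocol$T_max),
    record_every = max(1L, steps(protocol$record_dt)),
    early_stop = isTRUE(early_stop),
    stop_level = 0.25,
    stop_after = steps(protocol$T_max / 2),
    stop_window = 25L,
    init_eps = 1e-3
  )
  res <- simulate_potts_batch_cpp(buffer, source, cue_schedule, xi_buf,
                                  measure, xi_src, control)
  n_rec <- res$dims[2]
  used <- seq_len(res$n_rec_used)
  shape <- function(x, d3) {
    if (length(x) == 0) return(NULL)
    array(x, c(n_trials, n_rec, d3))[, used, , drop = FALSE]
  }
  structure(
    list(
      overlap = shape(res$overlap_buffer, p_buf),
      overlap_source = shape(res$overlap_source, nrow(measure$src_watch)),
      activity = shape(res$watch_activity, nrow(measure$watch)),
      shared = shape(res$watch_shared,
                     max(0, nrow(measure$watch) * (nrow(measure$watch) - 1) / 2)),
      u_hat = shape(res$u_hat, length(res$u_hat) / (n_rec * n_trials)),
      t = res$t_rec[used] * dt,
      steps_run = res$steps_run,
      final_buffer = res$final_buffer,
      final_source = res$final_source
    ),
    class = "potts_sim"
  )
}
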