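# The compiled batch engine and the plain-R stepper implement the same
# dynamics; they are compared here on small networks.

engine_run <- function(net, params, cue_pattern, n_steps, kick = NULL,
                       n_trials = 1) {
  buffer <- pottsbuffer:::net_for_engine(params, net$conn, net$weights)
  protocol <- list(dt = params$dt, T_max = n_steps * params$dt,
                   record_dt = params$dt)
  cues <- data.frame(trial = seq_len(n_trials), pattern = cue_pattern,
                     onset = 0, duration = 10, strength = 1)
  pottsbuffer:::run_engine(buffer, NULL, cues, net$patterns$states, NULL,
                           n_trials, protocol, early_stop = FALSE,
                           kick = kick)
}

test_that("compiled engine reproduces the reference stepper", {
  net <- tiny_network(N = 18, S = 3, a = 0.5, C_m = 7, p = 3, seed = 91,
                      dynamic_threshold = TRUE)
  n_steps <- 60
  sim <- engine_run(net, net$params, cue_pattern = 1, n_steps = n_steps)

  state <- init_network_state(net$params)
  ext <- matrix(0, 18, 3)
  xi <- net$patterns$states[1, ]
  on <- which(xi > 0)
  ext[cbind(on, xi[on])] <- 1
  n_cue <- round(10 / net$params$dt)
  for (s in seq_len(n_steps)) {
    state <- step_dynamics(state, net$weights, net$params,
                           external = if (s <= n_cue) ext)
  }
  fin <- sim$final_buffer
  expect_equal(matrix(fin$sigma, 18, 3, byrow = TRUE), state$sigma,
               tolerance = 1e-8)
  expect_equal(matrix(fin$r, 18, 3, byrow = TRUE), state$r, tolerance = 1e-8)
  expect_equal(matrix(fin$theta_fast + fin$theta_slow, 18, 3, byrow = TRUE),
               state$theta_fast + state$theta_slow, tolerance = 1e-8)
  expect_equal(fin$theta_A, state$theta_A, tolerance = 1e-8)
  expect_equal(fin$U_hat, state$U_hat, tolerance = 1e-8)
  # and the recorded overlap agrees with the R-side order parameter
  m_ref <- compute_overlap(state$sigma, xi, 0.5, 3)
  expect_equal(sim$overlap[1, dim(sim$overlap)[2], 1], m_ref,
               tolerance = 1e-8)
})

test_that("engine honors the working-memory kick and is trial-batched", {
  net <- tiny_network(N = 18, S = 3, a = 0.5, C_m = 7, p = 4, seed = 92)
  kick <- apply_wm_kick(net$patterns, c(2, 3), 0.08)
  sim2 <- engine_run(net, net$params, cue_pattern = c(2, 2), n_steps = 50,
                     kick = kick, n_trials = 2)
  sim1 <- engine_run(net, net$params, cue_pattern = 2, n_steps = 50,
                     kick = kick, n_trials = 1)
  # identical trials inside one batch evolve identically, and match the
  # same trial run alone
  expect_equal(sim2$overlap[1, , ], sim2$overlap[2, , ], tolerance = 1e-12)
  expect_equal(sim2$overlap[1, , ], sim1$overlap[1, , ], tolerance = 1e-12)

  # a zero kick equals no kick
  sim0 <- engine_run(net, net$params, 2, 50,
                     kick = matrix(0, 18, 3), n_trials = 1)
  simn <- engine_run(net, net$params, 2, 50, kick = NULL, n_trials = 1)
  expect_equal(sim0$overlap, simn$overlap, tolerance = 1e-12)

  # reference stepper agrees with the kicked engine
  state <- init_network_state(net$params)
  ext <- matrix(0, 18, 3)
  xi <- net$patterns$states[2, ]
  on <- which(xi > 0)
  ext[cbind(on, xi[on])] <- 1
  for (s in 1:50) {
    state <- step_dynamics(state, net$weights, net$params,
                           external = if (s <= 20) ext, kick = kick)
  }
  fin <- sim1$final_buffer
  expect_equal(matrix(fin$sigma, 18, 3, byrow = TRUE), state$sigma,
               tolerance = 1e-8)
})

test_that("retrieval far below capacity is sustained above 0.9", {
  # p = 10 patterns in a network whose capacity is ~ C S^2 / a >> p;
  # adaptation disabled by pushing tau2 out of reach; U raised so the
  # non-pattern units are properly quiescent
  params <- network_params(N = 300, S = 7, a = 0.25, C_m = 150, w = 0.8,
                           U = 0.3, tau2_fast = 1e8, tau2_slow = 1e8,
                           gamma2_fast = 1, gamma_A = 0, dt = 0.5)
  ps <- generate_random_patterns(300, 7, 0.25, 10, seed = 93)
  conn <- build_connectivity(300, 300, 150, seed = 94)
  net <- list(params = params, patterns = ps, conn = conn,
              weights = store_autoassociative(ps, conn))
  sim <- engine_run(net, params, cue_pattern = 4, n_steps = 600)
  m <- sim$overlap[1, , 4]
  late <- m[seq(length(m) * 0.5, length(m))]
  expect_true(all(late > 0.9))
})

test_that("halving dt changes small-network trajectories only slightly", {
  net <- tiny_network(N = 30, S = 3, a = 0.4, C_m = 12, p = 3, seed = 95,
                      dt = 0.5)
  sim_a <- engine_run(net, net$params, 1, n_steps = 200)
  params_b <- net$params
  params_b$dt <- 0.25
  sim_b <- engine_run(net, params_b, 1, n_steps = 400)
  # compare the cued pattern's overlap on the common time grid
  ta <- sim_a$t; tb <- sim_b$t
  common <- intersect(ta, tb)
  ma <- sim_a$overlap[1, match(common, ta), 1]
  mb <- sim_b$overlap[1, match(common, tb), 1]
  expect_lt(max(abs(ma - mb)), 0.05)
})
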