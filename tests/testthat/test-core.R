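test_that("connectivity has exactly C_m inputs per unit and no self loops", {
  conn <- build_connectivity(40, 40, 15, seed = 1)
  adj <- as_adjacency_matrix(conn)
  expect_equal(unname(rowSums(adj)), rep(15, 40))
  expect_true(all(diag(adj) == 0))
  # full connectivity with self allowed
  full <- build_connectivity(10, 10, 10, self_allowed = TRUE, seed = 2)
  expect_true(all(as_adjacency_matrix(full) == 1))
  # determinism
  expect_identical(build_connectivity(30, 50, 20, seed = 3)$idx,
                   build_connectivity(30, 50, 20, seed = 3)$idx)
  expect_error(build_connectivity(10, 10, 10, seed = 1), "exceeds")
})

test_that("packed autoassociative weights match the direct storage rule", {
  net <- tiny_network(N = 10, S = 3, a = 0.5, C_m = 4, p = 2, seed = 21)
  for (i in c(1, 5, 10)) {
    for (ci in c(1, 4)) {
      j <- net$conn$idx[i, ci]
      blk <- weight_block(net$weights, i, j)
      for (k in 1:3) {
        for (l in 1:3) {
          expect_equal(blk[k, l], oracle_weight(net$patterns, 4, i, k, j, l),
                       tolerance = 1e-12)
        }
      }
    }
  }
  # unconnected pair contributes a zero block
  j_out <- setdiff(1:10, c(net$conn$idx[1, ], 1))[1]
  expect_equal(weight_block(net$weights, 1, j_out), matrix(0, 3, 3))
})

test_that("hand-evaluated two-unit weight matches the storage rule", {
  # N=2, S=2, a=0.5, C_m=1, one pattern xi=(1,2):
  # J_12^{1,2} = (1-0.25)^2 / (1*0.5*0.75) = 1.5
  ps <- pattern_set(matrix(c(1L, 2L), 1, 2), a = 0.5, S = 2)
  conn <- build_connectivity(2, 2, 1, seed = 1)
  w <- store_autoassociative(ps, conn)
  expect_equal(weight_block(w, 1, 2)[1, 2], 1.5, tolerance = 1e-12)
})

test_that("empty pattern set stores zero weights", {
  ps <- pattern_set(matrix(integer(0), 0, 8), a = 0.5, S = 3)
  conn <- build_connectivity(8, 8, 3, seed = 4)
  w <- store_autoassociative(ps, conn)
  expect_true(all(w$values == 0))
})

test_that("stored weights average to zero over random pattern draws", {
  vals <- vapply(1:60, function(s) {
    ps <- generate_random_patterns(12, 3, 0.5, 4, seed = 1000 + s)
    conn <- build_connectivity(12, 12, 5, seed = 17)
    w <- store_autoassociative(ps, conn)
    w$values[1]
  }, numeric(1))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * se + 1e-12)
})

test_that("field on a clamped stored pattern is positive exactly on it", {
  net <- tiny_network(N = 12, S = 3, a = 0.5, C_m = 11, p = 1, seed = 31)
  xi <- net$patterns$states[1, ]
  sigma <- matrix(0, 12, 3)
  on <- which(xi > 0)
  sigma[cbind(on, xi[on])] <- 1
  state <- init_network_state(net$params)
  state$sigma <- sigma
  params0 <- net$params
  params0$w <- 0 # isolate the recurrent term
  h <- compute_field(state, net$weights, params0)
  expect_true(all(h[cbind(on, xi[on])] > 0))
  off_states <- h
  off_states[cbind(on, xi[on])] <- NA
  expect_true(all(off_states <= 1e-9, na.rm = TRUE))
})

test_that("uniform activations cancel the local feedback term", {
  net <- tiny_network(N = 8, S = 3, a = 0.5, C_m = 4, p = 0, seed = 41)
  state <- init_network_state(net$params)
  state$sigma <- matrix(0.2, 8, 3)
  h <- compute_field(state, net$weights, net$params)
  # all-zero weights (p = 0), so only the w-term could contribute; the
  # mean-subtraction kills it for uniform rows
  expect_equal(max(abs(h)), 0)
})

test_that("softmax activation update matches scalar arithmetic", {
  # beta=12.5, S=2, r=(0.2, 0), theta0+U = 0.1
  r <- matrix(c(0.2, 0), 1, 2)
  upd <- update_activations(r, theta0 = 0, U_eff = 0.1, beta = 12.5)
  denom <- exp(12.5 * 0.2) + exp(0) + exp(12.5 * 0.1)
  expect_equal(upd$sigma[1, 1], exp(2.5) / denom, tolerance = 1e-12)
  expect_equal(upd$sigma[1, 2], 1 / denom, tolerance = 1e-12)
  expect_equal(upd$sigma0[1], exp(1.25) / denom, tolerance = 1e-12)
  expect_equal(upd$sigma0 + rowSums(upd$sigma), 1)
})

test_that("softmax limits: symmetric case and winner-take-all", {
  S <- 7
  r <- matrix(0.1, 1, S) # r equal to theta0 + U for every state
  upd <- update_activations(r, theta0 = 0, U_eff = 0.1, beta = 12.5)
  expect_equal(unname(c(upd$sigma0, upd$sigma[1, ])), rep(1 / (S + 1), S + 1),
               tolerance = 1e-12)
  sharp <- update_activations(matrix(c(0.6, 0.1, 0.1), 1, 3), 0, 0.1, 500)
  expect_gt(sharp$sigma[1, 1], 0.999)
})

test_that("max-subtraction keeps extreme thresholds finite", {
  upd <- update_activations(matrix(c(-50, 20), 1, 2), theta0 = 100,
                            U_eff = 0.5, beta = 12.5)
  expect_true(all(is.finite(c(upd$sigma, upd$sigma0))))
  expect_equal(upd$sigma0[1], 1, tolerance = 1e-10)
})

test_that("simplex is conserved through arbitrary dynamics", {
  net <- tiny_network(N = 20, S = 4, a = 0.4, C_m = 8, p = 3, seed = 51,
                      dynamic_threshold = TRUE)
  state <- init_network_state(net$params)
  ext <- matrix(0, 20, 4)
  on <- which(net$patterns$states[1, ] > 0)
  ext[cbind(on, net$patterns$states[1, on])] <- 1
  for (step in 1:120) {
    state <- step_dynamics(state, net$weights, net$params,
                           external = if (step <= 20) ext)
    expect_lt(max(abs(state$sigma0 + rowSums(state$sigma) - 1)), 1e-10)
  }
})

test_that("quiescent network relaxes its thresholds toward zero", {
  net <- tiny_network(N = 16, S = 3, a = 0.5, C_m = 6, p = 2, seed = 61,
                      dynamic_threshold = TRUE)
  state <- init_network_state(net$params)
  state$theta_A[] <- 0.5
  state$theta_B[] <- 0.2
  state$U_hat[] <- 0.8
  # freeze activations near quiescence by keeping r strongly negative
  state$r[] <- -2
  params <- net$params
  params$beta <- 40
  for (step in 1:400) {
    state <- step_dynamics(state, net$weights, params)
  }
  expect_lt(max(state$theta_A), 0.05)
  expect_lt(state$U_hat[1], 0.2)
})

test_that("dynamic threshold fixed point tracks the mean active fraction", {
  # with exactly the scaled activity held fixed, U_hat converges to
  # activity / (threshold_scale * N)
  params <- network_params(N = 10, S = 2, a = 0.5, C_m = 4, w = 0,
                           tau2_fast = 1e6, tau2_slow = 1e6,
                           dynamic_threshold = TRUE, threshold_scale = 1,
                           dt = 0.5)
  ps <- pattern_set(matrix(0L, 0, 10), a = 0.5, S = 2)
  conn <- build_connectivity(10, 10, 4, seed = 7)
  w0 <- store_autoassociative(ps, conn)
  state <- init_network_state(params)
  # drive 5 units fully active via a large external field
  ext <- matrix(0, 10, 2)
  ext[1:5, 1] <- 5
  for (step in 1:600) {
    state <- step_dynamics(state, w0, params, external = ext)
  }
  expect_equal(state$U_hat[1], sum(1 - state$sigma0) / 10, tolerance = 1e-3)
})

test_that("working-memory kick marks exactly the union of WM states", {
  ps <- generate_random_patterns(60, 5, 0.2, 8, seed = 71)
  kick <- apply_wm_kick(ps, wm_ids = c(1, 2, 3), delta_theta = 0.1)
  manual <- matrix(0, 60, 5)
  for (mu in 1:3) {
    on <- which(ps$states[mu, ] > 0)
    manual[cbind(on, ps$states[mu, on])] <- 0.1
  }
  expect_equal(kick, manual)
  # single pattern: kicked set size = aN
  k1 <- apply_wm_kick(ps, 1, 0.2)
  expect_equal(sum(k1 > 0), 12)
})

test_that("kick coverage grows like 1 - (1 - a/S)^M for random patterns", {
  ps <- generate_random_patterns(400, 5, 0.25, 30, seed = 81)
  frac <- vapply(c(1, 5, 15), function(M) {
    mean(apply_wm_kick(ps, seq_len(M), 1) > 0)
  }, numeric(1))
  expected <- 1 - (1 - 0.25 / 5)^c(1, 5, 15)
  expect_equal(frac, expected, tolerance = 0.15)
  expect_error(apply_wm_kick(ps, integer(0), 0.1), "at least one")
})
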