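# Shared fixtures: everything is generated in code at fixed seeds.

tiny_network <- function(N = 24, S = 3, a = 0.5, C_m = 8, p = 2, seed = 11,
                         dt = 0.5, ...) {
  params <- network_params(N = N, S = S, a = a, C_m = C_m, w = 0.4,
                           tau2_fast = 10, tau2_slow = 30, gamma2_fast = 0.5,
                           gamma_A = 0.3, dt = dt, ...)
  patterns <- generate_random_patterns(N, S, a, p, seed)
  conn <- build_connectivity(N, N, C_m, seed = seed + 1)
  list(params = params, patterns = patterns, conn = conn,
       weights = store_autoassociative(patterns, conn, S, a))
}

# direct evaluation of the covariance storage rule, used as the oracle
# against the packed weight builder
oracle_weight <- function(patterns, C_m, i, k, j, l) {
  a <- patterns$a; S <- patterns$S
  abar <- a / S
  s <- 0
  for (mu in seq_len(nrow(patterns$states))) {
    s <- s + ((patterns$states[mu, i] == k) - abar) *
      ((patterns$states[mu, j] == l) - abar)
  }
  s / (C_m * a * (1 - abar))
}

# brute-force field evaluation from first principles (adjacency + rule),
# independent of both the packed storage and the compiled engine
oracle_field <- function(patterns, conn, sigma, w = 0) {
  N <- ncol(patterns$states); S <- patterns$S
  h <- matrix(0, N, S)
  for (i in seq_len(N)) {
    for (c_ in seq_len(conn$C_m)) {
      j <- conn$idx[i, c_]
      for (k in seq_len(S)) {
        for (l in seq_len(S)) {
          h[i, k] <- h[i, k] +
            oracle_weight(patterns, conn$C_m, i, k, j, l) * sigma[j, l]
        }
      }
    }
  }
  h + w * (sigma - rowMeans(sigma))
}

make_bump_trajectory <- function(events, t_max = 300, by = 2, n_patterns = 6) {
  # events: list of c(pattern, center, width, height)
  tt <- seq(0, t_max, by = by)
  tb <- expand.grid(t = tt, pattern = seq_len(n_patterns))
  tb$overlap <- 0
  for (e in events) {
    sel <- tb$pattern == e[1]
    tb$overlap[sel] <- pmax(tb$overlap[sel],
                            e[4] * exp(-((tb$t[sel] - e[2]) / e[3])^2))
  }
  tibble::as_tibble(tb)
}
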