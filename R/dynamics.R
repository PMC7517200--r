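#' Initialize a network state at the global null configuration
#'
#' All units start almost fully quiescent (`sigma_i^0 = 1 - eps`, active
#' components `eps/S`), with the input variables `r` set to the value that
#' reproduces exactly these activations under the softmax at zero thresholds.
#' Thresholds and the dynamic threshold component start at zero.
#'
#' @param params a [network_params()]
#' @param eps initial total active mass per unit
#' @param n_scopes number of dynamic-threshold scopes (1 for a global
#'   threshold, one per cluster for the sign buffer)
#' @return a `network_state` list
#' @export
init_network_state <- function(params, eps = 1e-3, n_scopes = 1) {
  N <- params$N; S <- params$S
  r0 <- params$U + log(eps / S / (1 - eps)) / params$beta
  structure(
    list(
      sigma = matrix(eps / S, N, S),
      sigma0 = rep(1 - eps, N),
      r = matrix(r0, N, S),
      theta_fast = matrix(0, N, S),
      theta_slow = matrix(0, N, S),
      theta_A = rep(0, N),
      theta_B = rep(0, N),
      U_hat = rep(0, n_scopes)
    ),
    class = "network_state"
  )
}

#' Softmax activation update of Potts units
#'
#' Maps input variables and thresholds to the activation simplex:
#' \deqn{\sigma_i^k = \frac{e^{\beta r_i^k}}{\sum_l e^{\beta r_i^l} +
#'   e^{\beta(\theta_i^0 + U_{eff})}}}
#' with the quiescent component taking the remaining mass. Computed with
#' max-subtraction so that large `beta * threshold` products cannot overflow.
#'
#' @param r `[N x S]` input variables
#' @param theta0 per-unit inhibition threshold (`theta_A + theta_B`)
#' @param U_eff effective constant threshold (scalar or per-unit)
#' @param beta inverse temperature
#' @return list with `sigma` (`[N x S]`) and `sigma0` (length `N`); rows of
#'   `cbind(sigma0, sigma)` sum to one
#' @export
update_activations <- function(r, theta0, U_eff, beta) {
  q <- beta * (theta0 + U_eff)
  m <- pmax(apply(beta * r, 1, max), q)
  e <- exp(beta * r - m)
  e0 <- exp(q - m)
  denom <- rowSums(e) + e0
  list(sigma = e / denom, sigma0 = e0 / denom)
}

#' Recurrent field of a Potts network (reference implementation)
#'
#' Computes, for every unit and active state, the input
#' `h_ik = sum_{j,l} J_ij^kl sigma_j^l (+ hetero term) + w (sigma_ik - mean_l
#' sigma_il)`. This is the plain-R reference used in tests and small
#' examples; batch simulations use the compiled engine.
#'
#' @param state a `network_state` (its `sigma` is used)
#' @param weights autoassociative [store_autoassociative()] weights
#' @param params the network's [network_params()]
#' @param hetero optional [store_heteroassociative()] weights
#' @param source_state state of the sending network (required with `hetero`);
#'   by default its activations drive the field (sigma-sigma coupling), set
#'   `hetero_theta = TRUE` for the theta-sigma variant
#' @param hetero_theta couple to the source's adaptive thresholds instead of
#'   its activations
#' @return `[N x S]` field matrix
#' @export
compute_field <- function(state, weights, params, hetero = NULL,
                          source_state = NULL, hetero_theta = FALSE) {
  N <- params$N; S <- params$S
  h <- field_contribution(weights, state$sigma, N, S)
  if (!is.null(hetero)) {
    assert_that(!is.null(source_state), "hetero weights need a source state")
    src <- if (hetero_theta) {
      source_state$theta_fast + source_state$theta_slow
    } else {
      source_state$sigma
    }
    h <- h + field_contribution(hetero, src, N, S)
  }
  h + params$w * (state$sigma - rowMeans(state$sigma))
}

field_contribution <- function(weights, sigma_pre, N, S) {
  idx <- weights$conn$idx
  C_m <- weights$conn$C_m
  h <- matrix(0, N, S)
  for (i in seq_len(N)) {
    for (c_ in seq_len(C_m)) {
      j <- idx[i, c_]
      base <- ((i - 1) * C_m + (c_ - 1)) * S * S
      # packed l-major block: entry (k, l) at base + (l-1)*S + k
      blk <- matrix(weights$values[base + seq_len(S * S)], S, S)
      h[i, ] <- h[i, ] + blk %*% sigma_pre[j, ]
    }
  }
  h
}

#' One explicit-Euler step of the network dynamics
#'
#' Advances the input variables, the two adaptation components, the two
#' inhibition components and (if enabled) the dynamic threshold, then
#' refreshes the activations through [update_activations()]. This mirrors the
#' compiled engine step exactly.
#'
#' @param state a `network_state`
#' @param weights autoassociative weights
#' @param params [network_params()]
#' @param hetero,source_state optional lexicon coupling (see
#'   [compute_field()])
#' @param external additive external field (`[N x S]`), e.g. a cue
#' @param kick optional `[N x S]` working-memory threshold kick (see
#'   [apply_wm_kick()])
#' @param scope dynamic-threshold scope id per unit (default: all in scope 1)
#' @param scope_norm normalization per scope (default
#'   `threshold_scale * N_scope`)
#' @return the advanced `network_state`
#' @export
step_dynamics <- function(state, weights, params, hetero = NULL,
                          source_state = NULL, external = NULL, kick = NULL,
                          scope = NULL, scope_norm = NULL) {
  N <- params$N; S <- params$S; dt <- params$dt
  h <- compute_field(state, weights, params, hetero, source_state)
  if (!is.null(external)) h <- h + external
  if (!all(is.finite(h))) {
    stop("non-finite field encountered; the dynamics diverged", call. = FALSE)
  }

  theta <- state$theta_fast + state$theta_slow
  state$r <- state$r + (dt / params$tau1) * (h - theta - state$r)

  g2f <- expand_to_map(params$gamma2_fast, N, S)
  t2f <- expand_to_map(params$tau2_fast, N, S)
  t2s <- expand_to_map(params$tau2_slow, N, S)
  kick_term <- if (is.null(kick)) 0 else kick
  state$theta_fast <- state$theta_fast +
    (dt / t2f) * (g2f * state$sigma - kick_term - state$theta_fast)
  state$theta_slow <- state$theta_slow +
    (dt / t2s) * ((1 - g2f) * state$sigma - state$theta_slow)

  stot <- rowSums(state$sigma)
  state$theta_A <- state$theta_A +
    (dt / params$tau_A) * (params$gamma_A * stot - state$theta_A)
  state$theta_B <- state$theta_B +
    (dt / params$tau_B) * ((1 - params$gamma_A) * stot - state$theta_B)

  U_eff <- params$U
  if (params$dynamic_threshold) {
    scope <- scope %||% rep(1L, N)
    scope_norm <- scope_norm %||%
      (params$threshold_scale * tabulate(scope, max(scope)))
    act <- tapply(1 - state$sigma0, scope, sum)
    for (s_ in seq_along(state$U_hat)) {
      state$U_hat[s_] <- state$U_hat[s_] +
        (dt / params$tau_U) * (act[[s_]] / scope_norm[s_] - state$U_hat[s_])
    }
    U_eff <- params$U + state$U_hat[scope]
  }

  upd <- update_activations(state$r, state$theta_A + state$theta_B, U_eff,
                            params$beta)
  state$sigma <- upd$sigma
  state$sigma0 <- upd$sigma0
  state
}

expand_to_map <- function(x, N, S) {
  if (length(x) == 1) matrix(x, N, S) else x
}

#' Working-memory threshold kick
#'
#' Builds the `[N x S]` kick matrix that lowers the adaptive threshold of
#' every (unit, state) pair active in at least one of the selected patterns,
#' by the same amount regardless of multiplicity. Passed to
#' [step_dynamics()] (or the batch engine) it adds `-delta_theta * H(...)` to
#' the threshold drive.
#'
#' @param patterns a [pattern_set()]
#' @param wm_ids indices of the patterns held in working memory
#' @param delta_theta kick magnitude
#' @return `[N x S]` matrix, `delta_theta` where kicked, 0 elsewhere
#' @export
apply_wm_kick <- function(patterns, wm_ids, delta_theta) {
  assert_that(length(wm_ids) >= 1, "need at least one working-memory pattern")
  N <- ncol(patterns$states); S <- patterns$S
  kick <- matrix(0, N, S)
  for (mu in wm_ids) {
    on <- which(patterns$states[mu, ] > 0L)
    kick[cbind(on, patterns$states[mu, on])] <- delta_theta
  }
  kick
}
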