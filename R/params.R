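#' Parameters of one Potts network
#'
#' Collects the structural and dynamical constants of a single network. Time
#' constants are expressed in the package's time unit (the unit in which
#' `tau1 = 3.33`); the integration step `dt` is in the same unit.
#'
#' The adaptation fields `tau2_fast`, `tau2_slow` and `gamma2_fast` may be
#' scalars or `[N x S]` matrices (per-unit-per-state maps, used by the sign
#' buffer).
#'
#' @param N,S,a,C_m network size, active states, sparsity, inputs per unit
#' @param beta inverse temperature of the softmax update
#' @param U constant activation threshold
#' @param w local feedback strength
#' @param tau1 input integration timescale
#' @param tau2_fast,tau2_slow fast/slow adaptation timescales
#' @param gamma2_fast fraction of adaptation carried by the fast component
#' @param tau_A,tau_B fast/slow inhibition timescales
#' @param gamma_A fraction of inhibition carried by the fast component
#' @param dynamic_threshold enable the activity-dependent threshold component
#' @param threshold_scale scope-size multiplier in the dynamic-threshold
#'   drive: the drive is `sum(1 - sigma_i0) / (threshold_scale * N_scope)`
#' @param tau_U timescale of the dynamic threshold
#' @param dt Euler integration step
#' @return a `network_params` object
#' @export
network_params <- function(N, S = 7, a = 0.25, C_m,
                           beta = 12.5, U = 0.1, w,
                           tau1 = 3.33,
                           tau2_fast = 11.1, tau2_slow = 33.3,
                           gamma2_fast = 1,
                           tau_A = 2, tau_B = 1e6, gamma_A = 0,
                           dynamic_threshold = FALSE,
                           threshold_scale = 0.55, tau_U = 2,
                           dt = 0.25) {
  assert_that(beta > 0, "beta must be positive")
  for (nm in c("tau1", "tau_A", "tau_B", "tau_U", "dt")) {
    assert_that(all(get(nm) > 0), sprintf("%s must be positive", nm))
  }
  assert_that(all(tau2_fast > 0) && all(tau2_slow > 0),
              "adaptation timescales must be positive")
  assert_that(all(gamma_A >= 0 & gamma_A <= 1), "gamma_A must lie in [0, 1]")
  assert_that(all(gamma2_fast >= 0 & gamma2_fast <= 1),
              "gamma2_fast must lie in [0, 1]")
  structure(
    list(N = as.integer(N), S = as.integer(S), a = a, C_m = as.integer(C_m),
         beta = beta, U = U, w = w, tau1 = tau1,
         tau2_fast = tau2_fast, tau2_slow = tau2_slow,
         gamma2_fast = gamma2_fast,
         tau_A = tau_A, tau_B = tau_B, gamma_A = gamma_A,
         dynamic_threshold = isTRUE(dynamic_threshold),
         threshold_scale = threshold_scale, tau_U = tau_U, dt = dt),
    class = "network_params"
  )
}

#' @export
print.network_params <- function(x, ...) {
  cat(sprintf(
    "<network_params> N=%d S=%d a=%.4g C_m=%d beta=%g U=%g w=%g dt=%g\n",
    x$N, x$S, x$a, x$C_m, x$beta, x$U, x$w, x$dt))
  cat(sprintf("  tau1=%g tau2=(%s, %s) gamma2_fast=%s tau_A=%g tau_B=%g gamma_A=%g\n",
              x$tau1, fmt_map(x$tau2_fast), fmt_map(x$tau2_slow),
              fmt_map(x$gamma2_fast), x$tau_A, x$tau_B, x$gamma_A))
  if (x$dynamic_threshold) {
    cat(sprintf("  dynamic threshold: scale=%g tau_U=%g\n",
                x$threshold_scale, x$tau_U))
  }
  invisible(x)
}

fmt_map <- function(x) {
  if (length(x) == 1) format(x) else sprintf("[%dx%d map]", nrow(x), ncol(x))
}
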