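#' Store patterns as autoassociative tensor weights
#'
#' Implements the covariance ("simil-Hebbian") storage rule for Potts units:
#' for connected units `i <- j` and active states `k, l`,
#' \deqn{J_{ij}^{kl} = \frac{c_{ij}}{C_m a (1 - a/S)} \sum_\mu
#'   (\delta_{\xi_i^\mu k} - a/S)(\delta_{\xi_j^\mu l} - a/S)}
#' Entries involving the quiescent state are identically zero.
#'
#' @param patterns a [pattern_set()]
#' @param conn a [build_connectivity()] adjacency (within-network)
#' @param S,a state count and sparsity used in the normalization (defaults
#'   from `patterns`)
#' @return a `potts_weights` object holding the weight values in the packed
#'   layout consumed by the simulator
#' @export
store_autoassociative <- function(patterns, conn, S = patterns$S, a = patterns$a) {
  stopifnot(inherits(patterns, "pattern_set"), inherits(conn, "connectivity"))
  assert_that(ncol(patterns$states) == conn$N_pre,
              "patterns and connectivity disagree on N")
  values <- build_auto_weights_cpp(conn$idx, patterns$states, a, S, conn$C_m)
  structure(list(values = values, conn = conn, S = as.integer(S), a = a,
                 kind = "auto"),
            class = "potts_weights")
}

#' Store lexicon-to-buffer heteroassociative weights
#'
#' Couples every lexicon item's stored pattern to its component patterns in
#' the buffer with strength `G * lambda(kind) * gain`:
#' \deqn{J_{ij}^{kl,het} = \frac{c_{ij} \lambda}{C_m^{het} a (1 - a/S)}
#'   \sum_{\mu\nu} G_{\mu\nu} (\delta_{\xi_i^\nu k} - a/S)
#'   (\delta_{\xi_j^\mu l} - a/S)}
#' with `i` a buffer unit and `j` a lexicon unit.
#'
#' `gain` is a single network-level calibration constant applied on top of
#' the per-kind `lambda`; see the methods vignette for why it exists and how
#' its default was fixed.
#'
#' @param lexicon_patterns lexicon-network [pattern_set()]
#' @param buffer_patterns buffer-network [pattern_set()]
#' @param lexicon a [build_word_lexicon()] / [compose_mixed_lexicon()] object
#' @param conn_het inter-network [build_connectivity()] (pre = lexicon units)
#' @param gain coupling gain multiplying every lambda
#' @param S,a normalization constants (buffer's by default)
#' @return a `potts_weights` object (kind `"hetero"`)
#' @export
store_heteroassociative <- function(lexicon_patterns, buffer_patterns, lexicon,
                                    conn_het, gain = 1,
                                    S = buffer_patterns$S,
                                    a = buffer_patterns$a) {
  stopifnot(inherits(lexicon, "lexicon"))
  assert_that(all(lexicon$G >= 0 & lexicon$G <= 1),
              "G entries must lie in [0, 1]")
  it <- lexicon$items
  mu <- rep(it$lexicon_pattern, each = 3)
  nu <- as.integer(t(as.matrix(it[, c("c1", "c2", "c3")])))
  g <- lexicon$G[cbind(mu, nu)] * lexicon$lambda[rep(it$item_kind, each = 3)] * gain
  values <- build_hetero_weights_cpp(
    conn_het$idx, buffer_patterns$states, lexicon_patterns$states,
    mu, nu, g, a, S, conn_het$C_m
  )
  structure(list(values = values, conn = conn_het, S = as.integer(S), a = a,
                 kind = "hetero"),
            class = "potts_weights")
}

#' @export
print.potts_weights <- function(x, ...) {
  cat(sprintf("<potts_weights:%s> %d post-units x %d inputs x %d^2 states\n",
              x$kind, x$conn$N_post, x$conn$C_m, x$S))
  invisible(x)
}

#' Extract one S x S weight block
#'
#' @param w a `potts_weights` object
#' @param i post-synaptic unit
#' @param j pre-synaptic unit (must be among `i`'s inputs)
#' @return `S x S` matrix with rows = post state `k`, cols = pre state `l`
#' @export
weight_block <- function(w, i, j) {
  c_ <- match(j, w$conn$idx[i, ])
  if (is.na(c_)) return(matrix(0, w$S, w$S))
  S <- w$S
  base <- ((i - 1) * w$conn$C_m + (c_ - 1)) * S * S
  # packed layout is l-major: values[base + (l-1)*S + k]
  matrix(w$values[base + seq_len(S * S)], nrow = S, ncol = S, byrow = FALSE)
}
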