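#' Construct a set of Potts activity patterns
#'
#' A pattern set holds `p` memories over `N` Potts units. Entry `(mu, i)` is
#' the state (1..S) unit `i` takes in memory `mu`, or 0 if the unit is
#' quiescent in that memory.
#'
#' @param states integer matrix `[p x N]` with entries in `0..S`
#' @param a nominal sparsity (fraction of units active per pattern, within the
#'   pattern's scope)
#' @param S number of active Potts states
#' @param cluster_bounds optional list of integer ranges, one per cluster, for
#'   patterns confined to unit clusters (gesture elements)
#' @param cluster_of optional integer vector, the cluster index of each
#'   pattern (0 = whole-network pattern)
#' @return an object of class `pattern_set`
#' @export
pattern_set <- function(states, a, S, cluster_bounds = NULL, cluster_of = NULL) {
  storage.mode(states) <- "integer"
  assert_that(all(states >= 0L & states <= S), "pattern states must lie in 0..S")
  assert_that(a > 0 && a <= 1, "sparsity a must lie in (0, 1]")
  structure(
    list(
      states = states, a = a, S = as.integer(S),
      cluster_bounds = cluster_bounds,
      cluster_of = cluster_of %||% rep(0L, nrow(states))
    ),
    class = "pattern_set"
  )
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf(
    "<pattern_set> %d patterns x %d units, S = %d, a = %.4g (%d active/pattern)\n",
    nrow(x$states), ncol(x$states), x$S, x$a, round(x$a * scope_size(x))
  ))
  if (!is.null(x$cluster_bounds)) {
    cat(sprintf("  clustered: %d clusters of %s units\n",
                length(x$cluster_bounds),
                paste(unique(lengths(x$cluster_bounds)), collapse = "/")))
  }
  invisible(x)
}

scope_size <- function(ps) {
  if (is.null(ps$cluster_bounds)) ncol(ps$states) else length(ps$cluster_bounds[[1]])
}

#' Generate uncorrelated random Potts patterns
#'
#' Each pattern activates exactly `round(a * N)` units (exact-count sparsity),
#' drawn uniformly without replacement, and assigns each an active state
#' uniform on `1..S`.
#'
#' @param N number of Potts units
#' @param S number of active states per unit
#' @param a sparsity
#' @param p number of patterns
#' @param seed RNG seed
#' @return a [pattern_set()]
#' @export
#' @examples
#' ps <- generate_random_patterns(N = 200, S = 7, a = 0.25, p = 10, seed = 1)
#' rowSums(ps$states > 0) # 50 active units in every pattern
generate_random_patterns <- function(N, S, a, p, seed) {
  assert_that(a > 0 && a <= 1, "sparsity a must lie in (0, 1]")
  n_active <- round(a * N)
  assert_that(n_active >= 1, "a * N must round to at least one active unit")
  states <- with_seed(seed, {
    m <- matrix(0L, p, N)
    for (mu in seq_len(p)) {
      on <- sample.int(N, n_active)
      m[mu, on] <- sample.int(S, n_active, replace = TRUE)
    }
    m
  })
  pattern_set(states, a = a, S = S)
}

#' Generate clustered gesture-element patterns
#'
#' The network is split into `n_clusters` equal, non-overlapping clusters of
#' units; the elements are divided equally among clusters and each element
#' activates exactly `round(a_sign * N/n_clusters)` units inside its own
#' cluster and none outside.
#'
#' @param N number of units (must divide evenly into `n_clusters`)
#' @param n_clusters number of clusters (one per gesture-element type)
#' @param a_sign within-cluster sparsity
#' @param n_elements total number of elements (must divide by `n_clusters`)
#' @param seed RNG seed
#' @param S number of active states
#' @return a [pattern_set()] with `cluster_bounds` and `cluster_of` set
#' @export
generate_cluster_patterns <- function(N, n_clusters, a_sign, n_elements, seed, S = 7) {
  assert_that(N %% n_clusters == 0, "N must divide evenly into n_clusters")
  if (n_elements > 0) {
    assert_that(n_elements %% n_clusters == 0,
                "n_elements must divide evenly among clusters")
  }
  n_c <- N %/% n_clusters
  n_active <- round(a_sign * n_c)
  bounds <- lapply(seq_len(n_clusters), function(cl) ((cl - 1) * n_c + 1):(cl * n_c))
  per <- if (n_elements > 0) n_elements %/% n_clusters else 0
  cluster_of <- rep(seq_len(n_clusters), each = per)
  states <- with_seed(seed, {
    m <- matrix(0L, n_elements, N)
    for (e in seq_len(n_elements)) {
      units <- bounds[[cluster_of[e]]]
      on <- safe_sample(units, n_active)
      m[e, on] <- sample.int(S, n_active, replace = TRUE)
    }
    m
  })
  pattern_set(states, a = a_sign, S = S, cluster_bounds = bounds,
              cluster_of = as.integer(cluster_of))
}

#' Fraction of units active in both of two patterns
#'
#' For two uncorrelated patterns of sparsity `a` the expectation is `a^2`.
#'
#' @param x a [pattern_set()]
#' @param i,j pattern indices
#' @return a proportion of the network's `N` units
#' @export
shared_active_fraction <- function(x, i, j) {
  stopifnot(inherits(x, "pattern_set"))
  mean(x$states[i, ] > 0L & x$states[j, ] > 0L)
}

#' Serialize a pattern set to JSON
#'
#' Round-trips bit-exactly through [read_pattern_set()].
#' @param x a [pattern_set()]
#' @param path file path
#' @export
write_pattern_set <- function(x, path) {
  obj <- list(
    states = unclass(x$states), a = x$a, S = x$S,
    cluster_bounds = x$cluster_bounds, cluster_of = x$cluster_of
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pattern_set
#' @export
read_pattern_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cb <- if (!is.null(obj$cluster_bounds)) {
    lapply(seq_len(nrow(obj$cluster_bounds) %||% length(obj$cluster_bounds)),
           function(i) as.integer(if (is.matrix(obj$cluster_bounds)) obj$cluster_bounds[i, ] else obj$cluster_bounds[[i]]))
  }
  pattern_set(as.matrix(obj$states), a = obj$a, S = obj$S,
              cluster_bounds = cb, cluster_of = as.integer(obj$cluster_of))
}
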