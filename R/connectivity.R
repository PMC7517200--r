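#' Sample a diluted connectivity matrix
#'
#' Each post-synaptic unit receives input from exactly `C_m` distinct
#' pre-synaptic units, drawn uniformly. Self-connections are excluded for
#' within-network adjacency.
#'
#' @param N_post,N_pre unit counts of the receiving and sending populations
#' @param C_m inputs per post-synaptic unit
#' @param self_allowed allow `i -> i` connections (inter-network adjacency)
#' @param seed RNG seed
#' @return an object of class `connectivity` with the `[N_post x C_m]` index
#'   matrix in `$idx` (sorted pre-unit indices per row)
#' @export
build_connectivity <- function(N_post, N_pre, C_m, self_allowed = FALSE, seed) {
  max_in <- N_pre - if (self_allowed) 0L else 1L
  assert_that(C_m <= max_in, "C_m exceeds the number of available pre-units")
  idx <- with_seed(seed, {
    m <- matrix(0L, N_post, C_m)
    for (i in seq_len(N_post)) {
      pool <- if (self_allowed) seq_len(N_pre) else setdiff(seq_len(N_pre), i)
      m[i, ] <- sort(safe_sample(pool, C_m))
    }
    m
  })
  structure(list(idx = idx, N_post = N_post, N_pre = N_pre, C_m = C_m,
                 self_allowed = self_allowed),
            class = "connectivity")
}

#' @export
print.connectivity <- function(x, ...) {
  cat(sprintf("<connectivity> %d post x %d pre, C_m = %d%s\n",
              x$N_post, x$N_pre, x$C_m,
              if (x$self_allowed) " (self allowed)" else ""))
  invisible(x)
}

#' Dense binary adjacency of a connectivity object
#' @param x a [build_connectivity()] result
#' @return an `[N_post x N_pre]` 0/1 matrix with row sums `C_m`
#' @export
as_adjacency_matrix <- function(x) {
  stopifnot(inherits(x, "connectivity"))
  m <- matrix(0L, x$N_post, x$N_pre)
  for (i in seq_len(x$N_post)) m[i, x$idx[i, ]] <- 1L
  m
}
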