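test_that("random patterns have exact-count sparsity and uniform states", {
  ps <- generate_random_patterns(N = 200, S = 7, a = 0.25, p = 200, seed = 1)
  expect_equal(unname(rowSums(ps$states > 0)), rep(50, 200))
  expect_true(all(ps$states >= 0 & ps$states <= 7))
  # states roughly uniform over 1..7 across all patterns
  tab <- table(ps$states[ps$states > 0])
  expect_equal(length(tab), 7L)
  expect_true(max(abs(tab / sum(tab) - 1 / 7)) < 0.02)
})

test_that("degenerate full-activity pattern set works", {
  ps <- generate_random_patterns(N = 10, S = 1, a = 1, p = 3, seed = 2)
  expect_true(all(ps$states == 1L))
})

test_that("pattern generation is reproducible and validates inputs", {
  a <- generate_random_patterns(50, 5, 0.2, 4, seed = 7)
  b <- generate_random_patterns(50, 5, 0.2, 4, seed = 7)
  expect_identical(a$states, b$states)
  expect_error(generate_random_patterns(50, 5, 0, 4, seed = 1), "sparsity")
  expect_error(generate_random_patterns(10, 5, 0.01, 4, seed = 1), "at least one")
})

test_that("mean shared-active fraction of independent patterns is about a^2", {
  # expectation for exact-count sparsity: (aN choose shared) hypergeometric
  # mean = a^2 * N; estimate over many pairs
  ps <- generate_random_patterns(N = 200, S = 7, a = 0.25, p = 300, seed = 3)
  pairs <- cbind(seq(1, 299, 2), seq(2, 300, 2))
  shared <- vapply(seq_len(nrow(pairs)), function(r) {
    shared_active_fraction(ps, pairs[r, 1], pairs[r, 2])
  }, numeric(1))
  expect_lt(mean(shared), 0.1)
  expect_equal(mean(shared), 0.0625, tolerance = 0.05)
})

test_that("cluster patterns are confined to their cluster", {
  ps <- generate_cluster_patterns(N = 201, n_clusters = 3, a_sign = 31 / 67,
                                  n_elements = 15, seed = 4)
  expect_equal(unname(rowSums(ps$states > 0)), rep(31, 15))
  expect_equal(as.vector(table(ps$cluster_of)), rep(5L, 3))
  for (e in 1:15) {
    on <- which(ps$states[e, ] > 0)
    expect_true(all(on %in% ps$cluster_bounds[[ps$cluster_of[e]]]))
  }
  # elements in different clusters never share active units
  expect_equal(shared_active_fraction(ps, 1, 15), 0)
  expect_error(generate_cluster_patterns(200, 3, 0.4, 15, seed = 1), "divide")
})

test_that("empty cluster pattern set is allowed", {
  ps <- generate_cluster_patterns(N = 201, n_clusters = 3, a_sign = 31 / 67,
                                  n_elements = 0, seed = 5)
  expect_equal(nrow(ps$states), 0L)
})

test_that("pattern sets round-trip through JSON exactly", {
  ps <- generate_cluster_patterns(N = 21, n_clusters = 3, a_sign = 0.4,
                                  n_elements = 6, seed = 6, S = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_pattern_set(ps, path)
  ps2 <- read_pattern_set(path)
  expect_identical(ps2$states, ps$states)
  expect_identical(ps2$cluster_of, ps$cluster_of)
  expect_equal(ps2$a, ps$a)
})
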