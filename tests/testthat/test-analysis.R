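test_that("overlap is 1 at the pattern, ~0 at null and on other patterns", {
  ps <- generate_random_patterns(120, 7, 0.25, 40, seed = 1)
  N <- 120; S <- 7
  xi <- ps$states[1, ]
  sigma <- matrix(0, N, S)
  on <- which(xi > 0)
  sigma[cbind(on, xi[on])] <- 1
  expect_equal(compute_overlap(sigma, xi, 0.25, S), 1, tolerance = 1e-12)
  expect_equal(compute_overlap(matrix(0, N, S), xi, 0.25, S), 0)
  # cross-overlaps with unrelated patterns are O(1/sqrt(N))
  cross <- vapply(2:40, function(m) {
    compute_overlap(sigma, ps$states[m, ], 0.25, S)
  }, numeric(1))
  expect_lt(max(abs(cross)), 0.35)
  expect_lt(abs(mean(cross)), 0.05)
  expect_true(all(cross <= 1))
})

test_that("normalized activity is state-blind and interpolates to 0.5", {
  ps <- generate_random_patterns(80, 5, 0.25, 2, seed = 2)
  xi <- ps$states[1, ]
  on <- which(xi > 0)
  sigma0 <- rep(1, 80)
  # active in *different* states than stored: still counts
  sigma0[on] <- 0
  expect_equal(normalized_activity(NULL, xi, sigma0), 1)
  expect_equal(normalized_activity(NULL, xi, rep(1, 80)), 0)
  sigma0 <- rep(1, 80)
  sigma0[on[seq_len(length(on) / 2)]] <- 0
  expect_equal(normalized_activity(NULL, xi, sigma0), 0.5)
})

test_that("utterance extraction reads constructed bump sequences", {
  traj <- make_bump_trajectory(list(
    c(1, 50, 12, 0.95), c(2, 100, 12, 0.9), c(3, 150, 12, 0.92)
  ))
  utt <- extract_utterances(traj)
  expect_equal(utt$pattern, c(1L, 2L, 3L))
  expect_true(all(diff(utt$onset) > 0))
  # repeated pattern stays two separate utterances (A, B, A)
  traj2 <- make_bump_trajectory(list(
    c(1, 50, 12, 0.95), c(2, 100, 12, 0.9), c(1, 150, 12, 0.92)
  ))
  expect_equal(extract_utterances(traj2)$pattern, c(1L, 2L, 1L))
  # a single monotone retrieval is one utterance
  traj3 <- make_bump_trajectory(list(c(4, 100, 40, 0.9)))
  expect_equal(extract_utterances(traj3)$pattern, 4L)
  # sub-threshold and too-short bumps are discarded
  traj4 <- make_bump_trajectory(list(c(1, 50, 12, 0.4), c(2, 100, 1.5, 0.9)))
  expect_equal(nrow(extract_utterances(traj4)), 0L)
})

test_that("extraction labels are stable across theta_on in [0.45, 0.6]", {
  traj <- make_bump_trajectory(list(
    c(1, 50, 12, 0.95), c(3, 100, 12, 0.85), c(2, 150, 12, 0.9),
    c(1, 200, 12, 0.88)
  ))
  labs <- vapply(c(0.45, 0.5, 0.55, 0.6), function(on) {
    u <- extract_utterances(traj, theta_on = on, theta_off = on - 0.15)
    classify_error(u, c(1L, 2L, 3L))$category
  }, character(1))
  expect_equal(unique(labs), "wrong_order")
})

test_that("the error taxonomy matches its definitions", {
  tgt <- c(10L, 20L, 30L)
  cls <- function(x) classify_error(x, tgt)
  expect_equal(cls(c(10, 20, 30))$category, "correct")
  expect_true(is.na(cls(c(10, 20, 30))$first_error_position))
  r <- cls(c(10, 30, 20))
  expect_equal(r$category, "wrong_order")
  expect_equal(r$first_error_position, 2L)
  expect_equal(cls(c(10, 20, 10))$category, "repetition")
  r <- cls(c(10, 20))
  expect_equal(r$category, "shorter_sequence")
  expect_equal(r$first_error_position, 3L)
  expect_equal(cls(integer(0))$category, "shorter_sequence")
  expect_equal(cls(integer(0))$first_error_position, 1L)
  expect_equal(cls(c(10, 20, 99))$category, "wrong_syllable")
  # insertions outrank repetitions, which outrank omissions
  expect_equal(cls(c(10, 10, 99))$category, "wrong_syllable")
  expect_equal(cls(c(10, 10))$category, "repetition")
  # trailing utterances beyond the third do not change the label
  expect_equal(cls(c(10, 20, 30, 10, 20))$category, "correct")
})

test_that("the classifier is total and single-valued on random sequences", {
  set.seed(99)
  tgt <- c(1L, 2L, 3L)
  for (rep_ in 1:300) {
    n <- sample(0:6, 1)
    seq_ <- sample(1:5, n, replace = TRUE)
    r <- classify_error(seq_, tgt)
    expect_true(r$category %in% c("correct", "wrong_order", "repetition",
                                  "shorter_sequence", "wrong_syllable"))
    expect_length(r$category, 1)
    r2 <- classify_error(seq_, tgt)
    expect_identical(r, r2)
  }
})

test_that("error aggregation partitions to 100 percent", {
  trials <- tibble::tibble(
    label = c("correct", "correct", "wrong_order", "repetition"),
    batch = c(1, 1, 2, 2)
  )
  agg <- aggregate_errors(trials)
  expect_equal(sum(agg$percent), 100)
  one <- aggregate_errors(tibble::tibble(label = "correct"))
  expect_equal(one$percent[one$category == "correct"], 100)
})

test_that("latching regime classification follows its definitions", {
  mk_utt <- function(patterns, horizon_end = FALSE) {
    n <- length(patterns)
    tibble::tibble(pattern = patterns,
                   onset = seq(0, by = 50, length.out = n),
                   offset = seq(40, by = 50, length.out = n) +
                     if (horizon_end) 1000 else 0,
                   peak = rep(0.9, n))
  }
  no_latch <- replicate(12, mk_utt(1L), simplify = FALSE)
  expect_equal(classify_latching_regime(no_latch, horizon = 1000),
               "no_latching")
  finite <- replicate(12, mk_utt(c(1L, 2L, 3L)), simplify = FALSE)
  expect_equal(classify_latching_regime(finite, horizon = 1000), "finite")
  infinite <- replicate(12, {
    u <- mk_utt(c(1L, 2L, 3L, 4L))
    u$offset[4] <- 990
    u
  }, simplify = FALSE)
  expect_equal(classify_latching_regime(infinite, horizon = 1000), "infinite")
  expect_error(classify_latching_regime(no_latch[1:5], horizon = 1000),
               "at least 10")
})
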