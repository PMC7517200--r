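test_that("50-word lexicon satisfies the positional balance constraint", {
  ps <- generate_random_patterns(200, 7, 0.25, 200, seed = 1)
  lex <- build_word_lexicon(50, ps, seed = 2)
  comp <- as.matrix(lex$items[, c("c1", "c2", "c3")])
  # 50 distinct syllables, each used three times, once per serial position
  syl <- sort(unique(as.vector(comp)))
  expect_length(syl, 50)
  for (pos in 1:3) {
    expect_equal(sort(comp[, pos]), syl)
  }
  # no word repeats a syllable
  expect_true(all(apply(comp, 1, function(z) length(unique(z)) == 3)))
  # cascade G values on the components, zero elsewhere
  for (wi in c(1, 17, 50)) {
    row <- lex$G[lex$items$lexicon_pattern[wi], ]
    expect_equal(unname(row[comp[wi, ]]), c(1.0, 0.9, 0.8))
    expect_equal(sum(row), 2.7)
  }
})

test_that("single-word lexicon falls back to an unconstrained triple", {
  ps <- generate_random_patterns(60, 7, 0.25, 60, seed = 3)
  lex <- build_word_lexicon(1, ps, seed = 4, p_lexicon = 60)
  expect_equal(nrow(lex$items), 1L)
  expect_equal(unname(lex$G[lex$items$lexicon_pattern[1],
                            unlist(lex$items[1, c("c1", "c2", "c3")])]),
               c(1.0, 0.9, 0.8))
})

test_that("lexicon generation is deterministic in the seed", {
  ps <- generate_random_patterns(100, 7, 0.25, 100, seed = 5)
  a <- build_word_lexicon(20, ps, seed = 9, p_lexicon = 100)
  b <- build_word_lexicon(20, ps, seed = 9, p_lexicon = 100)
  expect_identical(a$items, b$items)
  expect_identical(a$G, b$G)
})

test_that("mixed lexicon spans clusters for signs and is duplicate-free", {
  g <- generate_cluster_patterns(201, 3, 31 / 67, 15, seed = 1)
  s <- generate_random_patterns(201, 7, 51 / 201, 15, seed = 2)
  lex <- compose_mixed_lexicon(g, s, n_signs = 25, n_words = 25, seed = 3)
  expect_equal(nrow(lex$items), 50L)
  signs <- lex$items[lex$items$item_kind == "sign", ]
  words <- lex$items[lex$items$item_kind == "word", ]
  # sign components: one gesture element from each cluster
  for (i in seq_len(nrow(signs))) {
    comp <- unlist(signs[i, c("c1", "c2", "c3")])
    expect_true(all(comp <= 15))
    expect_equal(sort(g$cluster_of[comp]), 1:3)
  }
  # word components: distinct syllables (no-replacement sampling)
  for (i in seq_len(nrow(words))) {
    comp <- unlist(words[i, c("c1", "c2", "c3")])
    expect_true(all(comp > 15 & comp <= 30))
    expect_length(unique(comp), 3)
  }
  # G: signs flat at 1, words cascade
  expect_equal(unname(lex$G[signs$lexicon_pattern[1],
                            unlist(signs[1, c("c1", "c2", "c3")])]),
               c(1, 1, 1))
  expect_equal(unname(lex$G[words$lexicon_pattern[1],
                            unlist(words[1, c("c1", "c2", "c3")])]),
               c(1.0, 0.9, 0.8))
  expect_equal(unname(lex$lambda), c(0.2, 1.4))
})

test_that("full sign enumeration yields distinct combinations", {
  g <- generate_cluster_patterns(30, 3, 0.5, 9, seed = 4, S = 3)
  s <- generate_random_patterns(30, 3, 0.3, 5, seed = 5)
  lex <- compose_mixed_lexicon(g, s, n_signs = 27, n_words = 10, seed = 6)
  signs <- lex$items[lex$items$item_kind == "sign", c("c1", "c2", "c3")]
  expect_equal(nrow(unique(signs)), 27L)
  expect_error(compose_mixed_lexicon(g, s, n_signs = 28, n_words = 1, seed = 1),
               "combination space")
})

test_that("lexica round-trip through JSON", {
  ps <- generate_random_patterns(80, 7, 0.25, 80, seed = 8)
  lex <- build_word_lexicon(10, ps, seed = 9, p_lexicon = 80)
  path <- withr::local_tempfile(fileext = ".json")
  write_lexicon(lex, path)
  lex2 <- read_lexicon(path)
  expect_equal(lex2$items$c1, lex$items$c1)
  expect_equal(lex2$G, lex$G)
  expect_equal(lex2$lambda, lex$lambda)
})
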