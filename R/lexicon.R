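#' Build a word lexicon with positional balance
#'
#' Assigns each of `n_words` lexicon items an ordered triple of buffer
#' (syllable) patterns such that every syllable participates in exactly three
#' words, once in each serial position. The instruction matrix `G` carries the
#' graded cascade (1.0 / 0.9 / 0.8 by default) that tells the buffer in which
#' order to produce the three syllables.
#'
#' The assignment draws one random permutation of the syllable pool per
#' serial position and rejects draws in which any word would contain the same
#' syllable twice.
#'
#' @param n_words number of words (equals the syllable-pool size)
#' @param patterns buffer [pattern_set()] whose rows are candidate syllables
#' @param seed RNG seed
#' @param p_lexicon number of patterns stored in the lexicon network
#' @param g_cascade instruction strengths by serial position
#' @param lambda_word heteroassociative coupling strength for words
#' @return an object of class `lexicon`: a tibble of items plus `G` and
#'   coupling metadata
#' @export
build_word_lexicon <- function(n_words, patterns, seed, p_lexicon = 200,
                               g_cascade = c(1.0, 0.9, 0.8),
                               lambda_word = 0.2) {
  stopifnot(inherits(patterns, "pattern_set"))
  p_buffer <- nrow(patterns$states)
  assert_that(n_words <= p_buffer, "more words than stored buffer patterns")
  assert_that(n_words <= p_lexicon, "more words than stored lexicon patterns")

  built <- with_seed(seed, {
    word_ids <- sample.int(p_lexicon, n_words)
    syllables <- sample.int(p_buffer, n_words)
    if (n_words >= 3) {
      repeat {
        pos <- cbind(sample.int(n_words), sample.int(n_words), sample.int(n_words))
        if (all(apply(pos, 1, function(z) length(unique(z)) == 3L))) break
      }
      comp <- cbind(syllables[pos[, 1]], syllables[pos[, 2]], syllables[pos[, 3]])
    } else {
      # degenerate designs (n_words < 3) cannot satisfy the balance
      # constraint; fall back to unconstrained distinct triples
      comp <- t(replicate(n_words, sample.int(p_buffer, 3)))
    }
    list(word_ids = word_ids, comp = comp)
  })

  G <- matrix(0, p_lexicon, p_buffer)
  for (wi in seq_len(n_words)) {
    G[built$word_ids[wi], built$comp[wi, ]] <- g_cascade
  }

  items <- tibble::tibble(
    item_id = seq_len(n_words),
    item_kind = "word",
    mode = "sequential",
    lexicon_pattern = built$word_ids,
    c1 = built$comp[, 1], c2 = built$comp[, 2], c3 = built$comp[, 3]
  )
  new_lexicon(items, G, lambda = c(word = lambda_word),
              p_lexicon = p_lexicon, p_buffer = p_buffer)
}

new_lexicon <- function(items, G, lambda, p_lexicon, p_buffer) {
  structure(
    list(items = items, G = G, lambda = lambda,
         p_lexicon = p_lexicon, p_buffer = p_buffer),
    class = "lexicon"
  )
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf("<lexicon> %d items (%s), G is %d x %d\n",
              nrow(x$items),
              paste(sprintf("%d %s", table(x$items$item_kind),
                            names(table(x$items$item_kind))), collapse = ", "),
              nrow(x$G), ncol(x$G)))
  invisible(x)
}

#' Components of one lexicon item
#' @param lexicon a [build_word_lexicon()] / [compose_mixed_lexicon()] object
#' @param item_id item index
#' @return integer triple of buffer pattern indices
#' @export
item_components <- function(lexicon, item_id) {
  row <- lexicon$items[lexicon$items$item_id == item_id, ]
  assert_that(nrow(row) == 1, sprintf("unknown lexicon item %s", item_id))
  c(row$c1, row$c2, row$c3)
}

#' Compose a mixed sign/word lexicon
#'
#' Signs are triples of gesture elements, one from each cluster (handshape,
#' movement, location); their three components are instructed simultaneously
#' (all G entries 1). Words are ordered triples of syllables sampled without
#' replacement and get the usual graded cascade. Signs couple with
#' `lambda_sign`, words with `lambda_word`.
#'
#' @param gestures clustered [pattern_set()] of gesture elements
#' @param syllables [pattern_set()] of syllable patterns (whole-network)
#' @param n_signs,n_words item counts
#' @param seed RNG seed
#' @param p_lexicon lexicon-network pattern count
#' @param gesture_ids,syllable_ids buffer pattern indices of the gesture and
#'   syllable rows within the combined stored pattern set
#' @param g_cascade word cascade
#' @param lambda_word,lambda_sign coupling strengths by item kind
#' @export
compose_mixed_lexicon <- function(gestures, syllables, n_signs, n_words, seed,
                                  p_lexicon = 200,
                                  gesture_ids = seq_len(nrow(gestures$states)),
                                  syllable_ids = nrow(gestures$states) +
                                    seq_len(nrow(syllables$states)),
                                  g_cascade = c(1.0, 0.9, 0.8),
                                  lambda_word = 0.2, lambda_sign = 1.4) {
  n_g <- nrow(gestures$states)
  n_s <- nrow(syllables$states)
  per_cluster <- split(gesture_ids, gestures$cluster_of)
  n_comb_signs <- prod(lengths(per_cluster))
  n_comb_words <- n_s * (n_s - 1) * (n_s - 2)
  assert_that(n_signs <= n_comb_signs, "n_signs exceeds the combination space")
  assert_that(n_words <= n_comb_words, "n_words exceeds the combination space")

  built <- with_seed(seed, {
    # enumerate the sign space lazily: sample distinct triples
    sign_comp <- matrix(0L, 0, 3)
    seen <- character(0)
    while (nrow(sign_comp) < n_signs) {
      cand <- vapply(per_cluster, function(z) safe_sample(z, 1), integer(1))
      key <- paste(cand, collapse = "-")
      if (!key %in% seen) {
        seen <- c(seen, key)
        sign_comp <- rbind(sign_comp, cand)
      }
    }
    word_comp <- matrix(0L, 0, 3)
    seen <- character(0)
    while (nrow(word_comp) < n_words) {
      cand <- syllable_ids[sample.int(n_s, 3)]
      key <- paste(cand, collapse = "-")
      if (!key %in% seen) {
        seen <- c(seen, key)
        word_comp <- rbind(word_comp, cand)
      }
    }
    lex_ids <- sample.int(p_lexicon, n_signs + n_words)
    list(sign_comp = sign_comp, word_comp = word_comp, lex_ids = lex_ids)
  })

  p_buffer <- max(syllable_ids, gesture_ids)
  G <- matrix(0, p_lexicon, p_buffer)
  comp <- rbind(built$sign_comp, built$word_comp)
  kinds <- rep(c("sign", "word"), c(n_signs, n_words))
  for (ii in seq_len(n_signs + n_words)) {
    G[built$lex_ids[ii], comp[ii, ]] <-
      if (kinds[ii] == "sign") c(1, 1, 1) else g_cascade
  }
  items <- tibble::tibble(
    item_id = seq_len(n_signs + n_words),
    item_kind = kinds,
    mode = ifelse(kinds == "sign", "simultaneous", "sequential"),
    lexicon_pattern = built$lex_ids,
    c1 = comp[, 1], c2 = comp[, 2], c3 = comp[, 3]
  )
  new_lexicon(items, G, lambda = c(word = lambda_word, sign = lambda_sign),
              p_lexicon = p_lexicon, p_buffer = p_buffer)
}

#' Serialize a lexicon to JSON (bit-exact round trip)
#' @param x a lexicon
#' @param path file path
#' @export
write_lexicon <- function(x, path) {
  obj <- list(
    items = x$items, G = x$G, lambda = as.list(x$lambda),
    p_lexicon = x$p_lexicon, p_buffer = x$p_buffer
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_lexicon
#' @export
read_lexicon <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_lexicon(tibble::as_tibble(obj$items), as.matrix(obj$G),
              unlist(obj$lambda), obj$p_lexicon, obj$p_buffer)
}
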