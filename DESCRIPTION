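Package: pottsbuffer
Title: Potts Attractor-Network Model of the Phonological Output Buffer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates word and sign production with coupled Potts attractor
    neural networks. A lexicon network holding long-term word memories cues a
    buffer network through graded heteroassociative connections; firing-rate
    adaptation on two timescales, fast and slow local inhibition, and a dynamic
    global (or cluster-wise) threshold let the buffer latch through the three
    syllables of a word in order, or sustain the three gesture elements of a
    sign simultaneously. Includes generators for random Potts patterns and
    structured lexica, a vectorized batch simulator, utterance extraction from
    overlap trajectories, a speech-error taxonomy (transpositions,
    perseverations, omissions, insertions), ablation experiments, and tidy
    accessors and plots for all results.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
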