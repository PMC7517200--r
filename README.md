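# pottsbuffer

Attractor-network simulations of the phonological output buffer (POB) — the
working-memory stage that turns a stored word into an ordered sequence of
syllables — and of its sign-language counterpart, where three gesture
elements (handshape, movement, location) must be produced simultaneously
instead.

Two Potts attractor networks are coupled: a **lexicon** (600 units) that
holds word-level long-term memories, and a **buffer** (200 units) that holds
the phonological units. Each Potts unit is a cortical patch with `S = 7`
active states and one quiescent state; memories `ξ_i^μ` are stored with the
covariance rule

    J_ij^kl = c_ij / (C_m a (1 − a/S)) Σ_μ (δ_{ξ_i^μ k} − a/S)(δ_{ξ_j^μ l} − a/S)

on a diluted connectivity. A cued word sends a graded heteroassociative
"cascade" (weights 1.0/0.9/0.8 on its 1st/2nd/3rd syllable) into the buffer;
latching dynamics — the interplay of fast/slow firing-rate adaptation,
fast/slow local inhibition and an activity-dependent global threshold —
serializes the syllables. Produced sequences are classified into the
speech-error taxonomy used for buffer-impaired patients: transpositions
(wrong order), perseverations (repetition), omissions (shorter sequence) and
insertions (wrong syllable).

The package provides:

- generators for random Potts pattern sets, clustered gesture-element
  patterns, positionally balanced word lexica and mixed sign/word lexica;
- a vectorized C++ batch simulator of the coupled dynamics, plus a plain-R
  reference stepper (`compute_field()`, `update_activations()`,
  `step_dynamics()`);
- experiment drivers: `run_production()`, `run_batch()`, `run_ablation()`,
  `run_sob_batch()`/`run_sob_sequence()`, `run_latching_scan()`,
  `run_wm_kick_experiment()`, `coactivation_diagnostic()`;
- tidy accessors (`tidy()`, `glance()`) and plots (`autoplot()`) for every
  result type, and YAML experiment profiles (`list_profiles()`).

## A worked example

```r
library(pottsbuffer)

rec <- run_production("pob_step4", item_id = 1, seed = 42)
rec
#> <potts_trial> item 1: correct (targets 62,198,28; uttered 62,198,28,62)
autoplot(rec)            # overlap trajectories, word + three syllables
```

The record prints the three target syllables (buffer patterns 62, 198, 28),
the extracted utterance sequence — here correct, followed by one trailing
re-utterance ("keeps speaking", tracked separately, not an error — scoring
uses the first three utterances) — and the label.

A full batch cues every word of three independently drawn 50-word lexica:

```r
seeds <- sapply(1:3, function(b) seed_for(1, paste0("batch", b)))
b <- run_batch("pob_step4", seeds)
tidy(b)
#> # A tibble: 5 × 3
#>   category         percent   sem
#>   <fct>              <dbl> <dbl>
#> 1 correct           52.7   0.667
#> 2 wrong_order       38     3.06
#> 3 repetition         8.67  1.76
#> 4 shorter_sequence   0     0
#> 5 wrong_syllable     0.667 0.667
glance(b)$correct_fraction
#> [1] 0.527
autoplot(b)              # error-distribution bar chart
```

Wrong order (transposition) dominates the errors, as in buffer-impaired
speakers; the correct-sequence rate of this implementation sits at ~52–64%
across realizations (see the vignette's "Known limitations").

Ablations switch off one mechanism at a time:

```r
run_ablation("pob_step4", "no_slow_adaptation", seeds)   # repetitions dominate
run_ablation("pob_step4", "no_dynamic_threshold", seeds) # low, mixed accuracy
run_ablation("pob_step4", "no_fast_local_inhibition", seeds)
```

and the sign buffer stores 25 signs and 25 words in one clustered network:

```r
sob <- run_sob_batch("sob_default", seed = 2)
tidy(sob)
#> # A tibble: 2 × 5
#>   kind      n correct_fraction gesture_intrusions syllable_intrusions
#> 1 sign     25             1                   0                    0
#> 2 word     25             0                  25                    0
```

All 25 signs sustain their three gesture elements simultaneously with no
syllable intrusions; word production inside the sign buffer fails in this
implementation (see vignette).

## Command line

```sh
Rscript inst/cli/pottsbuffer batch --profile pob_step4 --seed 1 --out out/
Rscript inst/cli/pottsbuffer simulate --profile pob_step4 --item 3 --seed 1 --out out/
Rscript inst/cli/pottsbuffer ablate --profile pob_step4 --flag no_slow_adaptation --seed 1 --out out/
Rscript inst/cli/pottsbuffer sob --profile sob_default --seed 1 --out out/
Rscript inst/cli/pottsbuffer phase --seed 1 --out out/
```

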