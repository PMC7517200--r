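---
title: "A Potts attractor model of the phonological output buffer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Potts attractor model of the phonological output buffer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`pottsbuffer` simulates spoken-word and sign production with two coupled
Potts attractor networks. Each Potts unit stands for a small patch of cortex
with `S` discriminable active states plus a quiescent state; its activation
is a probability-like simplex over the `S + 1` options. Long-term memories
are lists of unit states `ξ_i^μ ∈ {0, …, S}`, stored once in tensor
couplings by a covariance ("simil-Hebbian") rule on a diluted connectivity
(each unit receives `C_m` inputs):

J_ij^kl = c_ij / (C_m a (1 − a/S)) · Σ_μ (δ(ξ_i^μ, k) − a/S)(δ(ξ_j^μ, l) − a/S)

with `a` the fraction of units active per memory. A *lexicon* network (600
units) stores word-level patterns and is parameterized not to latch; a
*buffer* network (200 units) stores the phonological units (syllables) and
is driven through heteroassociative couplings of the same form, weighted by
an instruction matrix `G` and a coupling strength `λ`. For a word, `G`
carries a graded cascade (1.0 / 0.9 / 0.8) over its first/second/third
syllable — the only order information the buffer receives.

The dynamics couple four adaptive processes to a softmax activation update:

* input integration `τ1 dr/dt = h − θ − r`, with the field `h` combining
  recurrent, heteroassociative, and local-feedback (`w`) terms;
* state-specific adaptation `θ_ik`, split into fast and slow components
  (`τ2_fast = 11.1`, `τ2_slow = 33.3`, weight `γ2_fast = 0.5`), modelling
  neural fatigue — the engine of latching;
* unit-level inhibition `θ_i0 = θ_A + θ_B` with a fast component
  (`τ_A = 2`, share `γ_A = 0.3`) and a very slow one (frozen on trial
  timescales);
* a dynamic threshold `Û` shared across the buffer (or across each unit
  cluster in the sign buffer), tracking the mean active fraction with
  `τ_U = 2` and enforcing winner-take-most competition among patterns.

Production works as a relaxation oscillator: the cued word holds a constant
graded drive on its three syllables; the dynamic threshold lets exactly one
ignite; adaptation terminates it; during the threshold dip the next
most-driven *fresh* syllable ignites. Utterances are read off the overlap
trajectories with a hysteresis detector and classified into the speech-error
taxonomy (transposition / perseveration / omission / insertion).

## Parameters that matter

All profile values are in `inst/profiles/*.yaml`; time constants are in the
unit where `τ1 = 3.33`. Defaults follow the published parameter set
(`N_POL = 600`, `C_m = 90`; `N_POB = 200`, `C_m = 150`; `p = 200`; `S = 7`,
`a = 0.25`, `β = 12.5`, `U = 0.1`, `w_POL = 0.45`, `w_POB = 0.5`,
`λ_word = 0.2`, `C_m^het = 150`), with the following package-level choices:

* **Coupling gain 1.35 and threshold scale 0.55.** Taken at face value, the
  printed combination of `λ = 0.2`, `U = 0.1`, `β = 12.5` and a dynamic
  threshold normalized by `a·N` cannot produce: at `β·U = 1.25` the null
  state is only marginally quiescent, the threshold equilibrates near 0.3
  (the source's own quoted thermal value is 0.216), and the maximal cascade
  drive `λ·G·(1 − a/S) ≈ 0.19` never clears it — the buffer stays silent.
  Two scale constants are therefore calibrated once and shared by every
  experiment: the heteroassociative gain (1.35, multiplying every `λ`) and
  the threshold normalization (`0.55·N_scope` in place of `a·N_scope`).
  With them the model shows exactly the described staging: overactivation
  with the cascade alone, sequential-but-coactivated retrieval with fast
  inhibition, isolated clean utterances under the dynamic threshold, and
  repetition suppression from slow adaptation.
* **Cue.** The lexicon cue is an additive field of strength 1.0 on the
  word's pattern states, held for 110 time units. A brief cue is not
  enough: the word attractor erodes after roughly `1.2·τ2_POL` under its
  own adaptation, which is shorter than one utterance cycle; the held cue
  keeps the word active across the three-utterance episode, matching the
  published trajectories in which the word deactivates only at the episode's
  end.
* **Integration.** Explicit Euler at `dt = 0.25` (so the fastest
  timescales, `τ_A = τ_U = 2`, take eight steps). At `dt = 1` the
  integration error acts as extra noise in the ignition races and costs
  about ten percentage points of accuracy. The small-network refinement
  test (`test-engine.R`) checks that halving `dt` moves trajectories by
  less than 5%.
* **Initial state.** The global null state, with `r` initialized to the
  value whose softmax reproduces `σ_i^0 = 1 − ε`, `ε = 10⁻³`. Initializing
  the activations alone is not meaningful — the first update would erase
  them.
* **Extraction.** An utterance opens when a pattern's overlap crosses 0.5
  while dominant, closes below 0.35 or when overtaken by a pattern leading
  by ≥ 0.1, and must last ≥ 10 time units. Hysteresis prevents flicker
  double-counts; labels are insensitive to the opening threshold across
  0.45–0.6. Classification uses the first three utterances; later ones are
  tracked as a "keeps speaking" diagnostic.

## The sign buffer

For signs the same buffer (201 units) is split into three 67-unit clusters,
one per gesture-element type. Gesture elements are generated inside one
cluster at sparsity 31/67; syllables span the whole network at 51/201; 170
further random patterns are stored as distractors at the syllable
statistics (the source does not state theirs). The dynamic threshold
becomes cluster-wise, normalized by `0.55·67` per cluster — the same scale
as the spoken buffer, with each cluster treated as its own inhibition pool.
Signs couple with `λ_sign = 1.4` and flat `G = 1` on all three elements;
the fast-adaptation share of each (unit, state) pair depends on who
recruits it (0 for gesture-only, `0.5·n_syll/(n_sign + n_syll)` for mixed,
0.5 otherwise), and the adaptation rates are randomized per (unit, state)
(`1/τ ~ N(b, b_slow/4)`, truncated at 10⁻⁴). Success for a sign requires
all three elements simultaneously above overlap 0.5, each dominant within
its own cluster, for ≥ 50 consecutive time units; intrusions are judged
within the production episode (cue window + 50 units).

## What the generators emulate — and what the tests can show

All inputs are synthetic by design: uncorrelated exact-count random
patterns, a positionally balanced 50-word lexicon (three random
position-permutations of the 50-syllable pool, rejected until no word
repeats a syllable), and the mixed 25-sign/25-word inventory drawn from 15
gesture elements and 15 syllables. None of this models real phonology — no
phonotactics, no feature structure, no frequency statistics — so passing
tests demonstrate properties of the mechanism, not fits to human data.

## Known limitations

Honesty about where this implementation's behavior departs from the
published statistics, at the calibrated operating point (all of this is also
visible in the acceptance suite, which keeps the corresponding checks
failing rather than weakened):

* The full model's correct-sequence rate plateaus at ~52–64% across
  pattern-set realizations (published: ~72%). The residual errors are
  overwhelmingly transpositions of the 2nd/3rd syllables, whose cascade
  separation (0.9 vs 0.8) is comparable to the quenched pattern-to-pattern
  variability of the recurrent gain at this network size.
* Spontaneous latching from the marginally quiescent background is stronger
  than in the source. Without the dynamic threshold (the intermediate
  model), extraneous stored patterns intrude into the first three
  utterances in most trials, so the ~55% intermediate-model accuracy is not
  reproduced (~20% here); with the threshold on, the same liveliness shows
  up only as trailing activity after production.
* Utterance termination here is carried mainly by the dynamic threshold
  rather than by fast unit-level inhibition, so removing `γ_A` barely
  impairs production, unlike the published omission-dominated ablation.
  The other two ablation signatures (repetitions without slow adaptation;
  low, error-diverse accuracy with a static threshold) do reproduce.
* In the mixed buffer, gesture elements latch spontaneously inside their
  clusters during word trials and out-compete the weaker word cascade, so
  word production in the sign buffer fails here; sign retrieval itself is
  perfect (all 25 signs sustained, no syllable intrusions), giving material
  separation in one direction only.
* The pattern-load ordering of latching regimes (none → finite → infinite
  with degradation) does not reproduce: this implementation latches most at
  low load and falls into the null state at high load, at both the scaled
  and the published network size.

## Problem sizes used

Batch experiments follow the 3 × 50 published design; the test suite runs
single 50-trial realizations per configuration and smaller networks
(N ≈ 10–400) for unit-level checks; the latching scan and working-memory
experiments use N = 400 with 10 trajectories per condition. The acceptance
script reruns the full 3 × 50 design for each headline number.
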