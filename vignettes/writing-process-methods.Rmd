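---
title: "Methods: keystroke and gaze analysis of written composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: keystroke and gaze analysis of written composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models it
fits, the conventions it fixes where the underlying constructs leave
room, the synthetic data it validates against, and the limits of both.

## The process model

Typewritten composition is treated as a semi-parallel cascade: planning
(message, syntax, lexicon, orthography) runs concurrently with motor
output. When planning keeps pace, the interval between two keypresses
(IKI) reflects finger-movement time only; when an upstream process lags,
the IKI absorbs the planning delay. IKIs therefore mix two distributions
— *fluent* and *hesitation* — rather than splitting at an arbitrary
"pause threshold". During hesitations writers sometimes look back into
the text already written; the package's focus is lookback that is *not*
followed by revision, the kind plausibly used to re-cue content.

## Document replay and segmentation

Editor events (`insert`, `backspace`, `delete_range`, `cursor_move`,
`mouse_move`, `shift`) are replayed into a timeline of document states.
Conventions:

* 0-based character indices, half-open delete ranges.
* The *point of inscription* is the index of the last-typed character;
  only text-modifying events move it, so cursor excursions used for
  reading leave it in place.
* Words are maximal non-whitespace runs. A sentence ends at `.`, `?` or
  `!` followed by whitespace (or end of text); abbreviations are not
  handled — the synthetic texts contain none. The whitespace after a
  terminator already belongs to the next sentence, which is what makes
  the minimum lookback depth at a sentence boundary exactly 1.
* Paragraphs split at newline characters.

Fixations are anchored against the text state at their onset. Screen
coordinates pass through a fixed-grid monospace layout model
(configurable characters/line, px/char, px/line, prompt region above the
text area); the real editor's rendering is not reproduced, so the grid is
the documented convention, and fixations that already carry a text anchor
(`char_idx`) bypass it. Distances behind the point of inscription are
signed: the character distance is measured from the fixated character
itself, and the word distance counts word boundaries between the fixated
word and the word containing the point of inscription. A fixation landing
on whitespace is assigned the nearest word by edge distance.

## Transition taxonomy

Consecutive keypress pairs are classified by the location of the
transition and by whether the second keypress continues the text
(writing) or initiates revision (editing). Where the taxonomy leaves
detail open, the package fixes it as follows (the session generator uses
the same rules, and a test asserts 100% agreement between generator
labels and classifier output):

* Any non-space typed character counts as letter-like, including digits
  and punctuation; terminators matter only as the character preceding a
  space. This maximises retained transitions.
* Post-word transitions (letter then space) are always merged into the
  within-word location: whether a character preceding an *edit* ends a
  word is indeterminate, so the merged category is the only one
  consistently available.
* Shifted capitals take two keypresses. The transition *into* the capital
  ends at the shift keypress (the shift is when the writer committed to
  the letter); the transition *out of* it starts at the character
  keypress.
* Editing transitions are categorised by the preceding keypresses only:
  `word->edit`, `pre-word->edit`, `pre-sentence->edit`.
* A run of cursor moves returning exactly to its origin with no
  intervening text change is absorbed into the surrounding transition (a
  scrolling strategy during lookback, not an edit).
* Pairs that start at an editing action, space-after-space pairs, and
  mouse-only pairs are tagged `other` and excluded downstream.

Before duration modelling, IKIs ≤ 50 ms (key-overlap artefacts) and
≥ 30 s (off-task activity) are removed, and any
participant × language × location × mode cell larger than 200
observations is reduced to exactly 200 by seeded sampling without
replacement.

## Lookback definition

A lookback is the maximal sequence of fixations whose onsets fall within
a writing transition's window, qualifying iff (a) the medians of the
in-text word and character distances are at least 1 word *and* 5
characters behind the point of inscription, (b) more than 80% of the
sequence's fixations lie strictly behind it, (c) the sequence does not
start on the writing prompt, and (d) fewer than 50% of its fixations are
on the prompt. Interpretations fixed here: medians are computed over
in-text fixations using signed distances (prompt and off-text fixations
count only in the denominators of (b) and (d)); the 5-character distance
is measured in linear-text characters, not screen columns; no
sub-sequence search is attempted — the window's full fixation sequence
either qualifies or it does not. All four thresholds are exposed for
sensitivity analysis (`lookback_criteria()`). Editing transitions are
excluded: looking back to the site of an edit is trivially expected.

Metrics: duration is the sum of all member fixation durations; words
fixated counts word *entries* (consecutive fixations on one word count
once, re-entries count again); depth is the sentence distance of the
modal fixated sentence, with ties excluded. The detector is tested for
exact agreement with an independent brute-force evaluation of (a)–(d) on
1,000 randomized windows, and for recall 1.0 / false-positive rate 0 on
generator output.

## Text measures

Tokenization matches the replay segmenter; tokens are case-folded and
stripped of punctuation. The open/closed ratio uses small shipped
English and Spanish function-word lists (deliberately minimal and
user-overridable — no standard inventory is bundled with the construct).
MTLD walks the token stream, completing a factor whenever the running
type-token ratio drops to ≤ 0.72 and adding a partial factor
`(1 − TTR)/(1 − 0.72)` at the end; the reported value averages the
forward and backward passes; texts whose TTR never reaches the threshold
are flagged undefined.

## The synthetic-session generator

The generator emits event logs, fixation streams, and ground truth for
every downstream stage. Its defaults *are* the study conditions the
package models: 39 participants × two languages; a shared fluent IKI
mean of 153 ms; hesitation means (L1/L2) of 1366/1912 ms before
sentences, 433/703 before words, 271/370 within words, with mixing
proportions .78/.94, .53/.88, .08/.20; editing probabilities .15/.24,
.07/.13, .05/.07; lookback probabilities .342/.396, .041/.108,
.003/.008 with durations 1932/2711, 1153/1423, 795/1004 ms, words
fixated 8.67/11.26, 4.42/4.59, 2.55/2.6, and depths 1.45/1.68, .54/.80,
.46/.85; texts of about 34/23 sentences of 21/14 words. Values the
underlying conditions do not pin down were chosen once as realistic and
are not revisited: lognormal scales of 0.25 (fluent) and 0.6
(hesitation), participant SDs of 0.15 on log duration and 0.2–0.3 on
logit probabilities, a 90 ms shift-to-character gap.

Editing episodes are local backspace-and-retype corrections at the rate
of the location's editing probability. Text content is a synthetic
lexicon per language (pseudo-word open class, shipped closed-class
words mixed in at a rate matching the target open/closed ratio):
lengths and boundaries are realistic, semantics deliberately absent.

Two couplings are worth knowing about. First, lookbacks are planted only
on hesitation transitions and the window is stretched when needed to
hold the planted fixations (`iki = max(iki, 1.2 × fixation total)`): a
lookback physically requires a window long enough for its fixations.
This slightly inflates the hesitation-mean of cells with frequent, long
lookbacks relative to the configured value — visible in full-pipeline
runs, absent in `simulate_iki_cells()`, which draws from the pure
mixture and is what the parameter-recovery tests use. Second,
non-lookback transitions receive near-inscription single fixations and,
at a low rate, *adversarial* sequences engineered to fail exactly one
criterion, so the detector's rejection paths are exercised.

What the generator does not emulate: real language (no semantics, no
spelling errors with linguistic structure), raw 60 Hz gaze samples or
fixation-parsing noise, calibration drift, scrolling and word-wrap of a
real editor, and mid-document revisions that change earlier text.
Passing tests therefore demonstrate that the pipeline implements its
stated definitions exactly — not that those definitions are robust to
real-world measurement noise.

## Bayesian models

All models are hand-written JAGS code. Shared structure: fixed effects
for language (sum contrast, first level +1/2) and two location contrasts
(before-sentence vs before-word, +1/2 vs −1/2; within-word +1/2 vs the
other two at −1/4) plus their interactions; participant random
intercepts and by-participant language slopes; weakly-informative
priors: Normal(0, 1) on standardized/log/logit-scale coefficients,
half-Normal(0, 1) on random-effect SDs.

The IKI mixture adds: Normal(log 150, 0.5) on the fluent location;
positive-truncated Normal(0, 1) on each cell's hesitation shift (the
positivity constraint is the label-switching guard); by-participant
mixing proportions on the logit scale; and weakly-informative scale
priors — Normal(0.3, 0.2) truncated positive on the fluent scale,
Normal(0.7, 0.2) on the hesitation scale. The scale priors do real work:
without them a single lognormal can be split into two near-identical
components, and with them the split is penalised. They are overridable
(`prior_sig_f`, `prior_sig_h`). Latent component indicators are
initialised by thresholding at 250 ms, which keeps chains out of the
label-degenerate mode. Cell summaries are population-level ms-scale
means, `exp(mu_f + delta_c + sigma_h^2/2)`, matching how the generator
converts means to lognormal locations, so generating truth and fitted
summaries share a scale.

Sign conventions: duration and proportion language effects are
first-minus-second contrasts, so an outcome larger in the second
condition prints negative. The multivariate text model instead reports
the standardized change *from* the first condition *to* the second
(positive measures are log-transformed, then z-scored) — the convention
in which a shorter second-language text prints a negative word-count
effect and a longer mean word length prints positive.

Bayes factors use the Savage–Dickey ratio `p_prior(0)/p_posterior(0)`,
with the posterior density at 0 from a Gaussian kernel estimate
(Sheather–Jones plug-in bandwidth, Silverman fallback). When the
posterior has no draws within five bandwidths of the null, the density
cannot be estimated and the BF is reported as a lower bound from a
one-draw density ceiling. For derived mixture effects, whose induced
prior is not normal, the prior density is estimated from prior draws the
same way. Display caps at 100 (`> 100`). KDE tails are unreliable:
validation against the conjugate normal–normal closed form is done at
nulls within about two posterior SDs, where 40k draws estimate the
density to a few percent.

### Sampling, convergence, and known degeneracies

Default sampler: 2 chains × 750 kept draws after 300 adaptation + 500
burn-in, seeded per chain. Fits attach split-chain Rhat and effective
sample sizes for the reported parameters and warn above Rhat 1.05;
`require_convergence = TRUE` turns the warning into an error. At these
reduced-draw settings the mixture's fluent location routinely shows Rhat
up to ~1.1 with recovery intact, which is why the default is a warning;
final inference should raise chains and draws and demand Rhat < 1.01.

Two degeneracies are inherent and documented rather than hidden. At the
single-component boundary (no true hesitations) the mixture is only
weakly identified: a lognormal tolerates a vanishing-shift split, so the
mixing proportion has an unidentified ridge and chains can sit in
either mode; the identifiable functionals — the fluent mean, the implied
overall mean, the absence of any sizeable hesitation excess — are what
the tests assert. At the Poisson limit of the negative binomial the
dispersion parameter is unidentified from above and its Rhat may warn;
cell means are unaffected.

## Problem sizes

The test suite fits the mixture at 30 participants × 200 before-word
IKIs per language (the scale of the conditions it models) with 2 × 600
kept draws, and the binomial/lognormal/negative-binomial recoveries at
39 participants with 12 observations per cell, single replicate; the
recovery criterion is 95% interval coverage of the generating cell
values (at most one miss among six cells per family). The workflow
scripts and `scripts/acceptance.R` run an 8-participant cohort at
otherwise default conditions — the rates and effects are unchanged, the
cohort is smaller — which keeps a full end-to-end run at a few minutes.

## Limitations

* The event-log schema is a reconstruction: editors log richer action
  streams (selections, IME input, autocorrect) that are out of scope.
* The layout model is a fixed grid; real rendering (proportional fonts,
  wrapping, scrolling) would change fixation anchoring and is the main
  obstacle to applying the pipeline to arbitrary editors.
* Closed-class lists are minimal; open/closed ratios are comparable
  within this package, not against external inventories.
* Savage–Dickey BFs are prior-sensitive by construction; the prior
  configuration is part of any reported result.
* MTLD of the synthetic lexicon runs higher than natural text of equal
  length, because pseudo-word pools lack natural frequency skew; the
  generator's diversity is structural, not linguistic.
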