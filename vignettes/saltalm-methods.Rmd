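---
title: "Automated language measures: definitions, conventions, and validation design"
author: "saltalm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated language measures: definitions, conventions, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltalm)
```

`saltalm` turns SALT-style transcripts of examiner–child conversation into
seven per-participant Automated Language Measures (ALMs), recodes them onto
a shared ordinal impairment scale, and runs the statistical battery used to
validate such measures against diagnostic groups and clinical scores. This
vignette is the package's own account of what is computed, which conventions
were open choices, and what the synthetic-data pipeline does and does not
demonstrate.

## The transcript dialect

Published SALT conventions vary between laboratories, and the exact coding
manuals behind clinical corpora are typically unpublished. The package
therefore fixes one documented dialect, bit-exactly:

* one c-unit per line, prefixed `C` (child) or `E` (examiner);
* mazes — false starts, repetitions, filled pauses — in parentheses;
* bound morphemes slash-marked on the word (`dog/s`, `walk/ed`, `go/ing`,
  `he/'s`): a token's morpheme count is 1 plus its slash markers, and its
  *root* is the material before the first slash (no lemmatization — `ran`
  and `run/ing` are different roots);
* `X` marks an unintelligible word, `XX` a fully unintelligible segment;
* an abandoned c-unit ends with `>` and is *incomplete*;
* `+ key: value` headers carry metadata (`participant_id`,
  `duration_min`).

Task duration is metadata, never inferred from text: it is the length of
the task *audio* in minutes, which text cannot recover.

Tokenization splits on whitespace, strips terminal punctuation, and case
folds. The multiword fillers *you know* and *I mean* are merged greedily,
left to right, into single filler units — but only inside mazes. Outside a
maze the same words are ordinary content (`You know him.`), and fillerhood
is only ever consumed by maze classification and the filler denominator,
both maze-internal; merging everywhere would silently distort morpheme
counts and repetition matching.

A c-unit is *fluent* iff it contains no maze, *intelligible* iff it
contains no unintelligibility mark anywhere (mazes included), and
*complete* iff not abandoned. Whether the original clinical coding treated
interrupted utterances as incomplete is unknowable from published material;
the package equates incomplete with abandoned.

## Measure conventions worth stating

**MLUM and NDWR** are computed over complete, fluent, intelligible child
c-units only, from out-of-maze tokens. Because eligible c-units are
maze-free by definition, excluding maze-internal tokens is moot — it is
kept explicit for robustness should eligibility rules ever be relaxed.

**Um proportion** counts `um` and `uh` anywhere in child speech, mazes
included: filled pauses live inside mazes under SALT conventions, and an
out-of-maze-only count would have a near-zero denominator. When neither
occurs the measure is *undefined* and encoded as `NA`, never imputed;
exclusion decisions belong to the analysis pipeline, not the measure.

**Content maze proportion** classifies each maze wholesale: a maze with at
least one non-filler, intelligible word is a content maze; the denominator
adds the filler *tokens* occurring in filler-only mazes. Fillers inside
content mazes are not double-counted into the denominator, reading the
formula's "content mazes" and "fillers" as disjoint events. Both this
measure and the um proportion return `NA` on an empty denominator.

**CPM** counts *attempted* child c-units — including incomplete and
unintelligible ones — per minute.

## Repetition matching

Repetition proportion measures the child's echo of the examiner's
immediately previous turn. A *turn* is a maximal run of same-speaker
c-units. Within a child turn, the matcher finds non-overlapping contiguous
runs of two or more child words that equal a contiguous examiner
subsequence under:

* word identity, after case folding;
* pronoun substitution within the groups {you, I, me, we, us}, {he, she},
  {him, her};
* free deletion of {the, a, an, is, are, am, 'm, 's, 're} on either side.

Three conventions were genuinely open and are fixed as follows:

1. **Contiguity.** Matched runs are contiguous on both sides after
   deletable words are removed. Echoes are contiguous phenomena, and
   non-contiguous matching degenerates (almost any shared word pair would
   eventually match).
2. **Deletable words never count.** They may be skipped freely, and they
   contribute to neither the matched-word numerator nor the child-word
   denominator. This is forced by the canonical worked exchange — examiner
   *"And the moon was coming up."*, child *"The moon was coming up then."*
   — which scores 4/5: the child utterance has six orthographic words, so
   the published count of five is only reachable when *the* is outside
   both counts; and a maximizing matcher that credited exact matches of
   deletable words would report five matched words, not four.
3. **Scope of the denominator.** Child words inside mazes and
   unintelligible tokens are excluded from both sides, consistent with
   their treatment elsewhere.

Candidate spans are selected to maximize total matched child words, with a
leftmost-longest tie break, via dynamic programming over reduced child
positions. An exhaustive oracle (`brute_force_repetition_oracle`)
enumerates every child-range set, examiner range, and deletion assignment
on short turns; the test suite holds the two implementations equal on
hundreds of randomized turn pairs whose vocabulary deliberately includes
the pronouns and deletable words.

## Ordinal recoding

Raw ALMs have heterogeneous, partly skewed distributions. To put them on a
common scale, each measure is recoded 1–4 against the cohort's own
empirical centiles: values up to the 50th centile score 1, then 2 up to the
75th, 3 up to the 90th, and 4 above it. For MLUM, NDWR, um proportion, and
CPM — where *low* values indicate impairment — the value is oriented
(negated) first, so score 4 is always the impaired 10% tail and the
50/25/15/10% occupancy pattern holds for every measure. Two numerical
choices are the package's own and are stated so results are reproducible
bit for bit: the quantile estimator is the common type-7 linear
interpolation, and bins are right-closed (a value equal to a threshold
takes the lower-impairment bin).

The um proportion needs one adjustment: zeros (children who only ever said
*uh*) can exceed 10% of a sample, in which case the zero block straddles
the top threshold and ties would drop some zeros to score 3. When zeros
exceed 10%, the top threshold is lowered to the largest oriented value
strictly below zero, so *every* zero scores 4 while no positive value
outranks a smaller one. This generalizes the fixed "shift the boundary to
the 86th centile" style of adjustment, which is specific to one sample's
zero rate; with ~12–14% zeros the generalized rule reproduces exactly that
shift. Fitted scales serialize to JSON so a frozen scale can be reapplied
to new data.

Bins require at least 10 defined values and refuse constant samples.

## The validation battery

`run_validation()` mirrors the structure of a measure-validation study:

* **Group comparison.** Per-ALM Kruskal–Wallis one-way ANOVAs on ranks
  (tie-corrected, via `stats::kruskal.test`), chosen because several
  measures are far from normal. Effect size is the rank eta-squared
  `(H − k + 1)/(n − k)`, reported unclamped — under the null it can be
  slightly negative, and clamping would bias simulation summaries.
  Significant comparisons get Games–Howell post-hoc contrasts (unpooled
  variances, Welch–Satterthwaite degrees of freedom, studentized-range
  p-values via `stats::ptukey`), implemented in the package since no
  installed dependency provides the test.
* **Convergent validity.** Spearman rank correlations (Pearson on
  midranks, i.e. tie-corrected) between ALMs and any supplied clinical
  score columns, pairwise-complete with a minimum of three pairs per cell,
  asymptotic two-sided p-values. No multiplicity adjustment is applied —
  the battery reports every comparison and leaves error-rate policy to the
  reader, which is also why the group screen is reported measure by
  measure.
* **Discriminant validity.** Binary logistic models (`stats::glm`) on one
  *shared* listwise-complete subsample: a covariates-only baseline
  (age + IQ), one model per ALM, and a combined model with all seven.
  Ordinal scores enter as 4-level categorical predictors with level 1 as
  reference — a joint Wald test on 3 degrees of freedom (fewer if a level
  is unobserved in the subsample) — rather than as
  linear scores, which would assert equal spacing the scale does not
  promise. Participants with any undefined measure (um proportion, most
  commonly) or missing covariate are excluded from *every* model before
  fitting, so all nine models report the same `n_used` and their fit
  statistics are comparable. Each model reports −2 log-likelihood,
  Nagelkerke pseudo-R² (exactly 0 for the null model), in-sample accuracy,
  sensitivity and specificity at a 0.5 cutoff (ties classify positive),
  and the AUC of its fitted probabilities (empirical ROC via `pROC`; the
  AUC equals concordance probability with half credit for ties).
  Quasi-complete separation is flagged on the result, not silently
  ignored — with strong effects and 23 parameters the combined model can
  and does saturate in-sample.

In-sample metrics match the single-sample design of a validation study;
cross-validated classification is deliberately out of scope.

## The synthetic cohort generator

`generate_cohort()` emulates the structure of an examiner-led conversation
task: examiner question templates alternate with one or more child c-units.
Child utterances realize a per-group token model — utterance length
1 + negative-binomial (overdispersed, like real utterance lengths), words
drawn Zipf-weighted from a finite vocabulary pool (so NDWR saturates with
talkativeness, as vocabulary measures do), bound morphemes attached with a
fixed probability, front-positioned mazes that are content or filler-only,
um-versus-uh choice by a preference parameter, per-c-unit unintelligibility
and abandonment, and explicit echo windows (2–5 contiguous words, optional
pronoun flip) copied from the preceding examiner turn.

Two design points matter for interpreting tests:

* **Echoes are detectable by construction, and only echoes are.** The
  child vocabulary pool is disjoint from the examiner templates, the
  pronoun groups, and the deletable words, so with echo probability zero
  the repetition proportion is *exactly* zero — the undefined/zero paths of
  the pipeline are exercised deterministically, and any detected repetition
  is a planted one.
* **Duration is derived, with individual variation.** Each participant
  draws a speech rate from a gamma distribution around the group mean
  (coefficient of variation 0.2, the order seen in clinical samples), and
  duration = c-units / rate. The group mean of CPM therefore recovers the
  planted rate, while within-group variation keeps rank tests
  non-degenerate.

Default group parameters qualitatively mirror the contrasts reported for
school-age ASD versus non-ASD conversation samples — shorter utterances
(mean words 4.5 vs 5.1, ~1.3 morphemes per word), smaller vocabulary pool
(260 vs 320), more and more-often-content mazes (rate 0.45 vs 0.35, content
share 0.65 vs 0.40), um preference 0.45 vs 0.70, unintelligibility 0.026 vs
0.009 per c-unit, speech rate 11.2 vs 13.5 c-units/min, echo probability
0.10 vs 0.05, about 73–80 c-units per transcript, IQ 99 (SD 19) vs 112
(SD 13) truncated at 70 — not any study's exact means, which depend on a
non-public corpus. What passing tests show is that the *pipeline* recovers
planted structure (directions, calibration, dominance of the combined
model); they cannot show field validity of the measures on real speech,
which has topic structure, self-repetition, and morphology the generator
does not attempt.

`parameter_recovery_check()` reports recovery targets where a closed form
exists: um proportion ↦ um preference, CPM ↦ planted rate, unintelligible
proportion ↦ per-c-unit probability, MLUM ≈ mean words × (1 + morpheme
rate) (slightly inflated by echo insertions), content maze proportion ≈
c/(c + (1−c)·1.3) for content share c and a mean of 1.3 filler tokens per
filler maze. NDWR and repetition proportion have no closed-form target and
are reported without a bias column.

## Simulation sizes and numerical tolerances

The test suite fixes every seed and uses problem sizes chosen to make the
checks sharp but cheap: the matcher-versus-oracle stress test uses 200
random turn pairs of up to 8 tokens (the oracle is exponential in turn
length); recoding occupancy uses 1000 continuous draws (±2% discreteness);
the null calibration of the Kruskal–Wallis screen uses 2000 two-group null
cohorts of 30 participants each with ~30 c-units per transcript — the size
of a rank test under the null does not depend on transcript length except
through ties, which the tie-corrected statistic handles, so shorter
transcripts are pure economy; and the planted-effect classification study
uses the default 50-per-group design at full transcript length. Logistic
coefficients are held to an independent iteratively-reweighted
least-squares oracle at 1e-6; measure fixtures are held to machine
precision against hand tallies.

## Known limitations

* The dialect is a documented stand-in, not a reimplementation of any
  laboratory's coding manual; real SALT exports would need a thin
  conversion layer.
* Morphology is only as rich as the transcribed slash markers; there is no
  lemmatizer, by design.
* The generator's English is synthetic: Zipf draws with front-attached
  mazes, not grammatical sentences. It validates plumbing and statistics,
  not linguistics.
* In-sample classification metrics overstate out-of-sample performance,
  especially for the 23-parameter combined model on ~150 participants;
  the battery reports them because the design under study is a
  single-sample validation, and flags separation when it occurs.
* Games–Howell p-values rely on `ptukey`, whose own accuracy bounds apply
  at extreme quantiles.
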