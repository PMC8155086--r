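# saltalm

Automated Language Measures (ALMs) from SALT-style transcripts of
examiner–child conversation.

Natural language samples are a rich, ecologically valid window on expressive
language in neurodevelopmental conditions, but scoring them by hand is slow
and costly. `saltalm` computes seven per-participant language measures
directly from transcripts, recodes them onto a common ordinal impairment
scale, and runs the cohort-level validation battery used to assess such
measures: nonparametric group comparison, convergent-validity correlations,
and covariate-adjusted logistic classification with ROC analysis. A
synthetic examiner–child cohort generator makes the whole pipeline testable
end to end without any clinical data.

## The seven measures

For a transcript split into c-units (a main clause with its subordinate
clauses, or a freestanding fragment), with mazes (disfluent material) in
parentheses, slash-marked bound morphemes, and `X` marking unintelligible
words:

| Measure | Definition |
|---|---|
| MLUM | mean morphemes per complete, fluent, intelligible child c-unit |
| NDWR | number of different word roots over the same c-units |
| um proportion | #um / (#um + #uh), undefined when neither occurs |
| content maze proportion | #content mazes / (#content mazes + #fillers) |
| unintelligible proportion | share of child c-units partially/fully unintelligible |
| CPM | attempted child c-units per minute of task audio |
| repetition proportion | child words echoed (in sets of ≥ 2) from the examiner's immediately previous turn, over total child words |

A *content maze* contains at least one word outside the closed filler set
(*ah, uh, um, mm, hmm, like, well, you know, I mean*). Repetition matching
allows limited pronoun substitution (*you/I/me/we/us*; *he/she*; *him/her*)
and deletion of *the, a, an, is, are, am, 'm, 's, 're* on either side.

Raw measures are recoded to an ordinal 1–4 impairment scale at the cohort's
empirical 50th/75th/90th centiles (reversed for MLUM, NDWR, um proportion,
and CPM, where *low* values indicate impairment), with a documented
adjustment that sends all zero um proportions to the top impairment score
when zeros exceed 10% of the sample.

## Worked example

```r
library(saltalm)

t <- parse_transcript("
+ participant_id: P01
+ duration_min: 1.0
E And the moon was coming up.
C The moon was coming (um) up then.
C I like dog/s.
", duration_min = 1)

compute_profile(t)
#> <alm_profile>
#>   mlum               4
#>   ndwr               3
#>   um_prop            1
#>   content_maze_prop  0
#>   unintell_prop      0
#>   cpm                2
#>   repetition_prop    0.5
```

The first child utterance contains a filler-only maze `(um)`, so it is not
fluent and only `I like dog/s.` (4 morphemes: i, like, dog, plural -s; 3
distinct roots) enters MLUM/NDWR. The um proportion is 1 (one um, no uh);
the maze is filler-only so the content maze proportion is 0. For
repetition, the child's turn echoes *moon was coming up* — four countable
words out of eight countable child words in the transcript (maze words and
the deletable *the* are not counted), giving 4/8 = 0.5.

A full synthetic study:

```r
spec  <- cohort_spec(seed = 42)              # two groups, planted effects
parts <- generate_cohort(spec)
alms  <- compute_alm_table(lapply(parts, `[[`, "transcript"))
cohort <- merge(cohort_table(parts), alms, by = "participant_id")
val <- run_validation(cohort, case_group = "asd")
val$model_summary    # -2LL, Nagelkerke R2, accuracy, sensitivity, specificity, AUC
plot_roc(val)        # nine overlaid ROC curves
```

The same workflow is available on disk via `alm_simulate()`,
`alm_compute()`, `alm_recode()`, `alm_validate()`, or from a shell through
the thin wrapper `inst/cli/alm.R`:

```sh
Rscript inst/cli/alm.R simulate --out cohort --seed 42
Rscript inst/cli/alm.R compute  --input cohort/transcripts --out cohort/alms.csv
Rscript inst/cli/alm.R recode   --alms cohort/alms.csv --out cohort/scores.csv --bins cohort/bins.json
Rscript inst/cli/alm.R validate --alms cohort/alms.csv --cohort cohort/cohort.csv --scores cohort/scores.csv --out cohort/report
```

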