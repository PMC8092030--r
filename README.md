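# emovista

Phase-resolved emotion surveillance of short social-media posts.

`emovista` is an R implementation of an infoveillance pipeline for tracking
public emotion through defined time phases (for example the stages of a
pandemic) using short posts such as tweets. It is aimed at computational
social scientists and digital epidemiologists who need a tested, fully
reproducible version of this class of analysis, including a synthetic
corpus generator with complete ground truth so every stage can be validated
without access to any platform data.

## What it computes

Given a corpus of posts (id, author, conversation, UTC timestamp, text),
the pipeline:

1. **Preprocesses**: removes URLs/handles, folds `#tag` to `tag`, drops
   stop words (negators and valence modifiers are protected), removes
   high-volume bot/news accounts by a per-user volume quantile, collapses
   duplicated texts, anonymizes authors with salted hashes, and assigns
   each post to a phase window.
2. **Expands emotion lexicons**: trains skip-gram word embeddings with
   negative sampling on the corpus and, for each of Plutchik's eight basic
   emotions (anger, sadness, disgust, fear, joy, surprise, trust,
   anticipation), adds each seed term's k nearest neighbors with cosine
   similarity ≥ τ. A term near several emotions goes to the argmax emotion,
   so lexicons stay disjoint.
3. **Scores emotions**: a match of term *t* (emotion *e*, weight *w*)
   contributes *w* · Π(modifier factors in the preceding window) to *e*;
   an odd number of negators in the window flips the contribution to the
   Plutchik opposite (joy↔sadness, trust↔disgust, fear↔anger,
   anticipation↔surprise). The post's dominant emotion is the argmax.
4. **Profiles intensity**: per-phase totals of the eight scores normalized
   to sum to 100%.
5. **Models transitions**: first-order Markov chains over dominant-emotion
   sequences within conversation threads; `P[i,j] = C[i,j] / Σ_j C[i,j]`
   with undefined rows reported rather than smoothed.
6. **Models topics**: per-phase LDA (collapsed Gibbs), RAKE keyphrases,
   and a cross-phase topic association map from embedding-centroid cosine
   similarity.
7. **Profiles behavior**: a growing self-organizing map (GSOM) over
   per-user topic ⊕ emotion feature vectors, with growth threshold
   `GT = −D · ln(SF)`, and labeled profile clusters from the trained map.
8. **Compares phases**: per emotion, Pearson chi-square tests (no
   continuity correction) and Newcombe hybrid Wilson-score confidence
   intervals for the difference of proportions.

## Worked example

```r
library(emovista)

# two-proportion comparison from published normalized intensities
first <- intensity_profile_from_percentages(
  c(anger = 13.84, sadness = 31.36, disgust = 9.81, fear = 17.58,
    joy = 16.94, surprise = 1.32, trust = 6.56, anticipation = 2.59),
  36317, "first_lockdown")
second <- intensity_profile_from_percentages(
  c(anger = 15.97, sadness = 31.01, disgust = 12.06, fear = 19.66,
    joy = 12.56, surprise = 0.74, trust = 5.63, anticipation = 2.37),
  10604, "second_lockdown")
cmp <- compare_intensity_profiles(first, second)
subset(cmp, emotion %in% c("anger", "sadness"))
#> # A tibble: 2 × 9
#>   emotion p1_pct p2_pct diff_pct ci_low ci_high   chi2 p_value significant
#>   <chr>    <dbl>  <dbl>    <dbl>  <dbl>   <dbl>  <dbl>   <dbl> <lgl>
#> 1 anger     13.8   16.0     2.13  1.36     2.92 30.2   3.80e-8 TRUE
#> 2 sadness   31.4   31.0     0.35 -0.656    1.35  0.475 4.91e-1 FALSE
```

Anger intensity is 2.13 percentage points higher in the second lockdown
(95% CI 1.36–2.92, p < .001) while sadness does not differ (p = .49).

The full pipeline runs from one config:

```r
res <- run_pipeline(demo_config_path(), out_dir = "demo_out")
res$gsom$profiles$profiles   # labeled behavior profiles
res$comparison               # two-lockdown comparison table
```

The demo config simulates a four-phase synthetic corpus, so the whole
analysis — lexicon expansion through behavior profiling — runs in about a
minute with no external data.

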