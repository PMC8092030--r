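---
title: "Methods: phase-resolved emotion surveillance with emovista"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase-resolved emotion surveillance with emovista}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emovista)
```

`emovista` analyzes collections of short social-media posts to track public
emotion across defined time phases. This vignette describes the models the
package implements, the assumptions behind them, the parameters that matter,
and the choices made where the design was genuinely open.

## The analysis model

The unit of observation is a post; posts are threaded into conversations and
each post falls into one phase by its timestamp. Four default phase windows
partition 2020-01-01..2020-09-30 at literal month boundaries (prepandemic
Jan–Feb, first lockdown Mar–May, easing of restrictions Jun, second lockdown
Jul–Sep); the windows are data, not code, and can be replaced.

### Lexicon expansion

Emotion scoring is lexicon-based in the Plutchik eight-emotion space. The
packaged seed lexicon has six seed words per emotion; because any fixed seed
list undercovers a live corpus, seeds are expanded through distributional
similarity: a skip-gram model with negative sampling is trained on the
cleaned corpus, and each seed contributes its `k = 20` nearest neighbors
with cosine ≥ `tau = 0.35`. A candidate close to several emotions is
assigned to the emotion of maximum similarity (ties by lexicographic
emotion order), so expanded lexicons are disjoint by construction and
expansion weight equals cosine similarity.

The embedding trainer is single-threaded by design: parallel SGNS updates
are racy in standard implementations, which breaks exact reproducibility.
Defaults (`d = 100`, `window = 5`, `min_count = 3`, `epochs = 10`) are
small-corpus appropriate; `tau` and `k` were fixed once against the
synthetic generator's planted-satellite benchmark and are documented
artifact defaults, not published values.

### Emotion scoring, negation, and valence modifiers

A lexicon match of term $t$ (emotion $e$, weight $w$) contributes
$w \cdot \prod m_i$ to $e$, where the $m_i$ are multiplicative modifier
factors found within `window = 3` tokens before $t$ (intensifiers 1.5,
inhibitors 0.5 by default). If an odd number of negators precedes $t$ in
that window, the contribution is routed to the Plutchik polar opposite
(joy↔sadness, trust↔disgust, fear↔anger, anticipation↔surprise); an even
count cancels, making the flip an involution. Routing to the opposite
rather than discarding keeps negated mass inside the eight-emotion space; a
`discard` mode is available. Each post gets a single dominant emotion (the
argmax, ties broken by the fixed order anger < sadness < disgust < fear <
joy < surprise < trust < anticipation) because the transition model needs
one state per post; the full score vector is retained.

The three-token negation window is the standard short-text scope; no
published window was available to adopt.

### Intensity profiles and the two-lockdown comparison

Per phase, raw intensity is the sum of post scores per emotion; normalized
intensity rescales the eight totals to 100%. The observation count is the
number of nonzero (post, emotion) cells rather than posts, since one post
can express several emotions — this observation-level convention is also
what makes published observation counts exceed conversation counts in this
literature.

Phases are compared emotion-wise as two independent proportions: Pearson
chi-square without continuity correction (df = 1) and the Newcombe hybrid
confidence interval built from the two Wilson score intervals. The normal
quantile is used at full precision (1.959964 at 95%); with the rounded 1.96
the reproduced bounds drift in the fourth decimal. When only percentages
and totals are available, counts are reconstructed as `round(p * n)`. No
multiple-testing correction is applied, matching the analysis the package
reproduces.

### Transition models

Dominant-emotion sequences are built per conversation per phase,
chronologically (ties by post id), skipping neutral posts. First-order
Markov transition counts are accumulated strictly within conversations —
never across — and row-normalized. Rows whose source emotion was never
observed are reported as undefined rather than smoothed; optional Laplace
smoothing exists for downstream consumers that need a fully defined chain.
Self-transitions are meaningful states (persistence of an emotion) and are
retained.

### Topic models and association

Per-phase topics come from LDA fit by collapsed Gibbs sampling (symmetric
priors, `alpha = 50/K`, `beta = 0.1`, 200 sweeps by default). Documents are
hard-assigned their argmax topic for volume counting; documents whose
maximum topic probability is below `1/K + 0.05` are treated as general
conversation without a prominent topic and excluded from volumes. Shares
are percentages of counted volume. When `K` is not fixed by the user it is
selected by maximizing mean UMass coherence of the top topic terms over a
small grid. Topic labels are the top-3 terms joined; published topic labels
are editorial, so a label map can override them.

Keyphrases are extracted RAKE-style: candidate phrases are maximal runs of
non-stop tokens, word score is degree/frequency over candidates, phrase
score is the sum of word scores.

Topics are associated across phases by the cosine of weight-averaged
embedding centroids of their top terms, truncated at zero so the similarity
lies in [0, 1]; edges require similarity ≥ 0.5 between distinct phases.

### GSOM behavior profiling

Users are represented by concatenated topic-proportion and normalized
emotion blocks (each summing to 1). The growing self-organizing map starts
as a 2×2 grid; each input moves its Euclidean-nearest node and grid
neighbors toward it (Gaussian kernel, learning rate and radius decaying
over the growth phase), and the winner accumulates squared quantization
error. When a node's error exceeds the growth threshold $GT = -D\ln(SF)$, a
boundary winner grows a node in every free adjacent position (new weights
by interpolation with the node beyond, else extrapolation past the parent,
else copy — clamped to the unit cube), and an interior winner redistributes
error to its neighbors scaled by the factor FD. The smoothing phase runs
with no growth, halved initial rate and radius 1. Training is
single-threaded and seeded. Defaults `SF = 0.3`, `alpha0 = 0.3`,
`FD = 0.5`, 50 + 50 epochs, initial radius 3.

Profiles are connected components of the node grid under the rule: an edge
joins grid-adjacent nodes whose weight distance is below a map-wide
reference distance. Two choices here were genuinely open and are worth
recording. First, the reference: the *mean* adjacent-node distance is the
default rather than the median, because adjacent distances are heavy-tailed
— small within a data cluster, an order of magnitude larger across cluster
boundaries — so the mean sits above the within-cluster regime while the
median falls inside it and fragments clusters (`merge_stat = "median"`
remains available). Second, connectivity is computed over all nodes, but a
component only becomes a profile if it contains nodes with at least
`min_hits` mapped observations: sparsely-hit interpolating nodes inside a
dense region must not break connectivity, while boundary nodes never bridge
clusters because their adjacent distances exceed the threshold. Profiles
are labeled by their strongest mean feature dimensions.

The published variant of this algorithm additionally forgets outdated
information during long-running acquisition; that mechanism is unreported
in detail and out of scope here — the standard growing map is implemented.

## The synthetic generator and what passing tests mean

Because no corpus of this kind is publicly deposited, the package ships a
generator that emulates the study conditions with full ground truth: four
phase windows; per-phase mixtures over the eight emotions (the two lockdown
mixtures are the published normalized intensity columns scaled to 1, the
other two encode the narrative pattern of early sadness/fear and
easing-phase joy); per-phase generating transition matrices with emotion
inertia ($P = 0.4I + 0.6\,\mathrm{mixture}$, whose stationary law is the
mixture itself); planted satellite vocabularies that co-occur with seed
terms so embedding expansion has something true to recover; four topical
vocabularies; negators/intensifiers/inhibitors; geometric conversation
lengths (mean 4); uniform timestamps within windows; post lengths uniform
8–25 tokens with ~30% neutral filler and at least 70% of non-filler tokens
from the true emotion's vocabulary; planted user clusters expressed through
topic preference; and bot accounts that re-emit one duplicated text at 20×
the median organic volume.

This emulates label–text consistency, co-occurrence structure, threading,
and contamination — not real language. Passing recovery tests therefore
demonstrates that each algorithm recovers planted structure at realistic
scale and noise, not that the pipeline's accuracy on real tweets matches
these numbers: real negation is longer-range, emotions are expressed
without lexicon terms, topics overlap heavily, and bot behavior is
adversarial rather than mechanical.

## Numerical choices and problem sizes

All stochastic components (generator, SGNS, LDA, GSOM, simulations) are
deterministically seeded and single-threaded; reruns of a config are
byte-identical, which the test suite asserts. Benchmarks use a ~10,000-post
corpus for lexicon recovery (embedding training is the dominant cost, about
a minute), 10,000 simulated transitions for Markov recovery (maximum
absolute estimation error ≤ 0.05), and two 200-point Gaussian blobs in
$[0,1]^4$ (σ = 0.05) for GSOM cluster recovery — sizes at which the
binomial/Monte-Carlo error bounds the tests assert are comfortably
attainable while the full suite stays fast.

Degenerate inputs are rejected explicitly rather than silently repaired:
all-zero intensity phases, sequences shorter than two, K exceeding the
document count, timestamps outside every window, spread factors outside
(0, 1).

## Known limitations

- Lexicon scoring cannot see sarcasm, irony, or emotion expressed without
  emotion-bearing vocabulary; emoji are not interpreted.
- The dominant-label reduction discards mixed-emotion posts' secondary
  emotions from the transition analysis (scores retain them).
- Chi-square on reconstructed counts inherits the rounding of published
  percentages; bounds are reproducible to four decimals, not exactly.
- The volume-quantile bot filter needs the quantile to exceed the bot
  fraction; the duplicate filter catches the rest (the generator's bots
  exercise both).
- First-order Markov chains assume the next emotion depends only on the
  current one within a conversation.
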