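---
title: "Modeling drug-pair response in combination screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling drug-pair response in combination screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comboscreen)
```

## The problem

Systematic pairwise drug screens measure the relative growth of tumor cell
lines under combinations of two drugs across small dose grids (3×3 or 5×3
dose-level combinations; single agents at 3 or 5 concentrations). Growth is
expressed as a fraction: −1 is total lethality, 0 total growth inhibition,
1 unabated growth. Raw values slightly above 1 occur and are treated as
artifacts, capped at 1. `comboscreen` models this data end to end: it
aggregates dosed measurements into per-tuple targets, scores combination
benefit, learns a neural growth predictor from cell-line omics and drug
descriptors, and ranks drug pairs for virtual screening.

## Targets and combination scoring

Dose concentration is deliberately not an input feature. For every
(cell line, drug A, drug B) tuple the modeling target is the *lowest*
growth fraction observed at any dose combination (`aggregate_min_growth()`),
the best inhibition achieved on the grid. This focuses the model on the
effective end of the dose range and substantially de-skews the otherwise
nonresponse-heavy growth distribution.

Combination benefit is scored against a modified multiplicative
expectation. With $y^A, y^B$ the single-agent minimum growths and
$\tilde y = \min(y, 1)$,

$$
z^{AB} =
\begin{cases}
\min(y^A, y^B), & y^A \le 0 \text{ or } y^B \le 0\\
\tilde y^A \cdot \tilde y^B, & \text{otherwise,}
\end{cases}
\qquad
C^{AB} = (y^{AB} - z^{AB}) \times 100 .
$$

Negative $C^{AB}$ means the pair inhibited growth beyond what the two
singles predict multiplicatively — enhanced activity. The min branch
encodes that a fully inhibitory single agent ($y \le 0$) cannot be improved
upon multiplicatively; the truncation $\tilde y$ applies only inside the
product branch, exactly as the score is defined. Whether the singles should
also be truncated before the min branch is ambiguous in the score's usual
statement; we implement the formula as printed (no truncation in the min
branch), which only matters for singles above 1, which the response table
excludes anyway since targets are capped.

`score_table()` joins every pair row with its two single-agent rows per
cell line. Pairs with a missing single-agent measurement are skipped with a
warning by default (real screens have gaps); `on_missing = "error"` makes
them fatal.

## Feature preprocessing

Cell lines are characterized by one or more omics matrices (gene
expression, microRNA, proteome); drugs by a numeric descriptor matrix.
The canonical pipeline (`preprocess_features()`) is:

1. **Sparse-column filter** — descriptor columns with ≥ 90% missing rows
   are dropped (`missing_frac = 0.9`, boundary inclusive).
2. **Mean imputation** — remaining holes are filled with the column mean
   over the fitting rows.
3. **Min–max scaling** — each feature is mapped to [0, 1]; constant
   columns map to 0 to avoid dividing by a zero range.

Abundance-type assays can be `log(x + 1)`-transformed first
(`log1p_transform()`); sources distributed pre-transformed are declared as
such via the state tag rather than sniffed, and descriptors are never
transformed (their heterogeneous scales — binary fingerprints next to
molecular weights — are exactly what min–max scaling absorbs).

Imputation and scaling statistics can be fitted once and reused
(`fit =` argument). By default the package fits statistics on whatever
rows it is given; fitting on training folds and transforming held-out rows
is leakage-safe and supported, while fitting once on the full matrix
mirrors the common whole-dataset preprocessing convention. For entity-level
feature matrices (every cell line and drug appears in training in the
row-level split used here) the distinction is immaterial, which is why the
cross-validation helper preprocesses once up front.

For ablation experiments, `encode_entities()` replaces real features with
one-hot identity vectors or fixed seeded uniform noise vectors
(default width 500), testing whether assays carry information beyond
entity identity.

## The two-level network

`build_growth_model()` constructs a feedforward network with two jointly
trained levels:

* **Feature encoders** — one stack per omics assay, plus a single drug
  descriptor encoder. The two drug slots are symmetric, so one encoder
  instance serves both: all weights are shared by construction. Single-agent
  rows replicate the same descriptors into both slots
  (`predict_single_drug()`).
* **Growth tower** — the encoded features are concatenated and passed
  through a deeper fully connected stack ending in a scalar growth
  prediction, trained on mean squared error.

Adjacent layers of equal width are joined by additive residual skips when
`residual = TRUE`; requesting residuals with unequal adjacent widths is a
configuration error, which is why equal-width stacks are preferred to
pyramids. Activation is ReLU, initialization is fan-in (He) scaled, and
dropout is available but off by default; none of these choices is forced by
the problem, they are conventional defaults, all seed-controlled.

Two numerical choices deserve note:

* **Residual init scaling.** With one-layer residual blocks, plain He
  initialization doubles activation variance at every skip, so deep towers
  start with wildly inflated outputs. Skip-layer weights are therefore
  initialized at a quarter of the He scale, which keeps initial activation
  variance bounded at any depth. In our small-scale experiments residual
  and plain towers then train comparably — consistent with residuals being
  an optimization convenience whose benefit ("occasionally improves
  validation loss") is regime-dependent — so the test suite asserts
  correct gradient propagation through skips and stable deep-tower
  training rather than a residual-vs-plain race.
* **Slot symmetry and interaction features.** Ordered concatenation of
  the two drug encodings is *not* order-invariant even with a shared
  encoder. Plain ordered concatenation remains the default forward pass,
  and inference averages the two slot orderings
  (`slot_average = TRUE`), which is symmetric by construction.
  `symmetrize = "sum"` instead merges the encodings by elementwise sum
  before the tower, making a single pass order-invariant;
  `"sum_prod"` adds their elementwise product, a ready-made
  pair-conjunction feature; and `"interact"` further adds products of the
  pooled cell encoding with the drug sum. The product blocks reflect the
  multiplicative structure of combination response — expected pair growth
  is a product of single-agent growths, each itself a cell-by-drug
  interaction — and in our experiments they substantially improve how
  well pair-specific synergy learned on some cell lines transfers to
  held-out (cell, pair) measurements.

Training (`train_growth_model()`) is minibatch Adam on MSE with optional
linear learning-rate warm-up and reduce-on-plateau decay; runs are
repeatable from the build and training seeds under single-threaded
deterministic execution.

## Evaluation

Every (cell, drug A, drug B) measurement is treated as an independent data
point. `stratified_kfold()` bins the continuous targets into 5 classes and
deals each bin round-robin across folds, so per-fold class counts match the
global counts within one sample. "Binned evenly" is read as equal-width
intervals over the observed range by default, with an equal-frequency
option — either satisfies the proportion-preservation goal. Blocked
splitting by cell line or drug is deliberately out of the default path:
the row-level split answers "can the model interpolate the screen", not
"can it extrapolate to new drugs", and the latter needs a different scheme.

`compute_metrics()` reports MSE, MAE, $R^2 = 1 - SS_{res}/SS_{tot}$
(negative allowed), and Pearson/Spearman correlations.
`random_pair_baseline()` establishes the chance floor by predicting each
sampled target with an independent draw from the same empirical
distribution; its expected $R^2$ is −1 for *any* non-degenerate
distribution, because the expected squared difference of two independent
draws is twice the variance. `cross_validate()` trains one model per fold
and pools out-of-fold predictions, each row predicted exactly once.

## Ranking and error views

`top_k_pairs()` ranks a cell line's pairs by ascending BestComboScore
(most negative — strongest enhancement — first), with deterministic
lexicographic tie-breaks; ordered duplicates collapse to the unordered key
by default. `top_list_difference()` counts true-list members missing from
a predicted list; `pooled_frequency_ranking()` pools per-cell top lists
and ranks pairs by how many cell lines carry them. Predicted top lists are
built by recomputing BestComboScore from *predicted* single and pair
growths, exactly as the true lists are built from measured ones.
`per_cell_error_summary()` and `pair_error_matrix()` flatten out-of-fold
errors along the cell-line axis and onto the drug-pair plane (diagonal =
single agents), and `cluster_order()` orders drugs by average-linkage
hierarchical clustering under correlation distance (undefined correlations
from constant rows default to distance 1).

## The synthetic screen

Real combination screens are large and access-controlled; the package
ships a seeded generator (`simulate_screen()`) so every claim above is
testable end to end. Latent cell factors (dim 3) project to three omics
assays (widths 40/20/30) with assay noise; latent drug factors project to
60 descriptors with heterogeneous column scales, 15% of columns masked to
≥ 90% missing and a 2% background missing rate. Per (cell, drug), a
potency in (0, 1) — a logistic transform of the latent interaction, biased
low so the growth marginal is skewed toward nonresponse — drives a
monotone-decreasing dose curve; single agents are measured at 3 or 5
concentrations, pairs on 3×3 or 5×3 grids. The pair base response is the
multiplicative truncated-product expectation of the single-agent responses
at the corresponding dose fractions, so non-synergistic pairs have
BestComboScore ≈ 0 by construction; 10% of pairs receive a planted synergy
offset reaching −0.35 growth fraction at full dose (true score −35).
Gaussian measurement noise (sd 0.05) is added, values are floored at −1,
and noise can push values slightly above 1, exercising the cap. 2% of
records are flagged as failing QC.

Default panel sizes are 20 cell lines × 15 drugs (2 400 tuples, ~25 000
dosed records) — large enough for the network to learn the response
surface, small enough that the full test suite runs in minutes on one CPU.
What the generator does **not** emulate: real pharmacology (no dose–response
curve shapes beyond monotone linear-in-fraction decay), correlated assay
structure, batch effects, or the heavy-tailed score distribution of real
screens. Passing tests therefore demonstrate that the machinery is correct
and that the architecture can recover a known multiplicative-with-synergy
response surface — not that it attains any particular accuracy on real
screen data, which additionally needs orders of magnitude more data and
wider layers.

## Problem sizes and configurations used in the checks

Two model configurations are exercised. A scaled-down configuration
(encoders 64–64, tower 64–64–64, 50 epochs) verifies parameter recovery:
held-out $R^2 \ge 0.8$ on the default screen. The virtual-screening
configuration (160-wide encoders and tower, `symmetrize = "interact"`,
plain 3-layer tower, 120 epochs, batch 64, plateau-halving learning rate
from 2·10⁻³, and a 2-model bag per cross-validation fold) is
cross-validated 5-fold; its pooled out-of-fold predictions drive the
planted-pair recovery check (≥ 80% of planted pairs per cell line
re-identified in the predicted top-K). The wider interaction
configuration exists because memorizing pair-specific synergy across
cell lines is a much harder task than fitting the smooth response
surface: at width 64 with ordered concatenation the model captures only
about half of the planted offset out-of-fold, while width and explicit
product features progressively close the gap, and bagging two
independently seeded models per fold cancels much of the remaining
seed-to-seed prediction variance that otherwise scrambles top-K
rankings. For calibration, an oracle that reproduced the *measured*
screen exactly would itself recover only about 90% of the planted pairs
(measurement noise moves the observed top lists), so the bar sits close
to what the data support. Full-scale guidance (≥ 1000-neuron layers,
≥ 100 epochs, all assays plus descriptors) remains reachable through the
same configuration objects.

## Known limitations

* The network is plain dense matrix arithmetic in R; it is adequate for
  the bundled screen sizes but not for 10⁵-row screens with 10⁴-wide
  inputs, which want GPU-backed frameworks.
* Mean imputation and min–max scaling are the conventions of the modeled
  workflow, not the best available missing-data treatment.
* The additivity reference is the modified best-dose expectation only; the
  original summed-over-doses combination score is out of scope.
* Uncertainty on rankings (e.g. bootstrap stability of top-K lists) is not
  quantified.
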