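---
title: "Temporal link prediction for contact networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal link prediction for contact networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contactpred)
```

## The problem

A contact stream records undirected pairwise interaction events
`(t, i, j)` — typically face-to-face proximity detections at a social
gathering, sampled every few tens of seconds. Link prediction on such a
stream asks: among the node pairs that have *never* interacted up to a
prediction time `t1`, which will interact in the testing window
`[t1, t2)`? The question matters both for applications (contact
recommendation, epidemic forecasting) and for understanding how such
networks grow.

`contactpred` treats this as a scored-ranking problem. The pipeline is

1. aggregate the training contacts into a weighted undirected graph,
2. score every candidate pair with a neighborhood statistic,
3. label candidates by their testing-window contact count, and
4. evaluate the ranking (PR curves, AUC, DeLong paired comparisons).

All four stages are exposed as separate functions
(`build_graph()`, `score_candidates()`, `label_candidates()`,
`roc_auc()`, ...); `link_prediction()` runs them end to end and returns a
classed object with `print`/`summary`/`coef`/`predict`/`plot` methods.

## Aggregation and the decaying-weight schemes

The training window is half-open, `[t0, t1)`, and so is the testing
window `[t1, t2)`: an event exactly at `t1` belongs to testing. This
convention is applied everywhere (including the activity histogram bins),
so no event is ever counted twice. Events are stored sorted by
`(timestamp, canonical pair)`; the lexicographic tie-break makes the
global contact index — and therefore the decayed weights below — a pure
function of the data, independent of input row order.

Under flat weighting, `w(i,j)` is the number of training contacts of the
pair. The decaying schemes index all selected training contacts
`c_1, …, c_n` in this global order and let contact `c_k` add

* linear: `k / n`,
* exponential: `γ^(n−k)`, `γ = ε^(1/n)`,

to its pair's weight. Both are normalized so that the newest contact
contributes exactly 1; the oldest contributes `1/n` (linear) or
`γ^(n−1) → ε` (exponential). The decay floor `ε` defaults to 0.01: the
oldest information in a window is then worth about 1% of the newest,
which is aggressive enough to matter on drifting data while keeping every
contact's contribution strictly positive. As `ε → 1` the exponential
scheme degenerates to flat weighting (this is a tested property). Note
that the index `k` runs over *all* training contacts, not per pair: a
pair's weight depends on when its contacts fall within the global
activity sequence, which is what lets a window with bursty activity decay
by information content rather than wall-clock time. Windows can also be
specified by contact count (`by_contact_count`), taking the last `n`
events before `t1`.

Decay acts on edge *weights* only; it cannot remove an edge from the
graph, so a stale contact still contributes its endpoints to
common-neighbor sets. Weighted scores therefore benefit from decay in
proportion to how much of their signal flows through the weights — this
is visible in the drifting experiments below, where exponential decay
recovers most, but not all, of an optimally truncated window.

## The ten predictors

The scores and their formulas are listed in `?lp_methods`. Design
choices worth recording:

* **α placement.** The weight-contribution exponent is applied to each
  raw weight, and node strengths are sums of α-powered weights,
  `s_α(z) = Σ w(z,u)^α`. This makes the endpoints of the parameter range
  exact: at `α = 0` every weight collapses to 1, so WCN = 2·CN,
  WPA = PA, WRA = 2·RA, and WJC is a strictly increasing transform of JC
  — all four rank candidates identically to their unweighted
  counterparts (a tested invariant). At `α = 1` the raw aggregated
  weights are used as-is.
* **Logarithms** are natural throughout. A common neighbor necessarily
  has degree ≥ 2, so `log|Γ(z)|` in AA is never zero; WAA uses
  `log(1 + s_α(z))`, safe for any positive strength. WAA at `α = 0` is
  therefore a near- (not exact) rank equivalent of AA.
* **Degenerate pairs.** An empty common neighborhood scores 0 for all
  O-summing methods; an isolated endpoint scores 0 for PA/WPA and (by
  the 0/0 → 0 convention) JC/WJC. Score tables are thus total over any
  candidate set.
* **JC denominator** is the plain union `|Γ(x) ∪ Γ(y)|`, the standard
  definition, with no special handling when `x` and `y` are themselves
  neighbors of the other (candidates are non-adjacent anyway).

All ten scores are verified exactly against an independent set-arithmetic
oracle on every graph with up to six nodes (via the graph atlas) with
random weights and α.

## Evaluation

A candidate is positive when its testing-window contact count is ≥ `S`
(default `S = 1`, plain new-link prediction; larger `S` targets strong
ties). The predicted-positive rule is `score ≥ T`. AUC is computed as the
Mann–Whitney rank statistic with ties counting ½, which equals the
trapezoidal area under the empirical ROC — the package computes the
former and the test suite checks agreement with an independent
trapezoidal implementation to 1e-10.

The DeLong test compares two predictors on the *same* candidates and
labels (a paired design). Per-observation placement values are computed
via midranks; the variance of the AUC difference is assembled from their
covariances, `z = ΔAUC/√var`, and the p value is two-sided normal. The
implementation is cross-checked in the tests against `pROC::roc.test`
and against a 2000-replicate paired bootstrap. Zero variance with zero
difference (e.g. self-comparison) yields `p = 1`; zero variance with a
nonzero difference yields `p = 0` with a warning. No multiple-testing
correction is applied to the pairwise matrices; consumers sweeping many
methods should correct downstream.

`flat_optimal` in `compare_weighting()` deserves a caveat: the training
start maximizing AUC is selected on the same testing window it is then
reported on — an in-sample selection. This mirrors how a tuned training
length is found in practice when one historical split is available, and
it makes `flat_optimal` an optimistic baseline by construction.

## The synthetic generator

`generate_stream()` draws each pair's contacts from an inhomogeneous,
history-dependent Poisson process with rate

```
base_rate × schedule(t) × community factor × hub factors
          × (1 + closure_boost · [recent common neighbor])
```

sampled exactly by thinning at the per-segment maximal rate. It emulates
the features of conference proximity data that matter for link
prediction: bursty activity (three 12-hour busy blocks separated by
near-silent nights, `quiet_mult = 0.05`), community structure
(`community_ratio`, default 10), a heavy-tailed degree distribution (a
small hub fraction with multiplied rates), triadic closure (pairs with a
common neighbor active in the last hour interact at `1 + closure_boost`
times the base rate — this is what makes common-neighbor scores
informative), and affinity drift (at `drift_time`, a fraction
`drift_fraction` of nodes have their community memberships permuted).
`drift_fraction` defaults to 0.5: real gatherings reshuffle gradually,
and a partial reshuffle both preserves some long-run structure and is
the regime where recency weighting is informative rather than merely a
window substitute.

The generator does **not** emulate spatial mobility, the 20-second
detection grid, repeated-detection autocorrelation within a single
conversation, or calibrated SocioPatterns statistics. Consequently,
passing planted-effect tests shows that the estimators *recover effects
that are present by construction*; it does not certify accuracy levels
on real proximity data, where effect sizes may differ.

`planted_fixture()` freezes four study conditions on a 120-node,
4-community, 60-hour stream (~5–10k events, training `[0, 48 h)`,
testing `[48 h, 60 h)`):

* `stationary` — control; the AUC-vs-training-length curve is flat
  within ±0.03.
* `drifting` — 40% of memberships permuted at 30 h; exponential decay
  beats flat-full weighting and lands within 0.03 AUC of the in-sample
  optimal flat window.
* `noisy_weights` — repeat-contact multiplicities are permuted among
  the pairs contacted before `t1` (topology and all post-`t1` events
  unchanged), so weights carry no information: WCN at `α = 0` matches or
  beats `α = 1`.
* `strong_tie_signal` — community-driven contacts intensify in the
  testing block while 300 one-off contacts on random never-met pairs are
  added there: `S = 4` positives are predictable (AUC ≈ 0.9) while
  `S = 1` is polluted (AUC ≈ 0.55).

These sizes keep the full 20-seed planted-effect battery at roughly one
to two minutes, while candidate sets (~5,000 pairs) are large enough for
the DeLong comparisons to resolve AUC differences of a few hundredths.

## Numerical and interface conventions

* Node identifiers are opaque strings; pairs are stored with endpoints
  in lexicographic order (C-locale radix sort), which fixes all
  tie-breaks deterministically.
* Timestamps are taken as given (seconds from onset); duplicate events
  at the same instant are kept as distinct contacts, and repeated
  detections are not collapsed — on sensor data every detection interval
  is evidence of ongoing interaction.
* Precision and recall report 0 with an explicit `*_defined = FALSE`
  flag on a 0/0; sweep cells with no positives (or no training contacts)
  are reported as `NA`, never dropped.
* Edge lists and score tables are written as plain whitespace/TSV text
  with ≥ 10 significant digits, so write → read round-trips are exact
  for integer weights and within 1e-9 relative otherwise.
* `generate_stream()` seeds its own RNG stream from `config$seed` and
  restores the caller's RNG state, so simulations are reproducible
  without side effects.

## Known limitations

* Predictors are neighborhood-based only; path-based (Katz), random-walk
  and supervised predictors are out of scope.
* Graphs are undirected and single-layer; event direction in the CSV
  dialect is discarded.
* The DeLong normal approximation is unreliable with very few positives
  (the variance estimate needs at least two observations per class; AUCs
  near 1 with a handful of positives give conservative p values).
* `flat_optimal` is in-sample, as noted above, and should be read as an
  upper reference, not an achievable predictor.
* The average shortest-path statistic is computed on the largest
  connected component only and ignores weights.
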