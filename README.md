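# contactpred

Link prediction for temporal contact networks in R.

Proximity sensors (conference badges, RFID tags, phones) produce *contact
streams*: long sequences of timestamped pairwise interaction events. A
natural question for such data is which pairs of people who have **not**
yet met will interact in the near future — the link-prediction problem,
posed on a graph aggregated from a training window of the stream.
`contactpred` implements the full workflow for this setting: windowed
aggregation with time-decayed contact weights, ten classic
neighborhood-based prediction scores, and a rank-based evaluation protocol
(precision/recall, ROC/AUC, and the DeLong paired test for correlated
AUCs), together with a synthetic contact-stream generator so that every
experiment runs offline and reproducibly.

## The model

From the contacts in a training window `[t0, t1)` an undirected weighted
graph *G* is built. Under **flat** weighting the weight *w(i,j)* is the
number of contacts between *i* and *j*. Because face-to-face interaction
has strong spatiotemporal locality — who you met *recently* predicts who
you will meet next far better than who you met days ago — the package also
implements two **decaying-weight** aggregations. With the training
contacts indexed `c_1, …, c_n` in time order, contact `c_k` increments its
pair's weight by

* linear: `k / n`
* exponential: `γ^(n−k)` with `γ = ε^(1/n)` (default `ε = 0.01`),

so the newest contact always contributes 1 and older contacts decay toward
`ε`.

For every *candidate pair* (no contact at any time before `t1`) a score
`l_ij` is computed. With `Γ(x)` the neighbor set, `O = Γ(x) ∩ Γ(y)`, and
the α-strength `s_α(z) = Σ_{u∈Γ(z)} w(z,u)^α`:

| method | score |
|---|---|
| CN  | `|O|` |
| AA  | `Σ_{z∈O} 1/log|Γ(z)|` |
| PA  | `|Γ(x)|·|Γ(y)|` |
| JC  | `|O| / |Γ(x) ∪ Γ(y)|` |
| RA  | `Σ_{z∈O} 1/|Γ(z)|` |
| WCN | `Σ_{z∈O} (w(x,z)^α + w(z,y)^α)` |
| WAA | `Σ_{z∈O} (w(x,z)^α + w(z,y)^α) / log(1 + s_α(z))` |
| WPA | `s_α(x) · s_α(y)` |
| WJC | `Σ_{z∈O} (w(x,z)^α + w(z,y)^α) / (s_α(x) + s_α(y))` |
| WRA | `Σ_{z∈O} (w(x,z)^α + w(z,y)^α) / s_α(z)` |

The exponent `α ∈ [0,1]` controls how much the link weights contribute:
`α = 0` ignores them (the weighted scores then rank exactly like their
unweighted counterparts), `α = 1` uses raw contact counts.

A candidate is a true positive when it accumulates at least `S` contacts
in the testing window `[t1, t2)`; `S = 1` is plain new-link prediction,
larger `S` restricts the target to strong ties. Scores are evaluated by
precision `TP/(TP+FP)` and recall `TP/(TP+FN)` at a threshold, by the full
PR curve, and by the AUC computed as the Mann–Whitney rank statistic
(probability that a random positive outscores a random negative, ties
counting ½). Two predictors evaluated on the same candidates are compared
with the DeLong paired test.

## Worked example

```r
library(contactpred)

fx  <- planted_fixture("stationary", seed = 42)   # synthetic conference
fx$stream
#> <contact_stream> 6871 events among 120 nodes, time span [18.7, 215990] s

fit <- link_prediction(fx$stream, t1 = fx$t1, t2 = fx$t2, method = "RA")
summary(fit)
#> <link_prediction> RA
#>   training window [0, 172800) s, flat weighting
#>   5041 candidates, 545 positives (S = 1)
#>   AUC = 0.7012
#>   best-F1 operating point: threshold 0.3715, precision 0.381, recall 0.475

cmp <- run_method_comparison(fx$stream, fx$t1, fx$t2,
                             methods = c("CN", "RA", "PA", "WCN"))
cmp
#> <lp_comparison> 4 methods, 5041 candidates, 545 positives
#>  method       auc
#>      CN 0.7038083
#>      RA 0.7012086
#>     WCN 0.6922759
#>      PA 0.5378167
```

Here resource allocation and common neighbors clearly beat chance
(AUC ≈ 0.70 vs 0.5): the generator plants community structure and triadic
closure, so sharing many low-degree neighbors is genuinely predictive.
Preferential attachment trails because hubs are few. The DeLong matrix
(`cmp$delong_p`) confirms that the PA deficit is significant while CN vs
RA is not. Real proximity streams are read with
`read_contact_stream(path, "sociopatterns_tsv")` (no header,
`timestamp id_a id_b` rows) or `"event_csv"`
(`timestamp,source,target`), and the same functions apply unchanged.

A thin command-line front end over these functions is installed at
`inst/cli/contactpred.R` (subcommands `predict`, `evaluate`,
`sweep-alpha`, `sweep-s`, `sweep-window`, `compare-weighting`, `stats`,
`synth`).

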