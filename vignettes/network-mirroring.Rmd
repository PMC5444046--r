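---
title: "Network mirroring: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network mirroring: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netmirror)
```

## The model

Drug repositioning asks which approved drugs could treat additional
diseases. netmirror operationalises one disease-based answer: *if two
diseases are molecularly similar, a drug used for one is a candidate for
the other* — and the most promising diseases to target are those whose
current treatments do **not** yet reflect their molecular similarity to
other diseases.

Two weighted, undirected disease networks are built over one disease set
$D$ (only diseases with at least one protein and at least one drug
association are kept, so every profile is non-empty):

* **PrDN**, the protein-based disease network: edge weights are Tanimoto
  similarities of binary disease–protein profiles,
  $w_{ij} = \frac{\sum_k D_{ik} D_{jk}}
                 {\sum_k D_{ik} + \sum_k D_{jk} - \sum_k D_{ik} D_{jk}}.$
  PrDN expresses repositioning *potential*.
* **DrDN**, the drug-based disease network: the same similarity on binary
  disease–drug profiles. DrDN expresses the treatment *status quo*. When a
  drug–protein table is available the disease–drug associations are
  derived through shared target proteins (boolean matrix product) and, by
  default, unioned with directly curated pairs.

Each disease's weight row is turned into a probability distribution over
the other diseases with an exponential transform,
$p_{ij} = e^{w_{ij}} / \sum_{k \ne i} e^{w_{ik}}$. Because $e^0 = 1$,
absent edges still carry positive probability; this is what keeps the
divergence below finite on sparse networks and must not be replaced by
plain weight normalisation. A disease is then scored by the
Kullback–Leibler divergence of its PrDN distribution $p_i$ from its DrDN
distribution $q_i$ (in nats, this direction only — KL is asymmetric and
PrDN is the reference of potential):
$\mathrm{KL}_i = \sum_{j \ne i} p_{ij} \ln (p_{ij}/q_{ij}) \ge 0$,
zero exactly when the two neighbourhoods agree. The top $\sigma\%$ of
diseases by $\mathrm{KL}_i$ become repositioning candidates, and the
ranking is divided into quintile tiers (tier 1 = top 20%) for evaluation.

For each candidate, similar diseases are found on PrDN with graph-based
semi-supervised learning: the candidate is labeled 1, all others 0, and
the smoothed scores solve $(I + \mu L)f = y$ with $L$ the combinatorial
graph Laplacian — the minimiser of $\sum_i (f_i - y_i)^2 + \mu f^T L f$.
Scores lie in $[0,1]$, the labeled disease attains the maximum, stronger
connection paths give higher scores, and disconnected components score 0.
The top $\delta\%$ of unlabeled diseases are the similar diseases, and
the union of their drug profiles is proposed for the candidate
($Dr_i^C = \bigcup_j \mathrm{Drug}(D_j)$). Drugs already used by the
candidate are kept and flagged `known_covered`; the rest are
`novel_drugs`.

## Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `sigma` | % of diseases kept as candidates | 20 | quintile convention; tiers are 20% blocks |
| `delta` | % of unlabeled diseases kept as similar | 20 | no principled universal value exists; at $N = 200$ we evaluate with 1.5 (three similar diseases, matching the scale at which a handful of close neighbours is meaningful) |
| `mu` | SSL regularisation strength | 1 | larger values diffuse the label further; the $\mu \to 0$ limit returns the label vector |
| `n_tiers` | evaluation tiers | 5 | tier sizes differ by at most one; the first `N %% 5` tiers take the extra member |

## Numerical and convention choices

* **Self-weights are 0.** The divergence compares connections to *other*
  diseases; a self-similarity of 1 would dominate the exponential
  normalisation. The comparison set excludes the disease itself
  (`include_self = FALSE`), consistently in both networks.
* **All-zero against all-zero profiles have similarity 0** (no shared
  evidence), and an isolated disease's probability row is exactly uniform.
* **Tie-breaks are deterministic everywhere**: descending score, then
  ascending disease id, with C-locale radix ordering. Two runs with the
  same inputs produce byte-identical outputs; the only randomness in the
  package lives in the synthetic generator and the fold shuffles, both
  seeded.
* **SSL solves** use one Cholesky factorisation of $I + \mu L$ (symmetric
  positive definite by construction) shared across all candidate labels; a
  normalized-Laplacian variant is available via `laplacian = "normalized"`.
* **Counts**: candidate and similar-disease selections take
  `ceiling(pct/100 * N)` members; `select_similar_diseases()` applies the
  percentage to the $N-1$ unlabeled diseases.

## The cross-validation design

`cross_validate()` repeats $k$-fold cross-validation over the
disease–drug association *pairs* (seeded shuffle, near-equal folds). Tier
membership comes from the full data's KL ranking so a disease's tier is
stable across folds, and the SSL similar sets depend only on PrDN, which
folding never touches; per fold, only the drug profiles are rebuilt from
training pairs before predictions are scored. Diseases that lose every
drug in a training fold stay in the disease set with an empty training
profile (removing them would break the shared node set of the two
networks) and are counted in `n_dropped_disease_folds`.

The prediction universe per disease is the full drug index. A predicted
drug that is a known association (training **or** held-out) is a true
positive — covering an existing treatment counts as success, the same
accounting used when repositioned drugs are compared against a disease's
existing pharmacopoeia; held-out drugs not predicted are false negatives;
predicted drugs never associated are false positives. Metrics are
macro-averaged over the diseases of a tier, then over folds and repeats
(`average = "micro"` pools counts instead). The greedy reference
experiment treats every disease as a candidate ($\sigma = 100$) and
reports the same aggregate over all diseases.

## What the synthetic generator emulates

`generate_tripartite()` produces the tripartite structure the method
needs, at desk scale (200 diseases x 1000 proteins x 100 drugs by
default):

* **Modules.** Diseases form 10 modules sharing a protein block; each drug
  targets proteins of one block. This gives PrDN community structure for
  the SSL stage to exploit — the method's premise is that molecularly
  similar diseases can share drugs, so the generator must contain such
  neighbourhoods.
* **Heterogeneous coherence.** Each disease draws a module coherence
  $c \in (0.05, 1)$: the fraction of its protein picks falling inside its
  own block (the rest scatter as background). Coherence emulates how well
  a disease is molecularly characterised. It drives both the
  informativeness of the disease's PrDN neighbourhood (hence its KL score,
  through the gap between its peaked protein distribution and its flatter
  drug distribution) and the quality of its predictions — which is what
  produces the tiered F-measure gradient on synthetic data.
* **Protein-consistent treatments.** Observed disease–drug pairs are a
  thinned sample of the protein-consistent pairs (disease and drug sharing
  a protein), with the keep probability scaled so expected treatment
  counts do not grow with annotation breadth (default coverage 0.8 of the
  module drug pool). High coverage keeps within-module drug overlap
  stable; with sparse treatment rows, the Tanimoto similarity of small
  drug sets is so variable that per-disease alignment noise, not signal,
  dominates the divergence ranking.
* **The planted signal.** `n_planted` diseases (20 by default) draw
  coherence from the top band of the range — well-characterised, but not
  uniformly the strongest hubs, which would make them every module-mate's
  top SSL pick — and have `decouple_frac` (0.55) of their drugs removed;
  half the removed count is replaced by drugs of one donor module
  (`permute_neighbors`) or at random (`resample`). A planted disease is
  thus under-treated relative to its protein profile *and* its drug-side
  neighbours point to the wrong module: exactly the mirror-divergence the
  method is built to detect. The removed protein-consistent pairs are
  returned as `withheld_true_pairs`.

What passing the synthetic checks does **not** show: real association
data have heavy-tailed degree distributions, cross-vocabulary noise,
correlated curation (the same literature feeding several databases), and
much larger, sparser universes (thousands of diseases and proteins).
The generator makes no attempt to match those; results on it validate the
machinery and the qualitative behaviour of the ranking, not clinical
performance.

## Problem sizes used by the checks

The packaged checks run the prioritisation on ten generated instances
(200 diseases each) for the planted-recovery rate, and the full 10-fold,
3-repeat cross-validation on sixteen instances, averaging the per-tier
F-measures across instances before comparing tier 1, the greedy
reference, and tier 5 — single instances at this scale have instance-level
variance of a few hundredths in F, so the comparison is made on the
simulation mean, as one would in any simulation study.

## Known limitations

* The exact semi-supervised variant (combinatorial vs. normalized
  Laplacian, unclamped labels) is a documented modelling choice; both
  Laplacians are provided, combinatorial is the default and the one whose
  $[0,1]$ score bound is exact.
* `delta` has no data-driven default; it remains a user parameter.
* KL scores are reported in nats and depend on $N$; they are comparable
  within one run, not across disease sets of different size.
* Whether directly curated disease–drug pairs should be unioned with the
  protein-derived ones or replace them is not determinable from first
  principles; union is the default (`--merge-direct`), replacement is a
  flag away.
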