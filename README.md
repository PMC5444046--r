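# netmirror

Network mirroring for drug repositioning: find diseases whose *treatment
status quo* lags behind their *molecular similarity* to other diseases,
and propose the drugs of their molecular neighbours.

## The problem and the method

Developing a drug de novo takes a decade and hundreds of millions of
dollars; repositioning an already-approved drug onto a new disease is far
cheaper — if one knows where to look. netmirror implements a
disease-based, network-based screen for such opportunities.

Two weighted disease networks are built over the same disease set, from
three binary association tables (disease–protein, disease–drug,
drug–protein):

- **PrDN** (protein-based disease network): edges weight the Tanimoto
  similarity of disease–protein profiles,
  `w_ij = |P_i ∩ P_j| / |P_i ∪ P_j|` — molecular similarity, the
  repositioning *potential*;
- **DrDN** (drug-based disease network): the same similarity on
  disease–drug profiles — the treatment *status quo*. Disease–drug links
  can be derived through shared target proteins and merged with curated
  pairs.

Each disease's weight row is converted to a probability distribution by an
exponential transform (`p_ij = exp(w_ij) / Σ_k exp(w_ik)`, keeping every
entry positive on sparse networks), and the disease is scored by the
Kullback–Leibler divergence of its PrDN distribution from its DrDN
distribution, `KL_i = Σ_j p_ij ln(p_ij / q_ij)`. A large `KL_i` means the
disease's molecular neighbours are not the diseases it shares drugs with —
a repositioning opportunity. The top σ% by KL become candidates. For each
candidate, graph-based semi-supervised learning on PrDN
(`f = (I + μL)^(-1) y`, one-hot label on the candidate) scores all other
diseases; the top δ% are its similar diseases, and the union of their drug
sets is proposed for the candidate. Predictions are validated by repeated
k-fold cross-validation over disease–drug pairs, with F-measure reported
per KL-ranking quintile (tier 1 = top 20%) against a greedy all-diseases
reference.

## Worked example

```r
library(netmirror)

# synthetic tripartite instance: 200 diseases, 10 modules, 20 diseases
# whose drug profile is decoupled from their protein profile
g <- generate_tripartite(synthetic_spec(seed = 1))

run <- run_network_mirroring(g$disease_protein, g$disease_drug,
                             sigma = 20, delta = 1.5, mu = 1)
run
#> <network_mirroring> 200 diseases, 40 candidates (sigma = 20, delta = 1.5, mu = 1)
head(run$ranking, 3)
#>   disease          kl rank tier is_candidate
#> 1   D0154 0.004196061    1    1         TRUE
#> 2   D0068 0.004150902    2    1         TRUE
#> 3   D0167 0.004034174    3    1         TRUE
run$results[[1]]
#> <repositioning_result> D0154 (KL = 0.004196, rank 1): 3 similar disease(s), 14 candidate drug(s) (13 novel)
run$results[[1]]$similar_diseases
#>      D0151      D0147      D0144
#> 0.01218666 0.01177195 0.01049987
```

The ranking orders diseases by divergence between their two networks;
`D0154` tops it, its three strongest PrDN neighbours by SSL score are
`D0151`, `D0147`, `D0144`, and the 14 drugs those neighbours use are
proposed for `D0154` (13 of them not among its current drugs, one already
covered). The planted signal is found:

```r
planted_recovery_rate(g, sigma = 20)
#> [1] 0.85

cross_validate(g$disease_protein, g$disease_drug, k = 10, repeats = 1,
               sigma = 20, delta = 1.5, mu = 1, seed = 17)
#> <evaluation_report> 1x10-fold CV (macro average)
#>  tier precision    recall f_measure n_diseases
#>     1 0.2010945 0.8686528 0.3011620         40
#>     2 0.2200545 0.7843621 0.3267706         40
#>     3 0.1414732 0.7460744 0.2278298         40
#>     4 0.1736680 0.7775228 0.2741758         40
#>     5 0.1352181 0.7201369 0.2221902         40
#> overall (greedy reference): F = 0.2704
```

85% of the planted diseases land in the top-20% candidates, and
cross-validated F-measure is highest in the top KL tiers: prioritising by
network divergence beats greedily repositioning onto every disease
(tier 1 F 0.30 vs 0.27 overall vs 0.22 in tier 5 on this single instance;
the packaged checks average such runs over many instances).

## Command line

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/netmirror.R simulate --out data/ --seed 1
Rscript inst/cli/netmirror.R run --disease-protein data/disease_protein.tsv \
    --disease-drug data/disease_drug.tsv --drug-protein data/drug_protein.tsv \
    --sigma 20 --delta 1.5 --mu 1.0 --out results/
Rscript inst/cli/netmirror.R evaluate --disease-protein data/disease_protein.tsv \
    --disease-drug data/disease_drug.tsv --k 10 --repeats 10 --seed 17 --out eval/
```

Inputs are two-column tab-separated edge lists (`#`-prefixed lines are
comments). `run` writes `ranking.tsv`, `fscores.tsv`,
`repositioning.json` and a JSON manifest; `evaluate` writes `report.json`
and a per-tier TSV.

## Scope

The package ships no harvested database content and no identifier
normalisation across vocabularies (MeSH, OMIM, DrugBank, ...); ids are
opaque strings. The synthetic generator (see the methods vignette,
`vignettes/network-mirroring.Rmd`) emulates modular tripartite structure
with a planted, controllable repositioning signal — it validates the
machinery, not clinical performance.
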