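# ppfil

Privacy-preserving federated incremental learning for clinical-style
tabular data, with a hash-chained model ledger — as a fully synthetic,
single-machine simulator.

## The problem

Hospitals and devices holding small clinical tables (blood pressure,
cholesterol, coded symptoms, a binary disease label) want to train a shared
classifier without pooling raw records, while new data keeps arriving as
*tasks* (new label groups or shifted populations), storage for old samples
is bounded, some participants may submit corrupted labels or poisoned
parameter updates, and every accepted model version must be auditable.
`ppfil` implements the full pipeline such a deployment needs and makes
every stage testable on synthetic data — no downloads, no GPU, no network.

## What is inside

| Stage | Method |
|---|---|
| Normalization | per-feature min-max `x' = (x - min)/(max - min)`, fit on train only, clipped elsewhere |
| Feature selection | chaotic bobcat optimisation (CBOA): population of 30 positions in `[0,1]^m`, logistic-map initialization, prey-directed exploration, decaying pursuit moves, greedy acceptance; fitness `J = (1 - CV acc) + alpha |S|/m`, minimized |
| Federated incremental core | per-client personalized informative model `v <- v - eta(sum grad + q(lambda)(v - w))`, `q(lambda) = (1-lambda)/(2 lambda)`; replay caches keep the top-M samples by accumulated gradient-norm importance `I = sum_p G^p / p`; local training E=5 epochs, B=64, eta=1e-3, momentum 0.9 |
| Privacy | update clipping + Gaussian local noise (`sd = multiplier x clip`) or randomized response; levels 1–5 map to multipliers 0.25–4 |
| Robust aggregation | median/MAD distance filter (iterated, with a relative floor), then weighted averaging `M = sum W_k (M_k + delta_k) / sum W_k` with accuracy-times-attribution-alignment weights |
| Ledger | SHA-256 over canonical key-sorted JSON, hash-chained blocks carrying model digests, accuracy-gated admission, proof-of-contribution scoring |
| Final classifier | entropy deep belief network: stacked CD-1 RBMs with widths constrained to `ceil(H) <= width <= visible count`, unrolled and fine-tuned with a softmax head |
| Threat models | extra noise, label flipping, static/adaptive model poisoning, Sybil, collusion |

## Worked example

```r
library(ppfil)

cfg <- experiment_config(use_cboa = TRUE, use_edbn = TRUE)
rep <- run_experiment(cfg, seed = 42)
rep
#> <experiment_report> accuracy 95.00% (precision 90.91%, recall 100.00%, F 95.24%)
#>   global linear model: 86.67% | ledger: 201 blocks | features: 4/12

head(rep$trace, 3)
#>   round task val_accuracy admitted aborted n_kept n_excluded
#> 1     1    1          0.5     TRUE   FALSE     10          0
#> 2     2    1          0.5     TRUE   FALSE     10          0
#> 3     3    1          0.5     TRUE   FALSE     10          0

validate_chain(rep$ledger)$valid
#> [1] TRUE
```

What the numbers mean: a synthetic 600-sample cohort (12 features, 4 of
them informative) is split 80/20; CBOA recovered exactly the 4 informative
features; ten clients ran 200 federated rounds, each round's aggregate
admitted to the ledger only when its server-validation accuracy did not
regress by more than one percentage point (all 200 admitted here, plus the
genesis block); the entropy-DBN trained on the selected features reaches
95.0% test accuracy, against 86.7% for the aggregated linear federated
model itself (the linear learner converges slowly at the clinical-default
learning rate).

The attack and privacy layers are one flag away:

```r
rep <- run_experiment(experiment_config(
  privacy = privacy_config(multiplier = 1, clip = 0.5),
  attack  = attack_config("label_flip", fraction = 0.2)), seed = 42)
```

A thin command-line front end for shell use lives at `inst/cli/ppfil.R`
(`run`, `cboa`, `privacy-sweep`, `attack-sweep` subcommands).

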