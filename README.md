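# pancox

Pan-cancer versus single-cancer prognostic survival modeling on
left-truncated clinico-genomic cohorts.

## The problem

Clinico-genomic registries link electronic-health-record survival data to
tumor panel sequencing across many cancer types. They pose two questions
this package addresses end to end:

1. **Methodological** — patients enter such a registry only when their
   tumor is sequenced, typically months after first-line (1L) therapy
   begins. With survival measured from 1L start, the data are
   *left-truncated*: patients who die before sequencing are never
   observed, and naive analyses are biased toward long survivors.
2. **Scientific** — does one *pan-cancer* model, trained on all cohorts
   pooled with cancer-type covariates, predict survival better than
   separate single-cancer models — especially for small cohorts, where a
   transfer-learning advantage is plausible?

Because the motivating registry data are proprietary, `pancox` ships a
synthetic cohort generator with the same statistical structure (delayed
entry, right censoring, prognostic lab trajectories, panel genomics with
unmeasured calls, cancer-specific features with structured missingness)
plus the full modeling pipeline, so the phenomenon can be studied and the
machinery tested against ground truth.

## The model

The core estimator is a lasso-penalized Cox proportional-hazards model
with risk sets adjusted for left truncation. For entry time $e_i$, exit
time $t_i$, event indicator $\delta_i$ and features $x_i$, it minimizes

$$-\frac{1}{n} \sum_{i:\delta_i=1}\Big[ x_i^\top\beta -
\log \sum_{j:\, e_j < t_i \le t_j} e^{x_j^\top\beta} \Big]
\; + \; \lambda \sum_j w_j |\beta_j|$$

(Breslow ties), with the entry-time and cancer-type covariates
unpenalized ($w_j = 0$). The solver is iteratively reweighted least
squares with cyclic coordinate descent (C++), warm starts along a
100-point $\lambda$ path, step-doubling line search, and a
Karush–Kuhn–Tucker certificate on the exact partial-likelihood gradient
at every path point. $\lambda$ is chosen by 5-fold cross-validation
maximizing the held-out concordance index. Models are evaluated by the
left-truncation-aware c-index, the IPCW integrated Brier score, and the
hazard ratio of a median-split risk stratification, with bias-corrected
bootstrap intervals.

## Worked example

```r
library(pancox)

cfg <- sim_config(n_cancers = 3, cohort_sizes = c(120, 200, 300), seed = 7)
cohort <- simulate_cohort(cfg)
res <- run_pan_vs_single(cohort, model_specs = c("benchmark", "full"),
                         seed = 3, nlambda = 40)
print(res[res$cancer_type == "c01",
          c("model_spec", "training_scope", "c_index", "ibs",
            "hr_low_vs_high", "n_selected_features")])
```

```
  model_spec training_scope   c_index       ibs hr_low_vs_high
1  benchmark            pan 0.3850267 0.2262575      1.5172959
4       full            pan 0.5133690 0.2164284      1.1416355
7  benchmark         single 0.5026738 0.2749834      0.9772589
8       full         single 0.5294118 0.2315216      1.0333885
  n_selected_features
1                  12
4                  14
7                   9
8                   6
```

Each row is one (model specification, training scope) evaluated on the
held-out test set of cohort `c01` (the smallest: 120 subjects, 24 in
test). `c_index` is discrimination (0.5 = chance), `ibs` calibration
(lower is better), and `hr_low_vs_high` the hazard ratio of
predicted-low-risk vs predicted-high-risk patients split at the training
median (< 1 means the split separates survival in the right direction).
At this tiny evaluation size the estimates are noisy — the
acceptance suite runs 20 seeded replicates of a larger design to show the
systematic pan-cancer advantage on small cohorts.

A command-line interface wraps the pipeline:

```sh
Rscript inst/cli/pancox simulate --config cfg.json --seed 4 --out-dir out/
Rscript inst/cli/pancox compare  --config cfg.json --seed 4 --out-dir out/ --bootstrap-B 200
```

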