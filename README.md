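# clinformer

Transformer models for right-censored survival prediction on tabular
clinicogenomic cohorts, with self-supervised pretraining, embedding-based
explainability, and generative in-silico perturbation analysis — in R, on a
single CPU, at clinical-study scale (hundreds to thousands of patients).

## Who this is for

Biostatisticians and translational researchers who work with cohorts like
immunotherapy trial arms or real-world registries: one row per patient,
a mix of continuous labs (albumin, NLR, TMB), binary mutation calls and
categorical annotations, arbitrary missingness, and overall survival in
months with a death/censoring indicator.

## The model

A patient is an **unordered set of (feature name, value) pairs**. Each pair
is embedded as a learned name embedding plus a linear projection of the
scalar value; a TASK token is prepended; there is **no positional
encoding**, so predictions are invariant to feature order and missing
features are simply absent (PAD slots are masked from attention and
losses). A multi-head self-attention encoder produces output embeddings;
the TASK embedding feeds a bias-free linear head whose scalar output `beta`
is the survival score (higher = longer predicted survival).

Training minimizes a differentiable sigmoid relaxation of Harrell's
concordance index over comparable pairs (event observed, shorter time
first):

    L = sum_ij w_ij / (1 + exp((beta_j - beta_i) / sigma)),
    w_ij = Delta_i 1(T_i < T_j) / sum Delta_i 1(T_i < T_j)

Masked-feature pretraining (20% of names replaced by MASK, values visible;
loss `1 * CE_names + 0.01 * MSE_values`) supports *gradual* learning
(pretrain and fine-tune on the same cohort) and *transfer* learning
(pretrain on a large unlabeled cohort, fine-tune on a small labeled one).

On top of the fitted model:

* **permutation importance** — concordance drop when one feature's values
  are shuffled across patients;
* **functional groups** — clusters of the pairwise cosine similarities
  among last-layer feature/outcome embeddings ("post-attention"), with Cox
  proportional-hazards screening of any-member-mutated group indicators and
  distillation of the top groups into a plain multivariate Cox model;
* **perturbation analysis** — rescoring every patient over a decile grid of
  a feature (or 50 sampled value pairs for feature pairs), interaction
  scoring via `Diff = max(-log10 p_f, -log10 p_g) + log10 p_fg` from
  rank-sum tests, and a median split of the per-patient score spread into
  perturbation-**variant** and -**invariant** populations;
* a **synthetic cohort simulator** (correlated feature blocks, sparse
  mutations, known log-hazard, inverse-transform survival times, calibrated
  censoring, missing-at-random cells) returning full ground truth, so every
  capability is testable against oracles without external data.

## Worked example

```r
library(clinformer)

# a synthetic cohort with known truth: 600 patients, 12 features,
# 4 of them driving the hazard, 30% censoring
sim <- simulate_cohort(600, blocks = list(list(size = 12, rho = 0)),
                       coef = c(b1_f1 = 0.5, b1_f2 = 0.5,
                                b1_f3 = -0.5, b1_f4 = -0.5),
                       censor_frac = 0.3, seed = 11)
co <- sim$cohort

splits <- make_splits(co, n_splits = 1, seed = 5)
fit <- fine_tune(co, splits, epochs = 30, d_k = 64, n_layers = 2, seed = 3)

tail(fit$curves, 3)
#>    split epoch      loss   c_index
#> 28     1    28 0.2594182 0.6651250
#> 29     1    29 0.2629009 0.6807126
#> 30     1    30 0.2570333 0.6622131

c_index(-sim$truth$eta, co$time, co$event)   # oracle upper reference
#> [1] 0.7289642
```

The model's held-out concordance (~0.66) approaches the oracle concordance
of the true log-hazard (~0.73) — the gap is the irreducible estimation cost
at this cohort size. Permutation importance then recovers the four planted
features, and `perturb_single()` / `split_variant_invariant()` identify the
patients whose predicted survival is sensitive to a chosen feature:

```r
model <- fit$models[[1]]
imp <- permutation_importance(model, co, idx = splits[[1]]$test, seed = 1)
sort(tapply(imp$importance, imp$feature, mean), decreasing = TRUE)[1:4]
#>      b1_f3      b1_f4      b1_f1      b1_f2
#> 0.05765673 0.05609798 0.05414526 0.04277150
```

A thin pipeline wrapper (`run_pipeline()`, or
`inst/scripts/clinformer-pipeline.R` from a shell) chains
simulate → pretrain → train → explain → perturb from one YAML config with a
single seed, writing CSV/JSON outputs plus a resolved-config copy.

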