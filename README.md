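# midrp

Multi-source disease risk prediction for case-control cohorts with
timestamped ICD-10 diagnosis histories.

Complex-disease risk depends jointly on inherited variation, lifestyle, and
the comorbidities already written into a patient's medical record. `midrp`
fuses these three sources into one risk score:

- **Medical history.** A causally masked Transformer is pretrained on
  sequences of 3-character ICD-10 codes with continuous admission times
  (sinusoidal *temporal* encoding in place of positional encoding), using a
  joint next-event / next-time objective
  `L = Σ α_event · CE(next code) + α_time · (t − t̂)²`. Per-patient
  embeddings are then read off the hidden states: for a case, the
  representation of the last event strictly *before* the first target
  diagnosis (zero vector if the diagnosis opens the record); for a control,
  the last event. The strict causal mask makes the extraction provably
  leak-free.
- **Lifestyle / physical exposures.** Each candidate feature is tested for
  a causal link to the disease by two-sample Mendelian randomization:
  instrument filtering (p ≤ 1e-5, MAF ≥ 0.01), confounder-SNP exclusion,
  LD clumping (10,000 kb, r² ≤ 0.001), allele harmonization, the
  inverse-variance-weighted estimator over per-variant Wald ratios
  β_y/β_x, run against two independent outcome GWAS, and a fixed-effect
  meta-analysis (Cochran's Q, I²). A feature is kept iff fixed-effect
  p < 0.05, I² < 0.05, heterogeneity p > 0.05, and the 95% CI excludes 0.
- **Genetics.** A precomputed polygenic risk score enters a logistic
  branch `P(y=1|x_s) = σ(w_s·x_s + b_s)`.

The integrator maps each non-genetic factor (features + embedding) through
`φ_j = tanh(W_j x_j) ∈ R²`, weights the stacked `N×2` matrix by a learnable
`Γ`, and softmaxes the class sums into a posterior `Q`. Training minimizes
`CE(P,y) + α·KL(Q‖P) + β·CE(Q,y)` — the KL term is posterior
regularization pulling the two branches into agreement — and the final
score is the sum of the two class-1 log-odds,
`R = (w_s·x_s + b_s) + [L_ng(1) − L_ng(0)]`.

Everything is testable offline: the package ships generators for
comorbidity-structured Markov event sequences, liability-model cohorts, and
exposure/outcome GWAS pairs, each exporting its ground truth (transition
matrix, Bayes-optimal scores, planted causal effects).

## Worked example

```r
library(midrp)

# 1. simulate a comorbidity-structured world and pretrain the history model
sim <- simulate_event_sequences(600, codes = synthetic_codes(12),
                                len_range = c(3L, 12L), seed = 7)
vocab <- build_vocabulary(sim$sequences)
cfg <- transformer_config(K = vocab$K, n_layers = 2, n_heads = 2,
                          d_model = 32, d_qk = 16, d_ff = 64, max_len = 12,
                          epochs = 6, lr = 3e-3, use_residual = TRUE,
                          seed = 7)
model <- pretrain_transformer(sim$sequences$sequences, vocab, cfg)
next_event_accuracy(sim$sequences$sequences, model, vocab)

# 2. causal feature selection from a simulated GWAS trio
g <- simulate_gwas_pair(true_effect = 0.3, seed = 7)
report <- select_causal_features(list(whole_grain_intake = g$exposure),
                                 g$outcome1, g$outcome2, g$ld)

# 3. integrator on a liability cohort, against the Bayes-optimal score
simL <- simulate_liability_data(5000, seed = 7)
tr <- 1:3500; te <- 3501:5000
sub <- function(idx) midrp_data(simL$data$x_s[idx],
  lapply(simL$data$factors, function(f) f[idx, , drop = FALSE]),
  simL$data$y[idx])
fit <- train_midrp(sub(tr), midrp_config(seed = 7))
compute_metrics(risk_score(sub(te), fit), simL$data$y[te])
```

Output:

```
next-event accuracy: 0.700 (Bayes accuracy of the generator: 0.700)
             feature pooled_beta pooled_se  fixed_p I2 causal
1 whole_grain_intake        0.25     0.025 1.36e-23  0   TRUE
test AUROC 0.822 (Bayes-optimal 0.827), accuracy 0.725, F1 0.696
```

The pretrained model matches the generating chain's analytic Bayes
accuracy (0.700); the MR pipeline recovers the planted causal effect 0.3
within sampling error and calls it causal; the trained integrator's test
AUROC sits within 0.005 of the generator's Bayes optimum.

## Command line

An `Rscript` wrapper is installed at `exec/midrp` (also callable as
`midrp_cli()` from R):

```sh
midrp simulate --preset cohort --n 500 --target A00 --seed 7 --out data/
midrp build-cohort --events data/events.tsv --participants data/participants.tsv \
      --target A00 --seed 7 --out data/cohort.tsv
midrp pretrain --events data/events.tsv --epochs 10 --residual --out model.json
midrp embed --model model.json --events data/events.tsv \
      --cohort data/cohort.tsv --target A00 --out emb.tsv
midrp select-features --exposures gwas/ --outcome1 o1.tsv --outcome2 o2.tsv \
      --ld ld.tsv --out report.tsv
midrp train --cohort data/cohort.tsv --features data/features.csv \
      --prs data/participants.tsv --embeddings emb.tsv --seed 7 --out run/
midrp evaluate --scores run/scores.tsv --split test --out report.json
```

## Documentation

The methods vignette (`vignettes/midrp-methods.Rmd`) documents the model
equations, every tunable parameter with its default and rationale, what
the synthetic generators do and do not emulate, numerical choices, and
known limitations.
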