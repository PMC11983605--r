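# aidnet

Multi-class diagnosis of autoimmune disorders from tabular clinical records,
using a hybrid deep network — 1-D convolutional feature extraction, a gated
recurrent (LSTM/GRU) stage, and a graph-based feature-topology refinement
layer fused into a softmax head — together with the full study protocol
around it: synthetic cohort simulation, leakage-free preprocessing, seeded
training, multi-class evaluation, baseline comparison with paired
significance tests, a six-variant ablation suite, and permutation feature
attribution.

## Who this is for

Researchers in clinical machine learning who want a reproducible, fully
inspectable reference implementation of this family of tabular deep
classifiers — with every stage (SMOTE, stratified splitting, Xavier/Adam
training, macro metrics, paired t-tests) exercisable end to end on a
synthetic autoimmune cohort, no data download required.

## The model

The preprocessed feature vector `x ∈ [0,1]^F` (13 clinical predictors:
age, gender, family history, symptom count, blood pressure, cholesterol,
BMI, WBC, RBC, hemoglobin, platelets, CRP, ESR — one-hot encoded and
min-max scaled) is treated as a 1-D single-channel signal. Stages:

1. convolution: `Z^l = W^l ∗ X^{l-1} + b^l`, `X^l = f(Z^l)` (two layers,
   kernel 3, 8/16 channels, ReLU);
2. gated recurrence over ordered segments of the convolution map (LSTM,
   hidden 32);
3. dense projection to an extracted-feature vector `X^L` (16 units);
4. topology refinement: adjacency `a_ij = ReLU(w_ij · X^L)` (one weight
   vector per feature pair; an absolute-correlation mode is available);
5. fused head: `ŷ = Softmax(W_out · Concat(A X^L, X^L) + b_out)`.

Training minimizes cross-entropy + `λ Σ w²` (λ = 1e-4) with Adam
(η = 0.001, batch 64, ≤ 100 epochs, dropout 0.5 on dense stages, Xavier
initialization, early stopping on a 10% stratified validation split).
Six ablation variants toggle the convolutional, recurrent and topology
stages (`full`, `cnn_only`, `cnn_lstm`, `cnn_topology`, `lstm_only`,
`mlp_only`).

## Worked example

```r
library(aidnet)

# simulate a 2,000-patient cohort with a strong planted biomarker signal
cohort <- generate_cohort(cohort_spec(n = 2000, seed = 7, effect_size = 3))
split  <- stratified_split(cohort$disease, seed = 7)

fit <- aidnet(disease ~ ., cohort[split$train, ], variant = "full",
              hp = hyperparams(seed = 7), seed = 7,
              validation = cohort[split$validation, ])
print(fit)
#> Hybrid diagnostic network (variant: full )
#> Model config (full): 15 features -> conv[8,16 ch, k=3] -> lstm[32] ->
#>   proj[16] -> topology[learned] -> softmax[8]
#> Classes: RA, SLE, MS, T1D, Psoriasis, IBD, Sjogren, Other
#> Trained 26 epoch(s) (early stopping) - best validation loss 0.06229 at epoch 16

evaluate_model(fit, cohort[split$test, ])
#> Accuracy:  96.5%
#> Macro precision/recall/F1: 96.9 / 94.9 / 95.8 %
#> AUC-ROC: 1  AUC-PR: 0.996
```

Accuracy is the held-out fraction of correctly diagnosed patients; macro
precision/recall/F1 weight the eight disease classes equally, so rare
diagnoses count as much as rheumatoid arthritis; the AUCs are one-vs-rest
macro averages. (At this cohort size a couple of hundred test patients
remain after the 80/10/10 split; accuracy rises further with `n`.)

Feature attribution and the ablation suite:

```r
permutation_importance(fit, cohort[split$test, ], seed = 7)   # CRP/ESR rank top
run_ablation(cohort, hp = hyperparams(epochs = 20), seeds = 1:3)
```

A thin command-line wrapper over the same functions ships in
`inst/cli/aidnet.R`:

```sh
Rscript inst/cli/aidnet.R simulate --n 10000 --seed 1 --outdir run/
Rscript inst/cli/aidnet.R train    --cohort run/cohort.csv --seed 1 --outdir run/
Rscript inst/cli/aidnet.R evaluate --cohort run/cohort.csv --model run/model.rds --seed 1 --outdir run/
```

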