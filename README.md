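# bigraphdta

Drug-target binding affinity prediction from compound SMILES strings and
protein amino-acid sequences, for computational chemists and ML
practitioners doing virtual screening on bioactivity tables (e.g. ChEMBL
IC50 exports).

The affinity is regressed on the pIC50 scale, pIC50 = -log10(IC50 in
molar).  The core model is a hybrid two-branch network:

* **drug branch** — the SMILES is parsed into a molecular graph (one node
  per heavy atom, 78-dim atom features) and encoded by three graph
  convolutions with the symmetric-normalized self-loop propagation rule

  H^(l+1) = sigma( D~^(-1/2) (A + I) D~^(-1/2) H^(l) W^(l) ),

  followed by global max pooling and two dense layers;
* **protein branch** — the sequence is integer-encoded to fixed length L
  (default 1000, zero-padded), embedded (128-dim), and read by a
  bidirectional LSTM (128 hidden units per direction) whose position-wise
  outputs are flattened through a dense layer;
* **head** — the concatenated 256-dim representation passes through
  1024- and 512-unit ReLU/dropout layers to a single affinity output.

Alongside the hybrid model the package provides the
graph-convolution/1D-CNN variant (`graphdta_gcn`), the two-branch
convolutional token model (`deepdta`), classical regressor baselines
(SVR / random forest / gradient boosting on learned or raw-token
features), selective L1/L2/elastic-net regularization of named layer
groups, layer freezing and transfer learning, seeded splits and k-fold
cross-validation, the MSE / R² / concordance-index metrics with exact tie
semantics, and a synthetic interaction-data generator with a planted,
calibratable structure-activity signal.  The forward/backward passes are
written in R matrix code with the LSTM recurrence as a compiled
RcppArmadillo kernel; every gradient path is verified against finite
differences in the test suite.

## Worked example

Generate a synthetic bioactivity table whose planted signal is calibrated
to a best achievable R² of 0.8, train the desk-scale hybrid model, and
evaluate on the held-out 20%:

```r
library(bigraphdta)

cfg <- synth_config(n_records = 600, n_targets = 10, seed = 42)
cfg$noise_sd <- noise_for_oracle_r2(cfg, 0.8)
records <- generate_dataset(cfg)
head(records, 3)
#> # A tibble: 3 x 4
#>   smiles                  target_id sequence              pic50
#>   <chr>                   <chr>     <chr>                 <dbl>
#> 1 CC(N)                   T007      IYWQVSDMYMLSPVAAWPHL…  4.45
#> 2 CCCCC(O)C(c1ccccc1)C(N) T003      HVMAKWNYHMRDRRDAGFCG…  5.24
#> 3 C(N)C(Cl)C(Cl)          T007      IYWQVSDMYMLSPVAAWPHL…  5.45

fz <- featurize_dataset(records, L = 100)
split <- split_dataset(nrow(records), ratio = 0.8, seed = 1)
model <- build_model(model_spec_small("bigraph"), seed = 1)
model
#> <dta_model> family=bigraph, 25 parameter tensors, 246369 parameters
#> layer groups: gcn1, gcn2, gcn3, fc_g1, fc_g2, embed_xt, protein_core,
#>               fc1_xt, fc1, fc2, out

fit <- train(model, fz, split, train_config(epochs = 25, seed = 1))
fit
#> <dta_run_report> 25 epochs; best epoch 24: test MSE 0.6315, R2 0.6189, CI 0.8091

p <- predict_affinity(fit$best_model, fz, split$test_indices)
evaluate(fz$labels[split$test_indices], p)
#> # A tibble: 1 x 4
#>     mse    r2    ci     n
#>   <dbl> <dbl> <dbl> <int>
#> 1 0.632 0.619 0.809   120

oracle_r2(cfg)
#> [1] 0.8
```

So 25 epochs of the small model already explain 62% of the label variance
against a noise-imposed ceiling of 80%, and rank test pairs with a
concordance of 0.81 (0.5 would be chance).  `autoplot(fit)` draws the
training/validation/test curves; `write_run_report(fit$report, dir)`
serializes the per-epoch log (JSONL) and the best-epoch summary (JSON).

Real data enters the same way: `load_interactions("chembl.csv",
units = "nanomolar")` applies the pIC50 transform (explicit IC50 units
are required), optionally joining sequences from a FASTA file by target
identifier.

A command-line driver wraps the full pipeline
(`synth` / `prepare` / `train` / `evaluate` / `transfer` / `baseline`):

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "bigraphdta.R", package = "bigraphdta"))') \
    train --data data.csv --model bigraph --preset small --epochs 50 --out runs/exp1
```

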