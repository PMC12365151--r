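# cmmfnet

Multimodal deep classifier for **lung adenocarcinoma subtypes** — in situ
(AIS), minimally invasive (MIA) and invasive (IA) — from 3D CT lesions,
their bounding boxes, and clinical records, implemented entirely in R.

On CT the three subtypes differ in lesion size, density (ground-glass to
solid) and margin irregularity, but the differences are subtle and
clinicians combine the image with the patient record. `cmmfnet`
implements a contrastive multimodal fusion network for this problem,
plus the full surrounding workflow: CT preprocessing, a synthetic
lesion-phantom generator (so everything is testable without clinical
data), and stratified cross-validated training and evaluation.

## The model

Per lesion, three inputs: a small crop $\mathcal I^S$ (32³ voxels at
1 mm), a large crop $\mathcal I^L$ (128×128×32), each paired with the
crop-relative lesion box $\mathcal B$, and the encoded clinical vector
$\mathcal C\in\mathbb R^{1\times l}$.

* **CT encoder** — 3D ViT: $p^3$ patch embedding ($p=8$ → 64 / 1024
  tokens), the six box coordinates embedded as an extra token at
  position 0, learnable positions, 12 pre-norm transformer blocks
  ($D=768$, 12 heads, $\mathrm{softmax}(QK^\top/\sqrt{d_k})V$), token-mean
  pooling → $f^S, f^L$.
* **Clinical encoder** — each record entry scales a learned
  $D$-dimensional row; the $l\times D$ sheet (plus positional rows) is
  flattened and projected → $f^C$.
* **Contrastive alignment** — $z_i = f/\lVert f\rVert$, logits
  $l_1=\alpha z_1 z_2^\top$, $l_2=\alpha z_3 z_2^\top$ with learnable
  $\alpha$ initialized at $\exp(\log\frac1{0.07})$; symmetric
  cross-entropy over matching pairs.
* **Fusion** — the raw features stack into
  $F=(f^S\,f^C\,f^L)^\top$; Phase 1: $n$ residual transformer blocks over
  the 3 modality tokens + per-token layer norm; Phase 2: channel
  attention, each row rescaled by
  $g_1+g_2 = \sigma(W_2\mathrm{ReLU}(W_1 AP)) + \sigma(W_2\mathrm{ReLU}(W_1 MP))$;
  linear head → 3 class logits.
* **Objective** —
  $L=\omega(L_{SC}+L_{LC})+(1-\omega)L_{\text{focal}}$ with the dynamic
  weight $\omega = L_c/(L_c+L_f)$ from detached values, and focal loss
  $-\frac1N\sum\alpha_t(1-p_t)^{0.25}\log p_t$ with inverse-frequency
  $\alpha_t$.

Training follows the method's recipe: Adam (lr $10^{-4}$, weight decay
$10^{-3}$, betas $(0.9,0.99)$), per-epoch exponential decay (0.99),
batch 24, stratified 5-fold cross-validation, flip augmentation with box
adjustment on training folds only. Metrics are accuracy, macro
precision/recall/F1 (undefined classes count 0) and macro one-vs-rest
AUC (midrank ties; constant scores give 0.5).

See `vignettes/cmmfnet-methods.Rmd` for the full methods account and the
design decisions.

## Worked example

Sixty noise-free phantoms, desk-scale model, 2-fold cross-validation
(about a minute on one CPU):

```r
library(cmmfnet)
spec    <- phantom_spec(noise_sd = 0, seed = 7)
cases   <- build_dataset_memory(spec, 60, seed = 7)
samples <- preprocess_cases(cases)

cfg <- cmmf_config(embed_dim = 64L, depth = 2L, n_heads = 4L,
                   patch_size = 16L, dff_layers = 1L, dff_heads = 4L)
tc  <- train_config(lr = 1e-3, epochs = 10L, early_stop_acc = 1.0, seed = 7)
cv  <- cross_validate(samples, cfg, tc, phantom_ehr_fields(spec), k = 2L)
print(cv)
print(cv$pooled$confusion)
```

```
Pooled validation metrics over 2 folds:
<metrics_report> n=60  acc 91.67%  macro P 90.74%  R 88.89%  F1 87.96%  AUC 1.0000
Per-fold mean (sd):
  accuracy   91.713 (1.966)
  precision  90.833 (1.179)
  recall     88.988 (2.104)
  f1         88.054 (2.303)
  auc         1.000 (0.000)
    pred
true  0  1  2
   0 13  0  0
   1  5 10  0
   2  0  0 32
```

Classes 0/1/2 are AIS/MIA/IA. The phantoms are separable by construction
(disjoint class radius ranges, class-shifted clinical fields), so at this
tiny budget the model already ranks every case correctly (AUC 1.0); the
five residual errors are MIA cases called AIS at the 0.5 threshold —
with the acceptance-scale budget (120 cases, up to 30 epochs) pooled
accuracy reaches 100%.

Useful entry points: `phantom_spec()` / `build_dataset()` (synthetic
world, NIfTI + CSV manifest on disk), `preprocess_case()` (resample →
HU window → dual-scale crop), `fit_ehr_encoder()` / `encode_ehr()`,
`cmmf_model()` / `model_forward()` / `model_loss()`,
`cross_validate()` / `evaluate_predictions()` / `paired_ttest()`. A thin
CLI over the same functions ships in `inst/cli/cmmf`
(`generate | preprocess | train | evaluate`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's main pipeline from scratch — generates a
phantom dataset, preprocesses it, trains the model with stratified
cross-validation at desk scale and logs the pooled metrics — and writes
the results JSON to `--out`.
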