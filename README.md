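# echoenhance

Convolutional enhancement and rule-based diagnosis for cardiac
ultrasound images — a compact, fully reproducible R implementation of
a deep-learning-assisted echocardiography workflow, exercised entirely
on synthetic data.

## Who this is for and what it does

Cardiac color Doppler ultrasound is the workhorse examination for
chronic heart failure (CHF), but its images carry heavy multiplicative
speckle. This package is for researchers and students who want a
desk-scale, end-to-end, *testable* version of the pipeline "denoise
the image with a small convolutional network → score the image quality
→ apply rule-based diagnostic criteria → quantify diagnostic
concordance", with every stage reproducible from a single seed and no
clinical data required.

The core pieces:

* **Enhancement network.** A three-stage convolutional net
  (feature extraction F1: 9×9×16 → nonlinear mapping F2: 5×5×8 →
  linear reconstruction F3: 5×5×1) with the self-gated *swish*
  activation `a(t) = t·σ(αt)` (trainable α; plain ReLU selectable),
  reflect padding, trained by mini-batch SGD
  (`p ← p − β·ḡ`, gradients averaged over batches of size z) on the
  pixel MSE `Loss = (1/n)Σ(s_j − s'_j)²`. Backprop is hand-derived
  and verified against finite differences to 1e-4.
* **Semi-supervised discriminator losses.** For real-class logits `l`
  with the generated-class logit pinned to 0 and `t = LSE(l)`:
  `L_label = −l_y + LSE(l)`, `L_unlabel = −t + softplus(t)`,
  `L_fake = softplus(t)`, combined as
  `L_D = L_label + v·(L_unlabel + L_fake)/2`.
* **Quality metrics.** MSE, `PSNR = 10·log10((2ⁿ−1)²/MSE)` dB, and
  SSIM from global image moments (sliding-window variant available),
  all on the integer 0..2ⁿ−1 scale.
* **Synthetic world.** A four-chamber cardiac phantom generator with
  a blur → unit-mean squared-Gaussian speckle → additive-noise
  degradation chain, and a patient-cohort sampler parameterised by
  the study groups' printed means/SDs (LVEF, LVDD, LAD + sarcopenia
  measures).
* **Diagnosis.** Strict rule-based positivity — CHF: LAD > 30 mm,
  LVDD > 55/50 mm (male/female), LVEF < 50%; AWGS sarcopenia:
  SMI < 7.0/5.4 kg/m², grip < 26/18 kg, gait < 0.8 m/s — plus
  concordance arithmetic (similarity = 100·group_CHF/final_CHF,
  half-up to one decimal) and pooled t / chi-square comparisons.

## Worked example

```r
library(echoenhance)

# a clean phantom and its degraded twin
spec  <- phantom_spec(64, 64)
clean <- generate_phantom(spec)
noisy <- degrade(clean, degradation_spec(speckle_sigma = 0.2,
                                         blur_sigma = 1, seed = 1))
quality_report(clean, noisy)
#>        mse  psnr_db      ssim
#> 1 1105.308 17.69597 0.8649947

# train the default 3-layer net on 12 paired phantoms (32x32)
pairs <- make_paired_dataset(12, phantom_spec(32, 32),
                             degradation_spec(0.2, 1, 0.01, seed = 100),
                             jitter_seed = 7)
fit <- train_enhancer(enhancer_net(seed = 1), pairs,
                      train_config(learning_rate = 0.1, batch_size = 4,
                                   epochs = 50, seed = 2))
round(c(fit$trace$loss[1], fit$trace$loss[50]), 4)
#> [1] 0.3885 0.0262

# diagnostic concordance from per-group CHF counts (cohort of 259)
similarity_percent(215, 230)   # experimental arm vs final diagnosis
#> [1] 93.5
similarity_percent(200, 230)   # control arm vs final diagnosis
#> [1] 87
proportion_percent(200, 259)   # CHF share of the control arm
#> [1] 77.2
proportion_percent(215, 259)
#> [1] 83
```

The quality report reads: the degradation leaves ~17.7 dB PSNR
against the clean phantom (identical images would be +Inf); global
SSIM of 0.86 is still high because whole-image moments are forgiving —
see the methods vignette. The training loss falls from 0.389 to 0.026
mean squared intensity error over 50 epochs. The concordance numbers are the
similarity of each study arm's ultrasound CHF calls to the final
combined diagnosis and each arm's CHF proportion, rounded half-up to
one decimal.

At the acceptance fixture scale (40 pairs, 200 epochs) the trained
network improves held-out PSNR by ≥ 2 dB over the degraded input;
`tests/testthat/test-acceptance.R` asserts this together with
oracle-equivalence, analytic-loss, metric-identity and cohort-power
criteria.

## End-to-end pipeline and CLI

```r
run_pipeline(run_config(seed = 1), "run_out")   # all artifacts + CSVs
```

or from the shell (after install):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/echoenhance", package="echoenhance"))')" \
  run-all --seed 1 --out run_out
```

Subcommands: `simulate`, `train`, `enhance`, `evaluate`, `diagnose`,
`concordance`, `run-all`. Images are 8-bit grayscale PNG or 8/16-bit
PGM; cohorts and reports are CSV; models are a documented JSON format.

## Documentation

`vignettes/methods.Rmd` documents the model and its assumptions, all
tunable parameters with defaults and rationale, what the synthetic
generators do and do not emulate, numerical choices, and known
limitations.
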