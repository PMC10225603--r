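# ssstn

Subject-to-subject semantic style transfer for EEG motor-imagery
classification, in R.

Motor-imagery brain-computer interfaces decode imagined movements from
the EEG's mu (8–13 Hz) and beta (14–30 Hz) rhythms. Because these rhythms
vary strongly between people, some users — *BCI illiterates*,
conventionally below 70% classification accuracy — get almost no control
from a standard per-subject pipeline. This package implements a
feature-level answer: train one squeeze-and-excitation CNN classifier per
subject on Morlet-CWT scalogram images, pick the best subject as the
*source* ("BCI expert"), and train an encoder–decoder generator `G` that
maps an illiterate target subject's scalograms `x_T` into the source's
feature space, with the source and target classifiers frozen. The
generator minimizes

    L_total = α·L_style + β·L_cont + γ·L_sem        (α = 0.1, β = 1, γ = 1)

where `L_style` is the KL divergence between softmaxed Gram matrices of
the source classifier's features on `G(x_T)` and on paired same-class
source trials, `L_cont` is the squared distance between the target
classifier's features on `x_T` and the source classifier's features on
`G(x_T)`, and `L_sem` is the source classifier's cross-entropy on
`G(x_T)` against the target's true label. The final prediction soft-votes
the two probability vectors: `ŷ_vote = ŷ_S' + ŷ_T`, argmax, ties to the
lowest class.

Because no deep-learning framework is among the dependencies, the package
contains its own small, fully gradient-checked neural-network engine
(im2col convolutions on BLAS, batch norm, SE blocks, self-attention,
Adam), plus a controllable ERD/ERS simulator so the whole method is
testable without any EEG download.

## Worked example

```r
library(ssstn)

# A strong "expert" and a weak "illiterate" with a different montage/band
expert <- subject_profile("expert", erd_depth = 0.9, snr = 8,
                          mu_center_hz = 10, beta_center_hz = 22,
                          channel_topography = list(1L, 3L), seed = 601)
illit  <- subject_profile("illiterate", erd_depth = 0.15, snr = 0.5,
                          mu_center_hz = 12, beta_center_hz = 26,
                          channel_topography = list(2L, 1L), seed = 701)

prep <- function(p, n) {
  cwt_transform(preprocess_epochs(
    simulate_subject(p, n, n_channels = 3, duration_s = 4.5,
                     fs = 250, K = 2)),
    freqs_hz = default_freqs(4, 40, 16), time_downsample = 48)
}
exp_tr <- prep(expert, 40); ill_tr <- prep(illit, 40)
illit_test <- illit; illit_test$seed <- illit$seed + 5000
ill_te <- prep(illit_test, 30)

spec <- classifier_spec(3, 16, 23, K = 2, conv_channels = c(16, 32))
ce <- pretrain_classifier(exp_tr, spec = spec, n_epochs = 40, seed = 1)
ci <- pretrain_classifier(ill_tr, spec = spec, n_epochs = 40, seed = 1)
ce
#> <ssstn_pretrain> subject expert: train 100.00%, test 100.00% (40 epochs)
ci
#> <ssstn_pretrain> subject illiterate: train 100.00%, test 60.00% (40 epochs)

tfr <- train_generator(transfer_bundle(ce, ci, seed = 801),
                       ill_tr, exp_tr, n_epochs = 120,
                       gen_spec = generator_spec(3, 16, 23,
                                                 enc_channels = c(16, 32, 64)))
evaluate_subject(tfr, ce, ci, ill_te)
#> <ssstn_eval> subject illiterate: ensemble 75.00% (source path 73.33%,
#>   target path 71.67%, pre-transfer 40.00%)
```

The expert's classifier is useless on the raw target data (40%, near
chance) because the target expresses its classes on other electrodes and
bands; after style transfer the same frozen classifier reaches 73% on
`G(x_T)`, and the soft-voting ensemble combines both views. `tidy()`,
`glance()` and `autoplot()` methods expose per-epoch loss tables and
accuracy summaries; `run_end_to_end(load_config("cfg.yaml"))` drives the
whole pipeline from a validated YAML config, and `exec/ssstn` wraps the
stages as a command line (`ssstn simulate | preprocess | cwt | pretrain |
transfer | ablate | evaluate | run`).

The per-subject accuracies printed for the SE-CNN backbone and the full
pipeline on the BCI Competition IV-2a/2b benchmarks ship as a reference
table:

```r
published_accuracies("iv2a", "SE-CNN")
select_source(published_accuracies("iv2a", "SE-CNN"))   # "3"
flag_illiterates(published_accuracies("iv2b", "SE-CNN")) # "2"
summarize_accuracy(published_accuracies("iv2a", "SSSTN"))$mean  # 80.655...
```

## Scope

The simulator models 1/f background noise, narrowband sensorimotor
rhythms, multiplicative post-cue ERD, and subject-specific montages — not
artifacts, drift, or session nonstationarity. Reproducing the published
BCI-competition accuracy tables requires the competition recordings and
GPU-scale training and is out of scope; see the methods vignette
(`vignettes/style-transfer-methods.Rmd`) for the full model description,
parameter meanings, design decisions and limitations.
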