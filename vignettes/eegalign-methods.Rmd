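---
title: "Contrastive EEG–text alignment: models, choices, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrastive EEG–text alignment: models, choices, and what the tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Clinical EEG archives pair every recording with a free-text report written
by a neurologist. `eegalign` trains a dual-encoder model so that windows of
the EEG time series and the text of the same recording's report land close
together in a shared embedding space, while windows and reports of *other*
recordings are pushed apart. Once aligned, the space supports decoding
without task-specific training: a class can be described by a sentence, and
a recording is classified by which sentence's embedding it is nearer to.

For matched pairs $(x_i, y_i)$ of EEG and text projections in a batch of
$N$, the loss is the temperature-scaled softmax over in-batch negatives

$$
\mathcal{L} \;=\; \frac{1}{N}\sum_{i=1}^{N} -\log
\frac{\exp(\mathrm{sim}(x_i, y_i)/\tau)}
     {\sum_{j=1}^{N}\exp(\mathrm{sim}(x_i, y_j)/\tau)},
$$

with $\mathrm{sim}$ fixed to cosine similarity on L2-normalized
projections. The default reported loss is the symmetric average of the
EEG-to-text and text-to-EEG directions (the CLIP convention); the literal
one-directional form is available with `symmetric = FALSE`. Useful
analytic anchors, all enforced by tests: the loss is non-negative, equals
$\ln N$ under uniform similarities, vanishes as the diagonal saturates,
and is invariant to rescaling `sim` and $\tau$ together.

$\tau$ is not specified by the reference recipe, so the logit scale
$1/\tau$ is a learnable parameter, clamped to $[10^{-3}, 100]$, with the
CLIP-standard initialization $1/0.07$ as the package default. Small-corpus
contrastive training passes through a plateau (projections of all items
share one direction; the loss sits at the log batch-size level) before
class structure emerges, and the time to escape depends on the
initialization: on the 200-recording synthetic corpus, escape takes 60–80
epochs at scale $1/0.07$ but 20–60 epochs at scale 5. The synthetic
acceptance runs therefore initialize the scale at 5 — a configuration
choice within the clamp range, read off the training loss alone — while
the default remains $1/0.07$.

## Architecture

* **EEG encoder.** A four-block convolution–max-pool network in the Deep4
  lineage: block 1 factorizes the spatio-temporal filter into a temporal
  convolution (kernel 10, shared across the 21 electrodes) followed by a
  spatial convolution across electrodes; blocks 2–4 are
  dropout(0.5)–conv(kernel 10)–batch-norm–ELU–max-pool(3). Default widths
  are 25/50/100/200; the dense softmax classifier of the original design is
  replaced by flatten + linear to a 128-d embedding. With 21 × 1200 inputs
  the time axis contracts 1200 → 397 → 129 → 40 → 10.
* **Text encoder.** A contract (`encode`, trainable parameters, truncation
  policy) with three implementations: a deterministic feature-hashing
  bag-of-words embedder (no parameters, fully offline — the test
  workhorse), a trainable token-embedding averager, and an adapter for a
  user-supplied pretrained sentence encoder. No pretrained checkpoint is
  bundled; the offline build errs informatively if one is requested.
* **Projection heads.** Two 3-layer MLPs with ReLU activations map the
  128-d EEG embedding and the text embedding into the shared 64-d space
  (width configurable, e.g. 32–512). The hidden layers are batch
  normalized before the ReLU, the SimCLR-style head. This is load-bearing
  at desk scale: without it the heads reliably collapse — outputs grow a
  dominant shared direction (norms in the hundreds), cosine similarities
  become uniform, and because the gradient through L2 normalization
  carries a 1/norm factor, the collapsed state is self-freezing. With the
  normalized head the loss still shows a plateau but always escapes within
  the training budget. Projections are L2-normalized; an all-zero row maps
  to the zero vector with a warning rather than NaN, and receives zero
  gradient.

The whole stack — im2col convolutions, batch-norm, max-pool, dropout,
Adam — is implemented in-package on BLAS matrix products with
hand-derived backward passes (there is no deep-learning runtime in the
target environment). Every layer's gradient is verified against finite
differences in the test suite; the layout-shuffling hot paths (im2col /
col2im, the block-1 electrode gather) are small C++ kernels.

## Preprocessing

The deterministic chain from raw microvolt recordings to model windows:
select the 21-electrode 10-20 montage (with alias normalization such as
`"EEG FP1-REF"` → `"Fp1"`), crop to seconds [60, 180) — recordings shorter
than 180 s are excluded, not padded — clip to ±800 µV, resample to 100 Hz,
divide by 30, and cut windows of 1200 samples with stride 519 (only
complete windows; a right-aligned extra window is available behind a flag).

Two numerical choices deserve note. Resampling is Fourier-domain
(spectrum truncation); the contract for this stage is the FFT-peak
property — band-limited content keeps its dominant frequency to within one
bin — not bit-level equality with any polyphase implementation. And because
Fourier resampling of a clipped plateau rings slightly past the clip bound,
`preprocess()` re-applies the (idempotent) clip after resampling so the
post-chain amplitude bound is exactly `800/30`; without this the stated
exact bound is unattainable by the literal five-stage composition.

## Reports, labels, prompts

Reports are split into 15 canonical sections by scanning for
case-insensitive colon-terminated headers at line starts, with an alias
table for real-world spelling variants; text before any header goes to a
reserved preamble. Rendering and re-parsing is the identity on section
contents. Four binary tasks are derived: pathological (from metadata), age
(> 50; age exactly 50 falls in the non-over class — the zero-shot prompt
"under 50 years old" is a class handle, not the label rule), gender, and
medication — a case-insensitive substring match for keppra/dilantin/
depakote anywhere in the report. Whether the original pipeline matched
within the medications section only is not documented; matching the whole
report follows the task's own phrasing ("the report contains"), and is the
package's choice.

## Training protocol

Adam with learning rate 5e-3, weight decay 5e-4, 20 epochs, batch size 64
(the reference recipe). Two parameter groups: the EEG encoder, both
projection heads and the logit scale at the full rate; the text encoder's
own parameters at `lr × text_lr_ratio` (default 1e-3). The text projection
head sits in the full-rate group deliberately: the reduced rate exists to
protect pretrained linguistic knowledge, and with a frozen hashing encoder
a down-scaled head could never align at ratio 0. Weight decay is not
applied to biases, normalization parameters or the logit scale.

After the last epoch the batch-norm running statistics are recalibrated
with one full training-mode pass (one window per recording, dropout off;
`bn_recalibrate` in the config, on by default). During contrastive
training the running averages lag the fast-moving parameters — most
severely right after the plateau escape — which can leave inference-mode
projections collapsed while training-mode projections are well separated;
one calibration pass closes the gap. Checkpoints store the calibrated
statistics.

Batch composition: by default at most one window per recording per batch,
sampled uniformly, so in-batch negatives never share a report (windows of
the same recording would otherwise be false negatives). This policy is the
package's choice, not documented in the reference recipe, and can be
switched off. Empty-report recordings are dropped from pairing with a
logged count. One master seed drives initialization, shuffling and
sampling; the loss trajectory is exactly reproducible for fixed data,
configuration and seed.

## Evaluation regimes

All metrics are balanced accuracy (mean of per-class recalls). Evaluation
is at the *recording* level: a recording's projection is the re-normalized
mean of its window projections (zero-shot), and a probe scores a recording
by its mean window probability. The aggregation is the package's choice —
the reference protocol does not state one — and window-level scores remain
available.

* **Zero-shot**: fixed prompt pairs per task; a recording takes the class
  of the nearest prompt projection by cosine; exact ties go to class A
  with a warning.
* **Probing**: ridge logistic regression (`glmnet`, small fixed penalty)
  or a 3-layer MLP head (hidden width 64 — unspecified upstream) on frozen
  embeddings. Probes consume the 128-d encoder embedding by default; which
  embedding fed the original probes is unstated, and the 64-d projection is
  exposed as an alternative.
* **Baselines**: a task-specific Deep4 trained end-to-end from scratch
  (upper bound), and an alternative-task model — supervised pretraining on
  a different task, then a frozen-encoder head (lower bound).
* **Few-shot**: recordings split 60/20/20 (contrastive-train / few-shot
  pool / eval), disjoint at the recording level and re-asserted at use.
  Fractions 1/2 … 1/50 of the pool are sampled *stratified by class*
  (guaranteeing at least one recording per class; plain uniform sampling
  would lose a class at 1/50), identically for all compared methods —
  asserted by a hash of the sampled ids. Five seeds per cell by default;
  bands are 80% percentile intervals over seeds.

## Frequency-domain attribution

For a prompt, each window is re-parameterized by its unitary real-FFT
coefficients per channel; the gradient of the cosine similarity between
the window's projection and the prompt's projection with respect to those
coefficients is `w_k · FFT(g)_k / sqrt(T)`, where `g` is the time-domain
input gradient and `w_k` doubles interior bins. Maps are reduced to
magnitudes (or signed real parts — both views are exposed since the
upstream convention is unstated) and averaged over the evaluation split's
windows; the pooled spectrum is always the channel-mean of magnitudes.
A linear read-out surrogate gives an analytic oracle: reading a single
(channel, frequency) cell concentrates all attribution mass there, and a
numeric gradient over the rFFT coefficients on tiny windows confirms the
closed form.

## The synthetic world

The generator exists so every pipeline stage and the end-to-end alignment
property are testable without the access-gated clinical corpus. Defaults
(chosen once, with physiological ranges in mind, then frozen):

* Background: 1/f-shaped Gaussian noise (exponent 1) with a 5% white
  floor and 30 µV RMS per channel — after the ÷30 rescaling the
  preprocessed signal sits near unit variance (measured sd ≈ 1.0–1.2).
  The 1/f shape is floored at 1 Hz, emulating the acquisition high-pass of
  clinical EEG hardware.
* Abnormal class: 20 Hz beta-spindle bursts (bandwidth 2 Hz, 1 s Hann
  bursts, duty 0.6, 50 µV) on C3/Cz/C4; report impression "This is an
  abnormal recording", description "20 Hz beta spindles in central
  regions", medications "Keppra". The event raises 14–30 Hz central band
  power ≥ 3 dB over non-event channels.
* Normal class: a *sustained* posterior dominant alpha rhythm (10 Hz,
  70 µV posterior / 25 µV widespread, overlap-added 4 s pieces with
  frequency jitter) rather than bursts — the morphology of eyes-closed
  alpha — giving the pooled spectrum its peak in 8–12 Hz above the 1 Hz
  floor. Impression "This is a normal recording", medications "Aspirin".
* Sharp waves are periodic raised-cosine-rise / exponential-decay
  transients recurring at the stated rate.
* Reports fill the three highest-coverage sections plus medications, with
  distractor sentences shared across classes so text length alone cannot
  separate them. Metadata: age uniform 18–85, gender fair coin —
  deliberately uninformative, so only the pathological and medication
  tasks are decodable in the default two-class world.

What a green end-to-end test establishes: the full loop — generation,
preprocessing, pairing, contrastive optimization, zero-shot prompting,
probing, attribution — is wired correctly and can recover a *strong,
stationary, class-pure* spectral contrast. What it does not establish:
performance on real clinical EEG, whose events are rarer, non-stationary,
artifact-laden and label-noisy, and whose reports are far more varied.

## Runtime scaling of the test suite

Tests and the synthetic end-to-end runs use reduced encoder widths
(8/16/32/64) and batch size 32 so the suite fits a single-CPU budget;
these are configuration knobs of the architecture, and the defaults remain
25/50/100/200 and batch 64. Corpus size (200 recordings), the 60/20/20
split, the few-shot fractions (down to 1/50), all thresholds and all
tolerances are used as stated, unscaled.

## Known limitations

* No pretrained language model is bundled; zero-shot transfer to *novel*
  phrasings therefore depends on the user supplying one — the bundled
  encoders generalize only lexically.
* EDF binary I/O is out of scope for this build (no reader available in
  the target environment); the reader contract is documented and a
  plain-text container stands in for interchange.
* Attribution maps are descriptive, not causal; they are validated against
  linear oracles and injected events, not against clinical judgement.
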