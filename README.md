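# eegalign

Contrastive alignment of clinical EEG recordings with the free text of
their medical reports, in pure R.

## The problem

Deep networks for EEG decoding are usually trained per task (pathology,
age, …) and their representations transfer poorly. Clinical archives,
however, pair every recording with a neurologist's report — a rich,
untapped supervision signal. `eegalign` implements the CLIP-style recipe
for this setting: a convolutional EEG encoder and a text encoder are
trained so that windows of a recording and the text of *its own* report
land close together in a shared 64-dimensional embedding space, while
mismatched window–report pairs are pushed apart. The aligned space then
supports

* **zero-shot classification** — describe each class by a sentence
  ("This is a normal recording" / "This is an abnormal recording") and
  classify a recording by its nearest prompt embedding, with no labels;
* **frozen-encoder probing and few-shot transfer** — small heads trained
  on the frozen 128-d EEG embeddings;
* **frequency-domain attribution** — gradients of the EEG–prompt cosine
  similarity with respect to the windows' Fourier coefficients, resolved
  by electrode and frequency.

For matched projections $(x_i, y_i)$ in a batch of $N$, the loss is the
InfoNCE objective

$$\mathcal{L} = \frac{1}{N}\sum_{i=1}^{N}-\log\frac{\exp(\operatorname{sim}(x_i,y_i)/\tau)}{\sum_{j=1}^{N}\exp(\operatorname{sim}(x_i,y_j)/\tau)}$$

with cosine similarity, a learnable temperature, and (by default) the
symmetric average of the EEG→text and text→EEG directions.

The EEG encoder is a four-block convolution–max-pool network (Deep4
lineage: temporal then spatial convolution, batch norm, ELU, dropout)
producing a 128-d embedding; both modalities pass through 3-layer MLP
projection heads. Preprocessing follows the standard clinical pipeline:
21-electrode 10-20 montage, crop to seconds 60–180, clip to ±800 µV,
resample to 100 Hz, divide by 30, windows of 1200 samples with stride
519. All neural-network primitives (convolution, batch norm, Adam,
backprop) are implemented in-package on BLAS matrix operations — no
deep-learning runtime is required — with gradient correctness enforced by
finite-difference tests.

Because the clinical corpus this pipeline targets is access-gated, the
package ships a first-class synthetic generator of paired EEG + report
data (1/f background, shared posterior alpha rhythm, class-defining
spectral events, templated reports), so the entire pipeline is testable
end to end offline.

## Worked example

```r
library(eegalign)

# a paired synthetic corpus: abnormal (20 Hz central beta bursts, "Keppra")
# vs normal; both classes share the same 1/f + posterior-alpha background,
# so the beta event is the only class-discriminative EEG feature
corpus <- generate_corpus(corpus_spec(n_recordings = 200, seed = 7))
prep   <- prepare_paired_data(corpus)          # preprocess + pair windows
labels <- setNames(prep$manifest$pathological, prep$manifest$id)

plan <- split_plan(prep$manifest$id, labels, seed = 7)   # 60/20/20
train <- prep$pairs
keep  <- train$recording_ids %in% plan$contrastive_train
train$recording_ids <- train$recording_ids[keep]
train$windows <- train$windows[train$recording_ids]
train$texts   <- train$texts[train$recording_ids]

# 20-epoch stages until the loss leaves the log(batch)-level plateau
model <- NULL; epoch <- 0
repeat {
  cfg <- train_config(epochs = 20, batch_size = 32, seed = 7 + epoch,
                      eeg_widths = c(8, 16, 32, 64), temperature_init = 5)
  fit <- train_clip(train, cfg, model = model)
  model <- fit$model; epoch <- epoch + 20
  cat(sprintf("epoch %d: mean loss %.3f\n", epoch, tail(fit$loss_history, 1)))
  if (tail(fit$loss_history, 1) < 3.0 || epoch >= 80) break
}
#> epoch 20: mean loss 2.739

preds <- zero_shot_classify(model, prep$pairs$windows[plan$eval],
                            task = "pathological")
balanced_accuracy(preds, labels[plan$eval])
#> [1] 1
```

The loss starts at the uniform-similarity plateau (about `log(32)` ≈ 3.5
for batch 32) and drops below 3 once matched pairs align; here seed 7
escapes within the first 20-epoch stage. The zero-shot prompts — never
paired with any task labels — then separate the 40 held-out recordings
perfectly in this strongly separable synthetic world. A balanced accuracy
of 1 validates the pipeline's wiring, not clinical performance. Runtime is
roughly two minutes per 20-epoch stage on one CPU at these reduced widths.

Attribution of the abnormal-class prompt localizes to the injected event:

```r
w <- prep$pairs$windows[plan$eval[labels[plan$eval]]][[1]]
att <- frequency_gradients(model, w,
                           prompt = "20 Hz beta spindles in central regions",
                           channel_names = default_montage())
att$grid[which.max(att$pooled)]   # pooled spectral peak, Hz
#> [1] 20.25
```

## Command line

`exec/eegalign` exposes the pipeline over a plain-text corpus layout:

```sh
eegalign synth      --n 40 --seed 7 --out corpus/
eegalign labels     --data corpus/ --out labels.csv
eegalign train      --data corpus/ --out ckpt.rds --epochs 40 --widths 8,16,32,64
eegalign zeroshot   --ckpt ckpt.rds --data corpus/ --task pathological
eegalign gradients  --ckpt ckpt.rds --data corpus/ --prompt "20 Hz beta spindles in central regions" --out map.rds
```
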