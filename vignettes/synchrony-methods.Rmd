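---
title: "Measuring dyadic speech synchrony with cross-partner autoencoders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring dyadic speech synchrony with cross-partner autoencoders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadsync)
```

## The model

`dyadsync` treats interpersonal synchrony as a *distributional* question:
are the frame-level acoustic features of speaker B drifting toward the
feature distribution of speaker A (and vice versa) over the course of one
conversation?

The instrument for "distance from a distribution" is a bottleneck
autoencoder. An autoencoder trained on one speaker's frames learns a
compact representation of that speaker's feature distribution; the
reconstruction error of an *unseen* frame then acts as a novelty score —
frames close to the training distribution reconstruct well, frames far
from it reconstruct poorly. For each session the package trains one
autoencoder per speaker on that speaker's own frames (every 10 ms frame is
an independent training instance; temporal order is ignored during
training), then reconstructs each speaker's frames, order preserved, with
the *partner's* model. The per-frame root-mean-square error across feature
dimensions gives two scalar traces per session, and the ordinary
least-squares slope of each trace over session-normalized time
`t ∈ [0, 1]` is the synchrony statistic: negative means the tested
speaker's frames are moving into the partner's distribution.

Two aggregates summarize a group of sessions: the average of all `2n`
speaker slopes (overall tendency of the group to converge), and the
Pearson correlation between partner slope pairs across sessions, which
separates "both partners adapt together" (positive) from "one partner does
the adapting" (negative).

Key assumptions, stated plainly:

* The slope only carries meaning *relative to other slopes computed the
  same way*. Its magnitude depends on the feature scaling and on the
  regression axis; the package fixes the axis to normalized session time
  so sessions of different length are comparable.
* Frame independence. The autoencoder sees frames, not trajectories;
  synchrony in purely temporal structure (rhythm, turn timing) is
  invisible to it.
* Within-session stationarity of everything *except* the convergence being
  measured. A recording-environment change mid-session would masquerade as
  (de)synchronization.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `frame_step` | 0.010 | s | standard LLD frame rate |
| architecture | halving rule; `130-64-32-12-32-64-130` at d=130, `4096-...-512-...` at d=4096 | neurons | canonical bottleneck shapes for these two feature sets; generic rule `d/2, d/4, d/8` mirrored |
| `batch_size` | 256 | frames | reference training recipe |
| `epochs` | 512 | — | reference recipe; corpus-scale runs in this package's own studies use 64, which reaches the same plateau on the small architectures |
| `learning_rate` | 0.01 | — | Adagrad step size of the reference recipe |
| `slope_method` | `"ols"` | — | least squares over normalized time; `"mean_first_difference"` offered as the telescoped mean of consecutive differences |
| `overlap` (segmentation) | `"drop"` | — | frames where both speakers talk attribute to neither model cleanly |
| standardization | on, per recording | — | removes channel/environment variance; **off** for spectrogram-CNN embedding features, which degrade when rescaled |

Word-usage similarity uses the shared-type count normalized by mean tokens
per speaker, with range `[0, 2]`; similarity above 1 simply means shared
types dominate both speakers' token mass, which is common. A min-count
variant and a type-level Jaccard variant are available behind the `method`
argument but are non-default (they compress the dynamic range and, for
Jaccard, ignore token frequency entirely).

## Numerical choices

* **Standardization** uses the population (1/N) standard deviation;
  dimensions with standard deviation below `1e-8` are set to zero rather
  than divided by a vanishing scale. Standardization is exactly idempotent
  up to floating error.
* **Deltas** are plain first differences with `d[1] = 0`. Toolkits that
  compute deltas by local regression windows produce slightly different
  values; tables that already contain deltas should skip the op.
* **Frame-to-turn assignment** is by frame *start* time against half-open
  turn intervals `[start, end)`, frames 0-based in time. Half-open
  intervals make tiling exact: abutting turns never double-assign a frame.
* **Conversation halves** split at the midpoint of the transcript's time
  span; a turn belongs to the half containing its start, and the midpoint
  itself opens half 2.
* **The mean-first-difference slope** is computed in telescoped closed form
  `(y_n − y_1)/(t_n − t_1)`. Averaging `diff(y)` is mathematically
  identical but not bit-identical in floating point; the closed form makes
  the identity exact and costs nothing.
* **Autoencoder training**: He-normal weight initialization
  (`sd = sqrt(2/fan_in)`, recorded in the fitted object), zero biases,
  ReLU hidden layers, linear output, per-epoch reshuffling, last partial
  batch kept, Adagrad accumulator eased by `eps = 1e-8`. Initialization
  and shuffling derive from a single integer seed, so fits are exactly
  reproducible; the second autoencoder of a session uses `seed + 1`.
* **Training loss** is recorded per epoch as the mean per-element squared
  error over the frames as visited (the conventional running training
  loss). Non-finite loss aborts with the epoch number.
* A deliberate consequence of this recipe: on very small training sets the
  fixed budget of Adagrad steps drives the network toward the best smooth
  low-dimensional embedding of the data (close to the PCA residual of the
  bottleneck width), *not* toward exact memorization. Reconstruction
  errors should therefore be read as distribution distances, never as
  evidence that the model stores individual frames.

## What the synthetic generator emulates — and what it does not

`generate_dyad()` draws speaker A's frames from `N(mean_a, σ²I)` and
speaker B's from a Gaussian whose mean moves linearly from `mean_b0`
toward `mean_a`, closing fraction κ of the gap by session end (with
`symmetric = TRUE`, both speakers move toward the midpoint, closing κ/2
each). Defaults: 16 dimensions, 60 s sessions of alternating 5 s turns,
10 ms frames (3000 frames per speaker), unit noise, an initial mean gap of
2 per dimension — separation of the same order as the noise, so
convergence is detectable but not trivial. Transcript tokens come from a
shared pool with per-half probability (`shared_vocab_half1/2`, defaults
0.2/0.2) and speaker-private pools otherwise.

This emulates exactly the statistical structure the slope statistic
assumes — partner distributions that approach each other in mean — and
nothing else. Real conversational audio has turn-level autocorrelation,
non-Gaussian and multimodal feature distributions, silence and laughter,
channel bleed between speakers, and convergence that is episodic rather
than linear. Passing the package's tests therefore demonstrates that the
estimator recovers distributional convergence when it is present and stays
at zero when it is absent; it does not certify performance on any real
corpus.

The embedding generator places same-topic words inside a fixed angular
cone (half-angle 20°) around a topic centroid, which guarantees a
same-topic cosine of at least `cos(40°) ≈ 0.77` — a construction chosen
for its provable bound rather than for distributional realism.

## Design decisions

* **Spectrogram hop.** The spectrogram front end this package mirrors is
  described with a 500 ms window and "10 ms overlap"; read literally that
  is a 490 ms hop, but every other component of the pipeline runs at a
  10 ms frame *step*. The default is `hop_seconds = 0.010` (490 ms of
  overlap between successive windows) so spectrogram frames align with the
  LLD frames; the literal reading is one config value away
  (`hop_seconds = 0.49`).
* **Slope axis.** Regressing on normalized session time makes slopes
  session-length invariant, at the cost of making magnitudes
  incomparable with slope values computed per frame index or per second.
  Comparisons should stay within one convention; the per-step trend is
  also reported (`slope_per_step`).
* **Overlapping speech** is dropped by default. Attributing simultaneous
  speech to both speakers ("both") is supported for sensitivity analysis
  but lets each autoencoder train on frames containing the partner's
  voice.
* **PCC pairing** takes speaker A as the first speaker to talk in the
  transcript. Any fixed convention works; this one is observable from the
  data alone.
* **No trace smoothing** before the regression by default: OLS over
  thousands of frames is already an aggressive noise reducer, and
  smoothing induces autocorrelation that flatters the fit. A centered
  moving average is available (`smooth_window`) for exploration.
* **Directional convergence by default** in the generator (only B moves).
  It is the harder case for the statistic — only one of the two traces
  carries signal — and it reproduces the "one partner dominates" regime
  that shows up as negative pair correlations.

## Problem sizes

The package's own validation studies run at: 60 s sessions (3000 frames
per speaker, 16 dims), 64 training epochs, 10 sessions per group, and 10
replicate seeds for stochastic properties; estimator-level checks
(slope/correlation oracles) use up to 1000-frame traces. These sizes give
stable Monte-Carlo majorities while keeping a full run in the minutes
range on one CPU core.

## Known limitations

* Slope magnitudes are not comparable across feature sets or scaling
  conventions; only signs and within-convention comparisons are
  interpretable.
* A session-long monotone confound (speaker fatigue, level drift not
  removed by standardization) is indistinguishable from synchrony.
* The linguistic measures ignore word order and syntax entirely; the
  embedding similarity in particular pools each speaker's half into one
  mean vector, which washes out topic shifts inside a half.
* The mel-spectrogram utility covers the front end of spectrogram-CNN
  pipelines, but no pretrained network ships with the package; CNN
  embeddings must be computed externally (or any function honoring the
  `embedding_backend()` contract plugged in) and read back as feature
  tables.
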