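---
title: "Disorder prediction with boosted deep belief networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disorder prediction with boosted deep belief networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Intrinsically disordered regions (IDRs) are protein segments that do not
adopt a stable tertiary structure in their native state. They are common,
functionally important (signalling, transcription, binding through
disorder-to-order transitions) and systematically depleted in crystal
structures, which makes their sequence-based prediction a standard
structural-bioinformatics task. `idrboost` implements a complete
prediction stack for this task: windowed sequence-profile features, deep
networks pretrained as restricted Boltzmann machines (RBMs), a modified
AdaBoost ensemble per window configuration, averaging across
configurations, and a CASP-style evaluation suite. Everything is
trainable and testable at desk scale on the package's own synthetic data
generator.

## Feature encoding

Each residue contributes a 31-value feature row, all scaled to $[0,1]$:

* 2 binary solvent-accessibility inputs (exposed `10`, buried `01`),
  from an ACCpro-style two-state prediction;
* 3 binary secondary-structure inputs (alpha `100`, beta `010`, coil
  `001`), from an SSpro-style three-state prediction;
* 5 Atchley factors — the published five-dimensional numerical summary
  of amino-acid physicochemical variation — min-max rescaled per factor
  over the 20-residue table so each lies in $[0,1]$. Ambiguity codes
  (B, Z, X, U, J, O) receive the neutral value 0.5 per factor;
* 1 PSSM information content, divided by 6 and clamped to $[0,1]$
  (per-position information is bounded near $\log_2 20 \approx 4.3$
  bits, so 6 leaves headroom; the upstream requirement is only that
  inputs lie in the unit interval);
* 20 PSSM likelihoods — the percentage columns of the PSI-BLAST ASCII
  matrix divided by 100.

A classifier input is a window of `l_in` consecutive slots (20, 25 or 30)
around a target window of `l_tgt` residues (3, 5 or 7). Each slot carries
the 31 residue features plus one in-bounds flag; slots beyond the sequence
ends are all-zero with flag 0. Four protein-level features are appended:
fraction exposed, fraction helix, fraction sheet, and the relative
position of the target centre (`center / length`, 1-based). The input
dimension is therefore $32 \, l_\mathrm{in} + 4$: 644, 804 and 964 for
windows of 20, 25 and 30.

Two conventions were genuinely open and are fixed as follows. The context
around the target window is split left-heavy
(`ceiling((l_in - l_tgt)/2)` slots before the first target residue);
target windows slide with stride 1, so every residue centres exactly one
example per window configuration. We note that $32 \cdot 25 + 4 = 804$,
while the commonly quoted feature count for the middle window size is
772, which corresponds to a 24-slot window ($24 \cdot 32 + 4$); the
package implements the stated 25-residue window and documents the
discrepancy rather than silently changing the window.

Residues labelled `X` (unclassified by assessors) stay in sequence
coordinates, contribute target value 0, and are masked out of every loss;
in evaluation they are counted as not disordered.

## Restricted Boltzmann machines

An RBM defines the energy
$E(v,h) = -\sum_i a_i v_i - \sum_j c_j h_j - \sum_{i,j} h_j v_i w_{ij}$
and the visible marginal $p(v) = \sum_h e^{-E(v,h)} / Z$. For machines
with $n_v + n_h \le 20$ the package computes $p(v)$ exactly (closed-form
marginalisation of the hidden layer), and the test suite checks it
against a brute-force enumeration of every joint state — this is the
oracle that anchors the CD-1 implementation.

Training is single-step contrastive divergence with batch means:

* positive statistics from the data and the hidden activation
  probabilities $p^{(0)} = \sigma(vW + c)$;
* negative statistics from one reconstruction step: hidden states
  sampled from $p^{(0)}$, a probabilistic visible reconstruction
  $p^{(1,v)} = \sigma(hW^\top + a)$ (probabilities, not samples), and a
  probabilistic second hidden pass $p^{(1,h)}$;
* learning rates 0.01 (weights) and 0.1 (biases), weight cost 0.0002 on
  weights only, momentum 0.5 rising to 0.9 after 5 epochs, 20 epochs in
  batches of 100. Momentum is applied uniformly to weights and both bias
  vectors.

Weights initialise from $\mathcal N(0, 0.01^2)$; hidden biases at 0. By
default visible biases start at the logit of each feature's mean
activity. On wide, sparse inputs like the windowed encodings, zero-start
visible biases make early reconstructions far brighter than the data,
which drives hidden biases up until the layer saturates; the logit-mean
start (standard practice in the practical CD-training literature) removes
that transient. `train_rbm(..., init_visible_bias = "zero")` restores the
plain start.

## Deep networks

Hidden layers are pretrained greedily: RBM $k$ trains on the
deterministic activation probabilities of RBM $k-1$ over the full
dataset. A sigmoid output layer is then trained on the top activations
(10 epochs by default), and the whole network — all layers — is
fine-tuned by backpropagation on masked Bernoulli cross-entropy, 25
epochs in batches of 1000 at full scale. The fine-tuning optimizer is
plain mini-batch gradient descent; no rate is published for this step, so
the package uses 0.1 as the default (matching the RBM bias rate) and
exposes it. Backpropagation is verified against central finite
differences to a relative error below $10^{-5}$ — the decisive
correctness check for this module.

The full-scale architecture is `d_in`-750-750-350-`l_tgt`. All sizes are
configuration, not code: tests and the desk preset use reduced stacks
(24-12 hidden units).

## Modified AdaBoost

Per window configuration, the training pool holds one example per residue
of every training protein. Each round $t$:

1. every seventh round the pool probabilities $W_t$ reset to uniform
   (rounds 8, 15, 22, 29) — without this, a few hard examples come to
   dominate sampling and members stop generalising;
2. a sample (60,000 at full scale) is drawn i.i.d. with replacement from
   $W_t$;
3. a deep network $m_t$ is pretrained and fine-tuned on the sample;
4. the full pool is evaluated: an example is misclassified when any
   unmasked target residue is on the wrong side of 0.5 (ties classify as
   disordered); $\epsilon_t$ is the summed probability of misclassified
   examples, and $\alpha_t = \tfrac12 \ln \frac{1-\epsilon_t}{\epsilon_t}$;
5. correct examples scale by $e^{-\alpha_t}$, misclassified ones by
   $e^{\beta_i \alpha_t}$ with $\beta_i$ the count of misclassified
   target residues, then $W_{t+1}$ renormalises.

Members with $\epsilon_t \ge 0.5$ are retained with $\alpha_t = 0$ (they
contribute nothing to the vote); $\epsilon_t = 0$ is clamped to
$10^{-10}$ with a warning. An alternative fractional error rule (each
example weighted by its misclassified share of the window) is available
behind `error_rule = "fraction"`; the any-residue rule is the default
because the reweighting explicitly targets partially misclassified
examples. With $\beta \equiv 1$ and a single-residue target, one round
reduces exactly to textbook binary AdaBoost reweighting, which the test
suite checks against an independent implementation.

The ensemble score is the performance-weighted vote share
$H(x) = \sum_{t: m_t(x) > 0.5} \alpha_t \big/ \sum_t \alpha_t$,
componentwise over the target window. The vote condition uses strict
`> 0.5` as specified for $H$, while the hard classification $h_t$ uses
`>= 0.5`; the difference is measure-zero and documented.

At full scale there are 35 rounds for each of the five window
configurations 20→3, 25→3, 25→5, 30→5 and 30→7, i.e. 175 base
predictors. (One passage lists 30→3 in place of 30→5; the package
follows the configuration list given with the training description and
surfaces the discrepancy here.)

## From windows to residues

Within one ensemble, stride-1 target windows overlap: residue $i$ is
covered by up to `l_tgt` windows. Its score is the unweighted mean of the
in-bounds window outputs covering it — the simplest defensible
aggregation; nothing is published about this step. Ensemble tracks are
then averaged unweighted across window configurations, and optionally
averaged once more with an external predictor's per-residue score track
(the meta configuration). The decision threshold defaults to 0.5 with
ties called disordered.

## Evaluation

Positive means disordered. From TP/FP/TN/FN at a threshold: sensitivity,
specificity, balanced accuracy $(\mathrm{SENS}+\mathrm{SPEC})/2$,
$S_w = \mathrm{SENS}+\mathrm{SPEC}-1$, and the F-measure
($F_1$ with precision $\mathrm{TP}/(\mathrm{TP}+\mathrm{FP})$; the
F-measure is named but not printed in the source literature, so the
standard form is used, and undefined precision reports $F = 0$). The ROC
sweeps all distinct scores and integrates trapezoidally, which equals the
tie-corrected Mann–Whitney probability; the suite verifies this against
exhaustive pair counting and against an independent ROC implementation.

Standard errors use the published recipe: 80% of the predicted residues
resampled 1000 times,
$SE(\Theta) = \sqrt{\sum_i (\Theta_i - \Theta)^2 / 1000}$ with $\Theta$
the full-data value. Whether the original resamples were drawn with or
without replacement is not stated; the package subsamples without
replacement by default (the literal reading of sampling 80% of the
residues) and offers `replace = TRUE`. A resample on which a metric is
undefined is redrawn and reported.

## Synthetic data

The generator emulates the statistics of the curated training sets this
class of predictor is built on, without any download:

* lognormal protein lengths (meanlog 5.0, sdlog 0.45; median ≈ 150),
  minimum 31 residues;
* every protein carries at least one disordered region of ≥ 3 residues;
  region lengths are 3 + Geometric(0.15) (mean ≈ 8.7), placed at each
  terminus with probability 0.3 and internally at a Poisson rate derived
  in closed form from the target disorder fraction (default 6.5%), with
  a fixed-point correction for the mandatory-region fallback so the
  realized fraction tracks the target by construction;
* features couple to the labels with strength `coupling` ∈ [0,1]:
  disordered residues draw from a disorder-promoting composition
  (P/E/S/Q/K/G enriched, W/C/F/I/Y/V depleted), have coil probability
  0.45 + 0.45·coupling and exposure probability 0.45 + 0.40·coupling,
  and get flatter PSSM likelihood rows with lower information content —
  the low-complexity character of real disorder, and the mechanism by
  which the PSSM channel carries signal. At `coupling = 0` features are
  independent of labels and any predictor's held-out AUC sits at 0.5;
* `X` labels are injected at 1% over ordered positions (so the mandatory
  region survives in the labels) to exercise the exclusion rule;
* predicted-track noise: each SS/SA state is resampled uniformly with
  probability 0.1, emulating upstream predictor error.

What the generator does **not** model: homology between proteins,
realistic secondary-structure segment grammar, position-dependent profile
correlations, or length/disorder coupling. Tests passing on this data
show that the pipeline learns genuinely coupled signals at realistic
class imbalance — not that it reaches any particular accuracy on real
proteins.

## Presets, sizes and numerical choices

The `paper` preset carries the full published sizes (five ensembles,
750-750-350 hidden layers, 35 rounds × 60,000 samples — days of CPU) and
refuses to launch without `allow_long = TRUE`. The `desk` preset is the
package's own reduced configuration used throughout the tests and the
acceptance script: 24-12 hidden units, 2 RBM epochs, 5 output-layer
epochs, 30 fine-tuning epochs in batches of 100 at rate 0.5, 3 boosting
rounds over 1,500-example samples, training pools of roughly 30 proteins
(≈ 4,500 windows). At this scale the five-ensemble pipeline trains in
about half a minute on one CPU and reaches held-out AUC above 0.9 on
default-coupling synthetic data; the boosting demonstration uses 10
rounds so the reinitialisation at round 8 is exercised.

Numerical choices: sigmoids are computed stably (`plogis`) and clamped to
$[10^{-12}, 1-10^{-12}]$ so cross-entropy stays finite; the final short
batch of every epoch is used as-is; sampling uses R's RNG exclusively, so
a single seed makes simulation, training and prediction bit-reproducible.

## Known limitations

The package consumes PSI-BLAST/SSpro/ACCpro **outputs**; it does not run
those tools, and on real sequences its accuracy is bounded by the quality
of those upstream predictions. Scores from real CASP-scale training are
not reproducible at desk scale; the acceptance script reports the
desk-scale quantities it actually computes. The per-ensemble vote share
$H$ is a step function of member votes, so single-member ensembles give
coarse, few-valued score tracks; score resolution comes from combining
rounds and window configurations.
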