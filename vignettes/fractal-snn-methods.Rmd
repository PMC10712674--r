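---
title: "Fractal spiking neural networks for EEG classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractal spiking neural networks for EEG classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsnn)
```

## Overview

`fsnn` fits a spiking neural network classifier to multichannel EEG whose
architecture is generated by a fractal expansion rule. The pipeline has five
stages: feature extraction, per-channel multi-head self-attention, the
fractal spiking block, a spiking readout with a small linear head, and a
softmax classifier. This vignette explains each model component, the
numerical and design choices behind the implementation, and what the
synthetic data used in the tests does and does not demonstrate.

## Feature extraction

Raw EEG arrives as a channels-by-samples matrix with a sampling rate. The
preprocessing convention is:

1. optionally keep only the trailing 60 s of a trial (`last_seconds()`),
2. a zero-phase 4th-order Butterworth bandpass, 4–60 Hz by default
   (`bandpass()`; forward–backward filtering avoids phase distortion, the
   standard EEG practice),
3. per-channel z-scoring over the whole retained interval (`preprocess()`).

Each channel is then band-filtered once per frequency band — theta (4–8 Hz),
alpha (8–14 Hz), beta (14–30 Hz), gamma (30–45 Hz) — and cut into sliding
windows (1 s window, 0.5 s step by default). Filtering the whole channel
before windowing, rather than filtering each 1-s window separately, avoids
per-window filter transients; the difference is confined to window edges.
Two features are computed per window and band:

* **PSD** — the mean Hann-tapered periodogram density inside the band;
* **DE** — differential entropy under the Gaussian convention,
  $\tfrac12\log(2\pi e\,\sigma^2)$, with $\sigma^2$ the variance of the
  band-limited window. This closed form is the convention of the DE feature
  lineage used by the public EEG-emotion feature sets. Zero-variance windows
  would give $-\infty$; they are clipped at a configurable floor
  (default −20).

The rows of the resulting feature matrix $X \in \mathbb{R}^{n\times m}$
($n$ features, $m$ channels) are grouped into contiguous band blocks in the
configured band order; inside a band the PSD rows precede the DE rows, each
ordered by window index. The layout travels with the matrix (as an attribute
and in the on-disk TSV header) so that band-block indexing — used by
saliency analysis and the synthetic generators — is always explicit.
Five-band (delta-inclusive) matrices of the feature-only databases are
*read* and consumed by the model; only the four-band layout above is
*produced* from raw signal.

## Per-channel self-attention

Each channel's feature vector is processed independently. With $h$ heads the
length-$n$ vector is split into $h$ parts of $d = n/h$; head $\alpha$
computes $q = W_\alpha^{(q)}x$, $k = W_\alpha^{(k)}x$, $v = W_\alpha^{(v)}x$
and the scaled dot-product attention

$$\mathrm{softmax}\!\left(\frac{q k^{\top}}{\sqrt{n/h}}\right) v,$$

where $qk^\top$ is the $d\times d$ outer product and the softmax is applied
row-wise. The concatenated head outputs are mixed by an $n\times n$ output
matrix. No bias terms are used anywhere in the module. A degenerate reading
of the same formula treats $q k^\top$ as a scalar, whose softmax is
identically 1 and makes attention a plain linear map; the outer-product
reading is adopted because it is the only one in which the attention weights
depend on the input at all. With $d = 1$ the two readings coincide and the
head reduces to its value map.

Initialization puts the value and output matrices near the identity and the
query/key matrices near zero, so an untrained module is close to
mean-pooling within head parts — a stable starting point that leaves the
input distribution essentially unchanged at epoch one.

## Spiking primitives

The sequence axis of all spiking dynamics is the **channel axis**: channels
are the recurrence steps, feature rows index synapses/neurons. Filter states
are zeroed at every forward pass because every EEG sample restarts the
channel sequence.

**Axon** is a bank of independent second-order IIR synapse filters,

$$f[i] = \alpha_1 f[i-1] + \alpha_2 f[i-2] + \beta x[i],$$

with $\alpha_1 = e^{-1/\tau_m} + e^{-1/\tau_s}$,
$\alpha_2 = -e^{-(\tau_m+\tau_s)/(\tau_m\tau_s)}$ and
$\beta = e^{-1/\tau_m} - e^{-1/\tau_s}$. Its impulse response is
$e^{-i/\tau_m} - e^{-i/\tau_s}$, the keystone oracle of the test suite.
Equal time constants make $\beta = 0$ (a dead filter) and are rejected at
configuration time. Because the filter is linear and time-invariant, its
exact gradient is the same filter run on the time-reversed upstream
gradient.

**Soma** applies a learnable weight matrix, a threshold, and a decaying
reset filter. The printed equations define the membrane potential from the
reset value at the same step while the reset value depends on the spike at
that step; the implementation breaks this cycle by sequencing each channel
step as: decay the reset filter, compute the potential, fire, then add the
reset increment:

$$\tilde r = e^{-1/\tau_r} r_{i-1},\quad
  v_i = -\lambda \tilde r + W f_i,\quad
  y_i = U(v_i - V_{\mathrm{thre}}),\quad
  r_i = \tilde r + V_{\mathrm{rest}}\, y_i ,$$

which honours both update equations half a step apart. Firing is strict
($v > V_{\mathrm{thre}}$, $U(0)=0$), so spike matrices are exactly binary;
raising the threshold can only remove spikes — within a step trivially, and
across steps because fewer spikes also mean weaker subsequent reset
inhibition is impossible (the reset only ever *lowers* potentials, so the
per-step spike count is monotone in the threshold; the test suite asserts
the aggregate form of this property).

Backpropagation through the Heaviside step uses a triangular surrogate
$\max(0, 1 - |x|/w)/w$ (width $w = 1$ by default); everything else —
the reset recurrence included — is differentiated exactly by
backpropagation through time along the channel axis.

The six neuron hyperparameters are fixed, not learned: only the soma weight
matrices, the attention matrices and the head learn. Defaults are
$\tau_m = 8$, $\tau_s = 2$, $\tau_r = 2$, $\lambda = 1$,
$V_{\mathrm{rest}} = 1$, $V_{\mathrm{thre}} = 0$ (a threshold near zero
keeps roughly half the neurons active at initialization given the
$1/\sqrt{n}$ weight scale). All are package choices, configurable through
`neuron_config()`.

## The fractal block

Blocks are generated by the expansion rule

$$F_1(X) = \mathrm{Axon}(X), \qquad
  F_{c+1}(X) = \mathrm{Sum}\{(F_c \circ \mathrm{Soma} \circ F_c)(X),\;
  \mathrm{Axon}(X)\}.$$

$F_c$ has $c$ aligned columns (sub-paths) of axon depths
$2^{k-1}, k = 1..c$, $2^{c-1}-1$ soma junctions and as many sum layers.
Every soma owns an unshared $n \times n$ weight matrix (nothing in the
architecture calls for sharing, and unshared weights let the two halves of
each expansion specialize); axons carry no learnable parameters. "Columns"
are defined by the aligned expansion — the sub-networks one obtains by
consistently keeping either the long or the short branch at every sum
layer; mixed-depth combinations are reachable during drop-path training but
are not enumerated as columns. `column_masks()` produces the forced masks
that evaluate any single column, supporting sub-network analysis.

The order-2 block is additionally implemented by hand
(`f2_forward_explicit()`) as
$\mathrm{Axon}(X) + \mathrm{Axon}(\mathrm{Soma}(\mathrm{Axon}(X)))$ and
serves as a bit-exact oracle for the generic recursive evaluator.

### Inverted drop-path

During training each sum-layer input is kept independently with probability
$1-p$ and the sum of survivors is rescaled by $1/(1-p)$; at test time the
plain unscaled sum is used, making evaluation deterministic. The rescaling
keeps the training-time expectation equal to the test-time sum, which is the
point of the *inverted* variant (the classic variant scales at test time
instead; `drop_config(mode = "plain")` reproduces it, and `"none"` disables
dropping). The all-paths-dropped outcome is possible under the raw Bernoulli
rule; the implementation redraws until at least one path survives, matching
drop-path practice. The redraw introduces a small upward bias in the
expectation, so the unbiasedness test and the acceptance script disable the
guard (`redraw = FALSE`) when checking the Monte-Carlo mean against the
plain sum. Masks are drawn once per sum layer per forward call; the training
loop runs one batched forward per epoch, so a mask realization is shared by
the epoch's batch — a deliberate trade of mask diversity for an order of
magnitude of speed in pure-R training.

Defaults: order $c = 3$ and $p = 0.15$.

## Readout and classification head

The fractal output passes through a readout soma with $n_1$ neurons
($n_1 = n$ by default), giving a binary spike matrix
$Y_o \in \{0,1\}^{n_1 \times m}$. A linear layer doubles the feature
dimension ($2n_1$), a leaky ReLU (slope 0.01) follows, a second linear layer
maps to $z$ class logits per channel, and a learnable channel-weight vector
pools the per-channel logits into a single length-$z$ logit vector that a
softmax converts to class probabilities. The two linear layers carry biases;
the pooling weights do not. Cross-entropy on the softmax output is the
training loss — the head ends in a softmax over emotion classes and no
other loss is implied anywhere.

With the reset filter decoupled ($\lambda = 0$) the head is a per-channel
map and commutes with channel permutations exactly when the pooling weights
are permuted along; with the recurrence active, channel order deliberately
carries information and exact equivariance does not hold.

## Training

Full-batch Adam (learning rate $10^{-3}$, weight decay $10^{-4}$ on weight
matrices but not biases or pooling weights), 60 epochs by default. Sixty
epochs take the cross-entropy on the reference synthetic task from ~0.8 to
order $10^{-3}$; longer schedules change nothing but runtime at this
problem scale, and all schedule parameters are configurable. Regularization
comparisons (inverted drop-path vs none) use a longer schedule — 150 epochs
— so that both arms reach full training accuracy and the comparison
measures generalization rather than optimization speed; drop-path roughly
doubles the epochs needed to converge because each step trains a random
sub-network. Each
cross-validation fold re-initializes its model from a fold-specific seed
derived from the protocol seed, so no state leaks between folds and a fixed
seed reproduces fold assignment, weights and metrics exactly. Divergence
(non-finite loss) aborts with the epoch number rather than continuing
silently.

Training loss under inverted drop-path is stochastic epoch to epoch: each
epoch evaluates a different random sub-network. Convergence statements in
the tests therefore use a 10-epoch trailing moving average and tolerate
increases up to 0.5% of the total loss range.

## Evaluation protocols

`make_folds()` implements the two protocols used for subject-dependent and
subject-independent evaluation: seeded shuffled $k$-fold partitions (18
samples with $k=9$ give per-fold test sets of 2 and training sets of 16; 40
with $k=10$ give 4 and 36), and leave-one-subject-out, one fold per subject.
`fsnn_cv()` reports per-fold accuracies and their mean and sd; with LOSO the
per-subject accuracies are reported so means are taken within subject first,
then across subjects. Affect ratings are binarized at the scale midpoint
(`binarize_rating()`): high iff the rating is not less than the midpoint.
`mask_channels()` removes channel columns (for symmetric channel-disabling
studies); the model width adjusts on refit.

## Diagnostics

**Saliency** backpropagates the pre-softmax logit of a chosen class to the
input (surrogate gradients through the spikes), takes absolute values and
min-max normalizes. The pre-softmax convention makes the map invariant to
positive rescaling of the logits; the gradient-magnitude convention discards
sign. An all-zero gradient returns an all-zero map with a warning rather
than a fabricated normalization.

**Reliability** tables bin each class's predicted probabilities into
$[0,.25)$, $[.25,.5)$, $[.5,.75)$, $[.75,1]$ and report per bin the count,
mean predicted probability and empirical class frequency. Binning is per
class (each class's own probability across all test samples, matching
per-class reliability panels). Empty bins keep count 0 with `NA` statistics.

## Synthetic data: what it shows and what it does not

`generate_raw()` builds oscillatory surrogates: per trial and channel, one
sinusoid per band at a random in-band frequency and phase, plus white
Gaussian noise; classes differ by amplitude multipliers on designated
band/channel subsets. The reference **separable-2class** dataset is 2
classes × 20 trials, 14 channels, a 3× beta amplitude contrast on channels
1–4, noise sd 0.3, seed 7. Trials are 6 s at 128 Hz — a deliberate
desk-scale problem size (11 windows, $n = 88$ feature rows) chosen so the
full 9-fold cross-validation of the complete scheme runs in minutes on one
CPU; the generator's default duration of 60 s mirrors the trial length of
the raw-signal databases. The **noisy variant** weakens the contrast to
1.5× and raises the noise sd to 1.0, for regularization comparisons on a
task the clean dataset would saturate.

These surrogates reproduce exactly the statistical structure the feature
pipeline measures — band-power differences on channel subsets — and nothing
else. Passing tests demonstrate that the implementation extracts band
features correctly, that the spiking pipeline propagates and learns
class-discriminative structure, and that the protocols and diagnostics
behave as specified. They do not demonstrate performance on physiological
EEG: real recordings have 1/f spectra, artifacts, non-stationarity and
inter-subject variability that no sinusoid-plus-noise surrogate emulates.
`generate_feature_dataset()` likewise emulates only the *shape* and
block-shift structure of five-band feature databases (e.g. 500 × 62
matrices), not their content.

## Numerical choices and degenerate inputs

* Constant (zero-variance) channels are rejected before z-scoring with an
  explicit degenerate-input error; bands must satisfy
  $0 < \mathrm{lo} < \mathrm{hi} < f_s/2$.
* Windows that would overrun a record are dropped, never padded; the window
  count is exactly $\lfloor(\mathrm{dur}-\mathrm{win})/\mathrm{step}\rfloor+1$.
* Feature matrices round-trip through TSV at `%.17g`, which is bit-exact for
  doubles; model checkpoints are single RDS files and round-trip exactly.
* The softmax subtracts the row maximum before exponentiation; predicted
  probabilities are floored at $10^{-12}$ inside the loss only.
* Ties: spike firing at exactly the threshold is *no spike* ($U(0)=0$);
  drop-path mask redraws apply only when every path was dropped.
* Batched and single-sample execution paths share the same arithmetic and
  agree to machine precision (asserted in the tests); the single-sample
  functions are the reference implementations.

## Known limitations

* No EDF reader: raw signals enter as delimited text plus a YAML sidecar.
* Training is pure R; it is practical at the desk scale used here
  (tens of trials, $n \approx 10^2$) but not at full database scale.
* The surrogate-gradient width and neuron constants are global, not
  per-layer.
* Attention heads must divide $n$ exactly; there is no padding.
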