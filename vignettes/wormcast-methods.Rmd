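---
title: "Forecasting C. elegans lifespan curves: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting C. elegans lifespan curves: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormcast)
```

## The problem

A *C. elegans* lifespan assay tracks the number of live worms on a set of
Petri plates, day after day, until the whole population is dead. A condition
(a treatment group) is physically split across several plates of 10--15
worms; its survival curve is the sum of the plate counts. Assays run for 30
to 60 days and are scored by hand, which makes them the throughput
bottleneck of aging studies.

`wormcast` implements a forecasting pipeline for such assays: given the
counts and worm-position images of the first days, it predicts the rest of
the survival curve, attaches an uncertainty band to the prediction, and
applies a statistical criterion that tells the experimenter when the
prediction has become reliable enough to stop scoring -- typically around
the mean lifespan, i.e. halfway through the assay.

The pipeline has five stages, each usable on its own:

1. **simulate** -- a Weibull-based assay simulator (also the source of all
   training data);
2. **render** -- the synthetic-domain image representation;
3. **dataset / model** -- a bimodal sequence-regression network trained
   purely on simulated plates;
4. **uncertainty** -- Monte-Carlo input perturbation per plate, propagated
   to the condition;
5. **halting / evaluate** -- a log-rank criterion on the confidence band,
   and scoring utilities.

## The lifespan simulator

Individual lifetimes are modelled as 2-parameter Weibull: the probability
that a worm is still alive at day $t$ is

$$S(t) = e^{-(t/b)^a},$$

with shape $a$ (steepness of the mortality curve; deaths concentrate around
$t=b$ as $a$ grows) and scale $b$ in days. The exact mean lifetime is
$b\,\Gamma(1+1/a)$, close to $b$ for the shapes used here ($a \ge 3$). The
supported design ranges are 10--16 worms per plate and $b$ between 10 and
57 days; `simulator_params()` warns outside them.

Two discretisations are provided. The default draws one continuous Weibull
lifetime per worm and sets its death day to the ceiling, so the expected
per-day survival equals $S(t)$ exactly and worm identities are exchangeable
(which the trajectory assignment uses). The alternative
(`method = "deterministic"`) rounds $n\,S(t)$ day by day, yielding the
idealised noise-free curve. Lifetimes are drawn from the Weibull truncated
at `max_days` (by redraw); validation requires `max_days >= ceiling(b)` and
the recommended horizon is at least $2.5\,b$, where the truncated mass is
negligible.

**Capture gaps.** Operator-scored assays have no-capture days (typically
weekends); on those days the count of the last captured day is carried
forward, producing steps. `apply_capture_gaps()` reproduces this: by
default 2 consecutive gap days every 7 days with a random phase, applied to
half the curves (`prob = 0.5`). Day 0 is never a gap; a gap block covering
the extinction day extends the curve to the next captured day. The rates
are package choices -- the phenomenon, not its frequency, is what the model
must tolerate.

**Trajectories.** Worm deaths are assigned at random among the living at
each drop of the (gapped) curve. A live worm takes a fresh uniform position
inside a central "food lawn" disc every day (radius a configurable fraction
of the image, default 0.7 of the half-side, emulating the bacterial lawn
spotted at the plate centre, and keeping blobs clear of the borders); a
worm found dead lies at the position where it was last seen alive and never
moves again. Day-to-day position change is therefore exactly the
live/dead signal. On gap days the count is held but positions are still
resampled; the step distortion enters the count modality only.

## The synthetic image domain

Every capture day is reduced to a square single-channel image: filled
circles of radius `blob_radius` (default 2 px) at the worm centroids on a
constant gray background (128 on black-to-white 0--255), default 64 px per
side. The same representation can be produced from real micrographs by
external detection/classification tools, which is what lets a
simulator-trained model run on real assays; producing it from micrographs
is out of scope here -- `wormcast` starts from centroid lists.

Rendering is deterministic: centres round to the pixel grid, overlapping
circles merge into a flat region, out-of-bounds centres are an error (no
silent clipping). Images are stored 8-bit and scaled to $[0,1]$ at model
ingestion.

## Training data

For each simulated curve, one training sample is cut per remaining day:
from the first drop day $k_0$ (the first day a worm has died -- before
that, the curve carries no information about the plate's mortality) through
the day before extinction. The sample at current day $k$ has inputs
(counts, frames for days $0..k$) and label (counts for days $k+1$ to
extinction). A curve extinct at day $E$ thus yields $E - k_0$ samples, each
with at least one future day to predict.

Samples are split 80/20 into training and validation **by curve**: samples
cut from one curve are near-duplicates, and a sample-level split would leak
validation information into training. The default parameter law draws $a$
uniformly in $[3, 10]$, $b$ in $[10, 57]$ and $n$ in $\{10..15\}$; only
the ranges are prescribed by the design, the uniform law is a package
choice.

## The bimodal network

The predictor follows a two-branch design:

* **image branch** -- each day's frame passes through a small CNN (three
  3x3, stride-2 convolutions with widths 8/16/32, ReLU, global average
  pooling) producing a per-day embedding; an LSTM (width 64) summarises the
  embedding sequence. This branch sees movement (position change between
  days), the live/dead signal.
* **count branch** -- an LSTM (width 32) over three per-day features:
  scaled live count, scaled day index (survival hazards are
  time-dependent) and the day-to-day drop (deaths per day, the steepness
  cue of the mortality curve).
* **head** -- branch features are concatenated together with five skip
  features (scaled last observed count, day index, initial count, fraction
  still alive, and the normalised area under the prefix -- cheap
  sufficient statistics the recurrent encoder is slow to extract on its
  own) and pass through a fully connected layer (width 64, ReLU) to the
  output layer.

Ablation variants keep everything identical but drop one branch
(`counts_only`, `images_only`) or replace the image branch by a per-day
coordinate matrix of size `max_worms` x 2, lexicographically sorted and
zero-filled (`bimodal_coords`). In the `images_only` variant the count skip
feature is zeroed so the variant genuinely never sees counts.

There is no canonical set of layer widths for this design; the widths
above are declared package defaults, all configurable in
`model_config()`.

**Output head.** Two conventions are implemented. The default *relative*
head predicts the counts 1, 2, ..., `max_days` days after the current day;
the *absolute* head predicts counts at fixed assay days. The relative head
is the default because the regression targets are then aligned with what
the recurrent state naturally encodes (current level and decline shape),
whereas the absolute head forces the network to also encode "which day is
it" to place the decline; on matched scaled runs the absolute head
plateaued at a ~30% higher validation MSE. Raw head output is
post-processed into a valid curve: clipped to `[0, initial_count]`, then
made non-increasing starting from the last observed count (running
minimum). The post-processing is a package addition -- raw network output
is not guaranteed monotone.

**Normalisation and masking.** Counts are scaled by `1/max_worms`
(`max_worms = 16`, the largest population considered), day indices by
`1/max_days`, pixels by 1/255. Within a batch, prefixes are front-padded to
the longest prefix with a validity mask; the masked LSTM provably treats a
front-padded sequence exactly as the shorter sequence (tested). The loss is
the mean squared error over predicted-day slots; with the relative head all
slots are supervised (slots beyond extinction are genuine zeros -- the
plate is dead).

**Optimisation.** Training is SGD on the MSE; the full-scale default recipe is 100 epochs,
learning rate 0.001, batch size 16. That recipe amounts to hundreds of
thousands of gradient steps on a ~100k-sample dataset; the scaled study in
this package's tests (a few thousand steps) instead uses learning rate
0.02--0.3 with classical momentum 0.9 (`train_config(momentum =)`), which
reaches a comparable optimisation depth in far fewer steps. With momentum 0
the update is plain SGD. Optionally, Gaussian noise (`input_noise_sd`,
worms) is added to the training count prefixes: at prediction time the
uncertainty estimator feeds the model noise-perturbed counts, and training
under the same perturbation keeps those inputs in-distribution. The
best-validation epoch is checkpointed. Training, like every stage, is
bit-reproducible from its seeds.

The engine behind the model is written in vectorised base R: convolutions
as a precomputed im2col gather plus one dense matrix product per layer
(sparse-matrix scatter for the backward pass), a masked LSTM with full
backpropagation through time, momentum SGD. Every analytic gradient is
checked against central finite differences in the test suite.

## Uncertainty: input perturbation and error propagation

The network outputs a point prediction; its uncertainty is approximated by
the spread of predictions over `n_replicates` (default 30) copies of the
input with i.i.d. Gaussian noise, standard deviation `sigma` (default 1
worm), added to the count sequence and clipped at 0. Perturbed counts stay
real-valued (the model consumes continuous counts). Frames are left
untouched by default -- unit-variance intensity noise is ill-defined for
flat blob images -- but a position-jitter mode (Gaussian jitter of blob
centres, sigma in pixels) is available for image-mode models. Each plate
uses an independent noise stream.

Per plate, the replicate predictions are summarised by the per-day sample
mean $\bar P$ and sample standard deviation $S_P$ (denominator $N-1$).
Because a condition's count is the sum of its plates' counts -- a linear
function with unit partial derivatives -- the condition standard deviation
follows the error-propagation law

$$S_C = \sqrt{\textstyle\sum_k S_{P_k}^2},$$

and the confidence interval at level $\alpha$ is

$$\bar C \pm z_{\alpha/2}\, S_C / \sqrt{n},$$

with $n$ the number of plates. Note the $\sqrt n$ divisor: $S_C$ already
aggregates the plates, so dividing by $\sqrt n$ again double-counts plate
multiplicity relative to standard practice and narrows the band. It is
implemented this way deliberately as part of the method's formulation; `propagate_condition(sqrt_n = FALSE)` drops the divisor (and
widens the band, delaying halting). Bounds are clipped to
`[0, total initial count]`.

## The halting criterion

From the lower and upper CI bounds over all predicted days, two survival
curves are built (both starting from the observed condition prefix, so both
have the same initial population), rounded half-up to integers and
re-monotonised -- a log-rank test needs integral event counts; the rounding
convention is a package choice. The standard unweighted (Mantel--Cox)
log-rank statistic compares them: at each distinct death day the observed
group-1 deaths are compared with their hypergeometric expectation, the
statistic is $(\sum_j (d_{1j}-e_{1j}))^2 / \sum_j v_j$ with 1 df. Survivors
at the end of either curve are right-censored there; all deaths on one day
form one event time. The implementation is validated against
`survival::survdiff` to 6+ significant digits on random curve pairs.

If the bounds do **not** differ significantly ($p > \alpha$, default 5%),
the band is narrow in the log-rank sense and the assay may halt.
`find_halt_day()` replays the assay day by day, starting at the first day
the curve has fallen in *every* plate of the condition (before that, the
per-plate uncertainty estimate is unfounded), and reports the first
qualifying day plus the full p-value trace. A degenerate band (identical
bounds) halts with $p = 1$.

## Evaluation

`evaluate_assay()` scores a condition: at the proposed halting day $k^*$ it
builds the predicted condition curve (observed prefix + rounded mean
suffix) and reports

* **MAE (%)** -- mean absolute difference in survival percentage points
  over the *future* period, $k^*+1$ through reference extinction (the
  earlier period is known and excluded);
* **mean lifespans** -- defined as the average reconstructed death day
  (a drop of $m$ at day $d$ contributes $m$ deaths at day $d$); survivors
  at a non-extinct curve's end are counted at that day with a
  restricted-mean warning;
* **log-rank p** between reference and predicted curves;
* the same MAE for the **Weibull curve-fit baseline**: Levenberg--Marquardt
  least squares of $n_0 e^{-(t/b)^a}$ on the identical observed prefix
  (`minpack.lm::nlsLM`; start $a_0=5$, $b_0$ = last day above 50%
  survival, bounds $a \in [0.5, 100]$, $b \in [1, 200]$), extrapolated over
  the horizon. The baseline is the classical alternative: fit the
  parametric model to the prefix and extrapolate.

An exact-oracle predictor stub (`oracle_predictor()`) that returns the true
reference curves validates the whole chain end to end: with it, MAE is 0,
the log-rank p is 1, and halting fires immediately.

## Scaled study sizes

The test suite and the acceptance script run a scaled-down study chosen to
exercise the full pipeline on one CPU in minutes: 16 px images
(blob radius 1), label horizon 40 days, training on 200 simulated curves
with $a \in [5,10]$, $b \in [12,20]$ (matching the evaluated conditions; 60
curves for the three-seed ablation comparison), 40 epochs of momentum SGD
(learning rate 0.02, batch 16), evaluation on 5 held-out conditions of 4
plates x 10--15 worms, 20 noise replicates. The defaults shipped in the package
(`image_spec()`, `param_law()`, `train_config()`) remain the full-scale
design values.

## What the synthetic study does and does not show

All training and evaluation data come from the package's own simulator, so
the tests demonstrate that the pipeline is internally correct and that the
method works when its model of the world is right. Real assays deviate in
ways the simulator deliberately ignores: heterogeneous aging
subpopulations (a single Weibull assumes homogeneity), detection errors and
occlusions at the plate edge, escape/burrowing censoring, worm body shape
and postural detail beyond a centroid blob, and overlapping worms. Results
on synthetic conditions therefore bound what field performance can be
expected, and the Weibull-fit baseline is *advantaged* here: the reference
curves really are Weibull, so the parametric fit is exactly
well-specified, and it fits the *summed* condition prefix (roughly four
times the deaths available to any per-plate prediction). A useful
reference point: on sharp conditions the network's per-plate predictions
sit within about half a worm of the exact Bayes posterior mean computed by
numerical integration over the simulator's parameter prior -- close to the
information-theoretic limit of per-plate forecasting. When the realised
curve falls in a tail of that posterior, the well-specified point fit can
still win on that condition; on real, non-Weibull assays the comparison
tilts the other way.

## Numerical and degenerate-input choices

* Count curves are integer, non-increasing, 0-based in days, and must end
  at 0; constructors validate this.
* A curve with no death has no admissible prediction day
  (`first_drop_day()` errors; `find_halt_day()` raises a not-started error
  when no qualifying day exists before the horizon).
* Log-rank with no events in either curve is undefined (error); a fully
  degenerate comparison (zero variance, zero observed-minus-expected)
  returns statistic 0, $p = 1$.
* CI bounds are rounded half-up (`floor(x + 0.5)`) only at the halting
  stage; everything upstream stays real-valued.
* The Weibull fit needs at least two distinct prefix values; a flat prefix
  is a fit-failure error.
* All randomness flows through explicit seeds; identical seeds give
  bit-identical curves, datasets, trainings and reports.
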