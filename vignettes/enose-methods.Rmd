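---
title: "Methods: e-nose curve classification with swarm-tuned networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: e-nose curve classification with swarm-tuned networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enose)
```

This vignette is the package's account of its science: the models and
procedures it implements, the choices made where the design was genuinely
open, and what the synthetic experiments do and do not demonstrate.

## The measurement model

An electronic nose exposes an array of cross-sensitive gas sensors to a
sample's headspace and records one concentration curve per channel (here:
8 channels, 350 s at 1 s steps). Curves rise from zero to a class-dependent
plateau; the joint plateau pattern across channels is the volatile
fingerprint that separates healthy fruit from the three fungal infections
(*Aspergillus niger*, *Penicillium expansum*, *Penicillium crustosum*).

The synthetic generator emulates exactly this geometry:

$$v(t) = A \cdot \frac{1 - e^{-t/\tau}}{Z} + \varepsilon(t), \qquad
\varepsilon(t) \sim \mathcal N(0, \sigma^2),$$

with $\tau$ = 25 s, and $Z$ a normalisation constant making the mean of the
deterministic curve over the stable 150–300 s window equal exactly 1. The
plateau entry $A$ of the class-by-channel matrix is therefore defined as the
mean stable-window concentration — the quantity a practitioner would
calibrate a sensor against — and at $\sigma = 0$ the class-conditional
stable-window mean reproduces the matrix to machine precision, which the
tests assert.

Per-sample biological variability multiplies $A$ by a factor
$1 + \eta$, $\eta \sim \mathcal N(0, (j\sigma)^2)$ with `plateau_jitter`
$j$ converting the sensor-noise scale into a relative amplitude spread. One
dial (`noise_sd`) therefore controls all stochasticity: at zero the classes
are perfectly separable (and cross-validation must reach accuracy 1.0, which
it does), and at the defaults the problem is realistically hard. The two
duplicated sensors (channels 1 and 5) share one amplitude factor, because
identical hardware reading the same headspace differs only by sensor noise;
without this, the pair-consistency rule would discard healthy biology rather
than hardware faults.

**Calibration of the defaults.** `noise_sd = 0.08` mg/L and
`plateau_jitter = 2.75` were chosen once so that the default network lands
near 0.9 mean 10-fold accuracy (0.90 averaged over five generator seeds),
leaving visible headroom for architecture tuning; the class plateau rows
differ by 0.3–0.8 mg/L per channel, comparable to the spread visible in
published transient recordings. Injected outliers (10% of records by
default) multiply all live channels of a record by 5: they are extreme in
feature space but preserve curve morphology, so they specifically exercise
the outlier-removal stage rather than the classifier.

What the generator does *not* emulate: sensor drift and recalibration,
temperature/humidity covariates, valve switching transients, and the
heavy-tailed noise of real electrochemistry. Passing tests on synthetic data
therefore demonstrate the correctness and statistical sanity of the
pipeline, not field performance on real acquisitions.

## Preprocessing

**Smoothing.** k-point linear (moving-average) smoothing with
$k \in \{3,5,7,9,11\}$, default 7. The ends use the largest symmetric window
that fits, which keeps the output length equal to the input and introduces
no phase shift; the alternative (truncated one-sided windows) biases the
initial transient that two descriptors depend on.

**Dead channels.** A channel is excluded only when *every* value of *every*
record is within `epsilon` (default 1e-6 mg/L) of zero — a strict rule, so a
single genuine response retains the channel. With the default two silent
channels, the 48-feature table drops to 36.

**Pair rule.** The duplicated sensors are compared by the *maximum* absolute
difference over 150–300 s against a strict 1.2 mg/L threshold. The maximum
is the strictest aggregator consistent with reading "the difference between
the two sensors" as a pointwise quantity; a `mean` aggregator is available.

**Mahalanobis outlier removal.** Distances are computed per class (each
class's own mean and covariance) and compared against
$\sqrt{\chi^2_{1-\alpha}(d)}$, $\alpha = 0.025$, the standard multivariate-
normal tail argument. Two failure modes of the classical estimator matter in
this regime (36 features, ~40 samples per class):

* the in-sample squared distance is algebraically bounded by $(n-1)^2/n$,
  which for $n = 40, d = 36$ is *below* the chi-square cutoff — no point
  could ever be removed;
* clustered outliers (scaled copies of a class signature) inflate the
  covariance along their common direction and mask each other.

`remove_outliers()` therefore shrinks the class covariance toward its
diagonal: fully when $n < 2d$, by $\gamma = d/n$ beyond. The diagonal metric
accumulates per-feature evidence (a whole-record inflation deviates in all
36 features simultaneously), which removes both failure modes; as $n$ grows
the rule decays toward the classical estimator. In the recovery experiment
(10% injected outliers at scale 5, 20 seeds) the median recall is 100% with
0% median clean-sample loss; at $\gamma = 0.9$ the recall already collapses
to 62%, which motivated the rule. `mahalanobis_distances()` itself remains
the pure estimator (ridge only when the condition number exceeds 1e10) so
that the affine-invariance and $\sum d_i^2 = d(n-1)$ identities hold, and
tests assert them.

## Features

The six descriptors are computed over 30–300 s: trapezoidal integral,
population variance, average differential (identically
$(v_m - v_1)/((m-1)\Delta t)$ by telescoping), signed maximum one-step
gradient (these sensors rise; an absolute variant is a flag), the plateau
mean over the final half of the window (165–300 s with the defaults), and
the discrete energy $\sum v_i^2 \Delta t$. Each definition is pinned by a
unit test against an independent summation oracle, so any future
reinterpretation is a visible diff. The trapezoid-versus-plain-sum choice
for the integral matters only at $O(\Delta t)$; the trapezoid is exact for
the piecewise-linear interpolant.

## Dimensionality reduction

All three reducers share a fit/project contract (`predict()` computes
$(X - \mu)V$).

* **PCA**: eigendecomposition of the covariance; default k reaches 95%
  explained variance; component signs are fixed (largest-magnitude entry
  positive) so results are deterministic.
* **LDA**: Fisher's multiclass criterion $S_B w = \lambda S_W w$ with the
  within-class scatter ridge-regularised exactly as in preprocessing;
  at most `classes - 1` = 3 discriminants. Default in the pipeline: it is
  the supervised reduction and, as the tests show, separates these feature
  tables essentially perfectly in the low-noise regime.
* **FA**: iterated principal-factor extraction on the correlation matrix
  (squared multiple correlations as starting communalities). The
  maximum-likelihood flavour was deliberately not used: principal factoring
  is deterministic, has no Heywood-case optimiser failures, and its
  fixed-point iteration gives a clean convergence contract (error with the
  iteration count otherwise).

Inside cross-validation the projection is fit on the training fold only;
`global_fit = TRUE` reproduces the optimistic whole-dataset variant some
studies use, and is off by default because it leaks test information into
the projection.

## The network and its training

The BPNN is a feedforward perceptron: sigmoid hidden layers (ReLU by flag),
softmax output, mean cross-entropy loss, full-batch gradient descent.
Weights start uniform in $[-1/\sqrt{f}, 1/\sqrt{f}]$ (fan-in $f$), biases at
zero; inputs are standardised with training-fold statistics stored in the
model. Analytic gradients are verified against central finite differences to
better than 1e-5 relative error.

Numerical choices: softmax is computed with the row-max subtracted;
probabilities are floored at 1e-300 inside the log; a non-finite loss raises
an error advising a smaller learning rate. The default learning rate is 0.3
with 500 epochs — full-batch descent on standardised inputs needs a far
larger step than stochastic variants, and at 0.01 the network cannot fit
even the training data within the epoch budget. Two hidden layers of 8 nodes
are the untuned default; the layer count is configurable and the node counts
are the optimizer's search variables.

## The metaheuristics

All three optimizers minimise over a box, round integer dimensions after
every update, clip to bounds, track the best-so-far (whose history is
asserted monotone), and evaluate each individual exactly once per iteration
(so evaluations $\le$ population $\times$ (iterations + 1)).

**SSA** follows the canonical producer/scrounger/forewarner scheme: ranked
by fitness, the top 20% (producers) forage — shrinking multiplicatively by
$e^{-i/(\alpha T)}$, $\alpha \sim U(0,1]$, while the per-iteration alarm
value $R_2 \sim U(0,1)$ stays below the safety threshold ST = 0.8, otherwise
stepping by a shared Gaussian; scroungers move toward the best producer
$x_P + |x - x_P| \cdot A^+ L$ (the worse half instead jump near the worst
position by $Q\,e^{(x_w - x)/i^2}$); finally a random 10% (forewarners)
relocate relative to the global best ($x_{best} + \beta|x - x_{best}|$, or
the worst-distance step with $K \sim U(-1,1)$, $\epsilon = 10^{-8}$).
Forewarners reuse the ranking fitnesses of the current iteration, keeping
the single-evaluation budget. **PSO** uses inertia 0.7, cognitive = social
= 1.5, velocities clamped to 20% of the box span. **GWO** is the canonical
$\alpha/\beta/\delta$ encircling update with the exploration coefficient
decreasing linearly 2 → 0.

On the 5-D sphere at the study budget (population 15, 100 iterations) all
three reach medians far below their test thresholds (1e-2 for SSA/GWO, 1e-1
for PSO), and at a reduced paired budget SSA matches or beats PSO in all 20
paired seeds — a desk-scale echo of the convergence-ordering observation
that motivates preferring SSA.

**Architecture search.** The fitness of an integer hidden-size vector is the
negative mean stratified inner-3-fold validation accuracy of a network with
those sizes; fitness values are cached by rounded position, so re-visited
architectures cost nothing. Hold-out versus inner-CV fitness and the node
bounds (default 2–64 per layer) are declared configuration, since no
canonical values exist.

## Evaluation

Stratified k-fold cross-validation (default k = 10) deals each class
round-robin with a rotating offset, so per-class counts differ by at most
one between folds. Per fold, outlier removal, reduction and the classifier
see the training portion only; a structural leakage guard errors if any
fitting step received test rows. The report carries per-fold accuracies,
their mean and *sample* standard deviation across folds (the natural
fold-level reading of "standard deviation of accuracy"), macro-averaged TPR
and F1 of the pooled confusion matrix (macro, because the design is
balanced; micro is a flag away via the confusion matrix itself), and the
wall-clock training time, which is recorded but never asserted.

## Problem sizes used by the test-suite experiments

The suite works at the study's own scale where that is cheap (160 samples,
10 folds, 20 recovery seeds, 10 sphere seeds at population 15 and 100
iterations) and at a reduced search budget (population 8, 15 iterations,
5 seeds) for the tuning-helps comparison, chosen so a complete run stays in
the minutes range on one CPU while still exercising every stage at
realistic dimensions.

## Known limitations

* The synthetic generator's realism gaps listed above; no claim is made
  about accuracy on real acquisitions.
* Mahalanobis removal assumes roughly elliptical clean classes; heavy-tailed
  clean data would inflate the removal rate.
* The pair rule needs the duplicated channels to be genuinely redundant;
  on arrays without duplicated sensors it must be disabled.
* Full-batch training is deliberate (deterministic, testable); very large
  datasets would want mini-batching (`batch_size`), which trades
  determinism of the loss path for speed per epoch.
* The metaheuristics optimise node counts only — not weights, depth, or
  learning hyperparameters.
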