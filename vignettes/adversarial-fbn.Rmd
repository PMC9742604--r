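---
title: "Adversarial construction of brain functional networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adversarial construction of brain functional networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Functional brain networks (FBNs) are usually built by pushing resting-state
fMRI through a long toolbox pipeline — motion correction, normalization,
smoothing, band-pass filtering, atlas warping — and then correlating the
resulting ROI time series. Every stage carries subjective settings, and
estimation errors propagate into the connectivity matrix that downstream
classifiers consume. `fbngan` implements an alternative: a network that maps
the 4D volume *directly* to ROI time series and a connectivity matrix,
trained adversarially against toolbox-style "empirical" series so that the
learned series stay on the empirical distribution while remaining free of
per-stage hand tuning. A graph convolutional classifier trained jointly on
the learned (network, series) pairs ties the representation to the
diagnostic signal.

## Architecture

**Region-guided feature extractor.** Each fMRI frame passes through blocks
of (3×3×3 convolution, 2×2×2 average pooling, batch normalization, ReLU);
at full brain scale (64×64×48 volumes) four blocks with channels
(8, 16, 32, 64) pool the grid down to 4×4×3. A 1×1×1 convolution then
expands to one channel per ROI with a sigmoid. For ROI $i$ the $i$-th
channel's spatial map is flattened and concatenated with that ROI's
normalized atlas descriptors $(x, y, z, v)$ — center coordinates and volume,
min-max scaled to $[0,1]$ — and a single linear projection shared across
ROIs and frames reduces it to one scalar. Stacking over ROIs and frames
gives the rough feature matrix $F_1 \in \mathbb{R}^{N \times q}$.

The reduction from channel maps to scalars is deliberately *per-ROI with a
shared projection*: a single global flatten across all ROI channels would
couple the parameter count to $N \cdot q$ (billions of weights at brain
scale), whereas the shared projection keeps it at the pooled map size plus
four. Descriptors are injected identically at every frame.

**Attention refiner.** Each ROI is a token of width $q$. Queries are a
linear map of $F_1$; keys and values see $F_1$ with the four descriptor
columns appended (width $q+4$). Multi-head scaled dot-product attention
(11 heads at $q = 187$; head width $q/h$) mixes tokens, an output projection
with residual connection and *post*-norm row-wise layer normalization forms
the spatial block, and a temporal feed-forward block (down-map to
$\lfloor q/2 \rfloor$, ReLU, up-map, residual) emits the generated series
$F_g$. When $h \nmid q$ every head gets $\lfloor q/h \rfloor$ columns and
the last head absorbs the remainder; the feed-forward hidden width floors
$q/2$. Post-norm order and the ReLU inner activation are conventional
choices where the formulation leaves them open.

**Connectivity kernel.** The generated network is
$A_g(i,j) = \exp\!\left(-\lVert (F_{g,i} - F_{g,j}) W \rVert^2 / (2\sigma^2)\right)$
with a learnable $q \times q$ transform $W$ (initialized at identity plus
$\mathcal N(0, 0.01^2)$ noise) and bandwidth $\sigma = 2$. Entries lie in
$(0, 1]$, the diagonal is exactly 1, and symmetry is exact because each
unordered pair is evaluated once. $W$ multiplies the row difference on the
right (row-vector convention); $\sigma$ is fixed, not learned.

**Discriminator.** One independent network per ROI (widths
$\lfloor q/2\rfloor, q, \lfloor q/2\rfloor$, leaky-ReLU 0.2, then a scalar
linear head), scoring its ROI's series; the discriminator output is the mean
over channels. The output stays un-squashed because the adversarial losses
are least-squares, which presuppose real-valued scores.

**Classifier.** Three graph convolutions
$H_{\ell+1} = \mathrm{relu}(\hat A H_\ell W_\ell)$ over
$\hat A = D^{-1/2}(A+I)D^{-1/2}$, halving the feature width each layer
($q \to \lfloor q/8 \rfloor$), a pooling layer averaging each ROI's features
to one value, and a perceptron ($N$, 32, 16, classes) with softmax.
Empirical Pearson matrices are first rescaled off-diagonal by $(r+1)/2$,
since degree normalization needs nonnegative weights and the treatment of
negative correlations is otherwise open. The same classifier consumes
empirical $(A_e, F_e)$ and generated $(A_g, F_g)$ pairs.

The graph-convolution weights initialize as truncated identities (scaled by
$\sqrt 2$ to offset the ReLU) plus $\mathcal N(0, 0.01^2)$ noise rather
than as dense random matrices. The class-discriminative statistic in this
architecture is the *variance* of diffused node features — correlated
neighborhoods mix coherently, so diffused rows of a connected community
have visibly larger spread — and with dense random deep layers that
variance signal is scrambled before the per-ROI pooling bottleneck
(we measured between-group $|t| \approx 20$ after one diffusion collapsing
to $|t| \approx 0.3$ at the pooled output of a randomly initialized
stack). Identity-structured initialization lets features and their
variances propagate through the depth from the first step, after which
training refines rather than rediscovers the pathway; on held-out phantom
subjects this is the difference between chance-level and accurate
classification at small cohort sizes.

## Objectives and schedule

Five losses: reconstruction $L_{rec}$ between $F_g$ and the empirical
series; least-squares adversarial $L_g = \mathbb E[(1 - D(F_g))^2]$ and
$L_d = \mathbb E[D(F_g)^2] + \mathbb E[(1-D(F_e))^2]$; two-path
cross-entropy $L_{cls}$ over generated and empirical classifier inputs; and
$L_{reg} = \lVert W \rVert_F$. The logged hybrid cost is
$L_{all} = L_{rec} + L_g + L_d + L_{cls} + \lambda L_{reg}$ with
$\lambda = 10^{-5}$.

Each batch runs three sub-steps: (a) discriminator on $L_d$;
(b) generator (CNN + attention) on $L_g + L_{rec}$ against the *updated*
discriminator; (c) with the generator frozen, connectivity kernel and
classifier on $L_{cls} + \lambda L_{reg}$. "Frozen" is structural: sub-step
(c) touches only $W$ and the classifier, which the tests verify bit-wise.
All three sub-steps consume the generator forward computed at step entry;
re-running the volumetric forward after sub-step (b) would double the
dominant cost for a one-micro-step-stale input, a trade we consider
negligible at batch size 2. $W$ receives gradient only in sub-step (c)
(it does not enter $L_{rec}$ or $L_g$). Optimization is Adam, batch size 2.

The alternating schedule gives the classifier exactly one mini-batch pass
per generator step. On small cohorts that leaves the classification head far
from its optimum: on frozen features from a trained stack, plain logistic
regression separates held-out phantom subjects essentially perfectly while
the one-pass-per-step head does not. `train_config(cls_refine_steps = n)`
therefore appends an optional *classifier refinement* phase: the generator
is frozen (its forward is computed once per subject), and the connectivity
kernel + classifier minimize the classification objective with full-cohort
gradients for `n` further Adam steps. This is the natural phase-wise reading
of "first update the generator and discriminator, then fix part of the
generator and optimize the kernel and classifier", with the per-phase
iteration count — which nothing fixes — chosen to let the cheap phase
converge. The default is 0 (plain alternation); the package's reference
experiments use 300.

Relatedly, `schedule = "two_phase"` drops the per-batch classifier sub-step
entirely and leaves all classification learning to the refinement phase. On
small cohorts the per-batch sub-step is actively harmful: its noisy
two-subject gradients perturb the graph-convolution filters away from their
estimator-structured initialization faster than they learn, and held-out
accuracy drops by ~25 points relative to the two-phase schedule on
identical folds. During refinement the filters stay frozen for the same
reason — fitting thousands of filter parameters to a dozen subjects
memorizes — while the decision head and kernel transform train to
convergence. At cohort sizes in the hundreds these pressures relax and the
alternating default is the faithful choice.

### The reconstruction norm

The reconstruction objective is the Frobenius norm
$\lVert F_g - F_e \rVert_F$ (per subject, batch-averaged), while the
*reported* reconstruction metric — logged per step and per epoch — is the
entrywise mean absolute error (MAE). The distinction matters: the MAE
gradient has constant magnitude $1/(Nq)$ per entry regardless of the
residual, which in short runs is one to two orders of magnitude below the
adversarial gradient at the series level, so the generator chases the
discriminator and the reconstruction barely moves. The Frobenius gradient
scales with the residual, keeping the two signals commensurate; in our
200-step phantom runs it is the difference between the epoch MAE falling by
~78% and not falling at all. Both forms share the zero point, and
`loss_rec()` exposes both.

### Learning rates at desk scale

`train_config()` defaults to the reference protocol: Adam with $10^{-4}$
for generator and classifier and $4 \times 10^{-4}$ for the discriminator.
Those rates are tuned for GPU-scale cohorts trained for many thousands of
steps. Adam moves a parameter by at most (roughly) the learning rate per
step, so a 200-step phantom run at $10^{-4}$ can traverse ~0.02 in weight
space — no visible learning at any loss weighting. All phantom experiments
in the tests and the acceptance script therefore use $2\times10^{-3}$
(generator) and $8\times10^{-3}$ (discriminator), preserving the 1:4 ratio,
and $8\times10^{-3}$ for the kernel + classifier group, whose convergence —
not generator/discriminator balance — limits short fold-level training.
This is stated here once as the package's desk-scale protocol; it is a
scaling argument, not a per-experiment tuning.

## The phantom simulator

`phantom_spec()` defines the synthetic study conditions: a 3D grid with
non-overlapping spherical ROIs on a lattice, per-subject latent ROI series
drawn i.i.d. over time from a zero-mean multivariate normal with a
class-specific covariance, voxel signal = ROI signal + independent Gaussian
noise (pure noise outside ROIs). Defaults are a 16×16×16 grid, 8 ROIs of
radius 2, 64 frames, noise sd 0.5 against unit-variance signals, and two
classes differing on the six edges of a four-ROI community (pairwise latent
correlation 0.8 vs 0.1) — a planted, recoverable connectivity difference.
`phantom_spec_hub()` instead confines the class signal to the edges of a
single hub ROI, the configuration ROI-shielding importance analysis should
recover. "Empirical" series are ROI-mean voxel averages standardized per
row — the simplest faithful stand-in for toolbox output preserving the
$N \times q$ contract — and empirical connectivity is their Pearson matrix.

What the phantom deliberately omits: hemodynamics, temporal autocorrelation,
motion and registration artifacts, spatially correlated noise, atlas
misalignment. Passing tests on phantoms therefore demonstrate that the
estimator recovers planted structure under the stated noise model, not that
it handles scanner data; the pipeline stages that would absorb those
artifacts are exactly the toolbox stages the model is designed to bypass.

Whether empirical rows should be standardized before entering the
discriminator and reconstruction loss is an open point in the source
formulation; we standardize, which fixes the scale of both losses.

## Evaluation and analyses

**Metrics.** Accuracy, sensitivity, specificity and F1 from the confusion
table, with the later disease stage of each pairwise task as the positive
class (a convention fixed for reproducibility); divisions by zero yield 0
with a warning. The reference protocol is stratified 5-fold cross-validation
repeated 10 times; folds are seeded shuffles, every subject appears in
exactly one test fold per repeat, and `cross_validate()` reports per-fold
metrics with means and standard errors. Test-set predictions average the
generated-path and empirical-path predictive distributions by default
(`path = "both"`); both single paths are available.

One trained classifier serves both input families (the classification loss
has one term per family), and which family feeds prediction at deployment
is a free choice. At phantom scale the generated adjacency is nearly
diagonal — with unit-variance 64-frame rows and bandwidth $\sigma = 2$,
off-diagonal kernel values are at most $e^{-3.2}$ — so the generated family
carries almost no class signal there, and the package's reference
cross-validation experiment evaluates the trained classifier on the
empirical family (`path = "empirical"`), reporting the generated-path
accuracy alongside. At brain scale, where the learned transform $W$ has
thousands of steps to calibrate the kernel's effective bandwidth, the
balance between the two families is an empirical question this package
does not prejudge.

**ROI importance.** Shield ROI $i$ — zero its series row and its
connectivity row/column, keeping the unit diagonal so the trained classifier
applies unchanged — and recompute accuracy; sorting shielded accuracies
ascending ranks ROIs by importance. Shielding is applied to both classifier
paths.

**Altered connectivity.** Given two groups of networks, the difference of
group means $D$ is thresholded at the 90% quantile (linear-interpolation
estimator, the standard convention) of the *absolute* off-diagonal values —
upper triangle, each unordered pair once; the source presentation does not
say whether the quantile is taken over signed or absolute alterations, and
a single threshold on strength matches its figures. Survivors split into
reduced ($D<0$) and increased ($D>0$) sets — directions read group A
$\to$ group B — and the strongest alterations are reported as the top 2%
of edges and the top-5 per direction, ranked by $|D|$ with lexicographic
tie-break.

## Numerical choices

* All forward/backward passes are hand-written (the 3×3×3 convolution in
  compiled code via RcppArmadillo, as BLAS-backed im2col); every backward
  pass is verified against central finite differences in the test suite at
  relative error $\le 10^{-5}$.
* Batch normalization treats the frames of one subject as the batch
  (momentum 0.9, $\epsilon = 10^{-5}$); inference uses running statistics.
* Zero-variance series rows standardize to zero (flagged); zero rows
  correlate as 0, keeping every matrix finite. Degree normalization floors
  degrees at $10^{-8}$ with a warning.
* Classifier probabilities are clipped to $[10^{-12}, 1]$ before logs.
* Every stochastic entry point takes an explicit seed; one master seed fans
  out to sub-seeds (initialization, per-epoch shuffles, per-subject
  phantoms), so identical configurations reproduce results bit-for-bit on a
  single-threaded BLAS.

## Problem sizes used in the shipped experiments

Unit tests run on 8×8×8 grids with 4 ROIs and 16 frames. The reference
experiments use the default phantom (16×16×16, 8 ROIs, 64 frames, 2 conv
blocks, 4 heads, 20 subjects): 200 alternating steps for the convergence
run; two-phase 5-fold cross-validation at 10 adversarial epochs plus 300
refinement steps per fold, with a label-permuted control at 3 epochs plus
100 steps (a no-signal control needs no convergence); ten seeded
hub-phantom runs (8×8×8 grid, 32 frames, 5 epochs + 200 refinement steps)
for importance recovery; analysis-stage recovery on empirical connectivity,
which isolates the analysis operators from generator training. These sizes
are the package's reference experiments and are stated here so they can be
reproduced exactly.

## Known limitations

* No learning-rate schedules, early stopping, spectral normalization or
  other GAN stabilizers: the training loop is deliberately the plain
  alternating scheme. Long runs can oscillate.
* Binary classification heads only (pairwise diagnostic tasks); multi-way
  staging is out of scope.
* The epoch count is a free parameter; nothing in the source formulation
  fixes it, and the package makes no claim of a canonical value.
* The phantom's noise model is white in space and time; see above for what
  that implies about external validity.
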