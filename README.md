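# fbngan

Adversarial construction of brain functional networks from 4D fMRI, in R.

Functional connectivity analysis classically routes resting-state fMRI
through a toolbox pipeline and correlates atlas-parcel (ROI) time series;
every stage carries subjective settings that propagate into the network.
`fbngan` implements a learned alternative for researchers studying early
Alzheimer's-type group differences (or any two-group fMRI cohort): a
generator maps the raw 4D volume directly to ROI time series and a
connectivity matrix, a per-ROI discriminator keeps the generated series on
the empirical distribution, and a graph convolutional classifier ties the
learned networks to diagnosis. The package also ships the group analyses
built on those networks — ROI-shielding importance ranking and
altered-connectivity edge detection — plus a synthetic phantom simulator
with planted, recoverable connectivity differences for end-to-end
validation.

## The model

For a volume sequence $X$ and an atlas with per-ROI centers and volumes
$(x, y, z, v)$ (min-max normalized to $[0,1]$):

* **Rough features** $F_1 = \mathrm{CNN}(X; x, y, z, v) \in \mathbb{R}^{N \times q}$ —
  per frame: 3D conv / average-pool / batch-norm / ReLU blocks (channels
  8, 16, 32, 64 at brain scale), a 1×1×1 conv to $N$ ROI channels with
  sigmoid, then per-ROI flattening concatenated with the ROI's descriptor
  quadruple and a shared linear projection to one scalar per ROI and frame.
* **Generated series** — ROIs as tokens: $Q = \mathrm{LP}(F_1)$,
  $K, V = \mathrm{LP}(F_1 \| x \| y \| z \| v)$, multi-head attention
  $\mathrm{softmax}(Q_i K_i^\top / \sqrt{q/h}) V_i$, output projection with
  residual + row layer-norm, and a temporal feed-forward
  ($q \to \lfloor q/2\rfloor \to q$, residual) giving $F_g$.
* **Generated network**
  $A_g(i,j) = \exp\left(-\lVert (F_{g,i} - F_{g,j})W \rVert^2 / 2\sigma^2\right)$
  with learnable $W \in \mathbb{R}^{q \times q}$, $\sigma = 2$.
* **Adversary** — $N$ independent per-ROI scorers, mean-aggregated, trained
  with least-squares losses
  $L_d = \mathbb E[D(F_g)^2] + \mathbb E[(1 - D(F_e))^2]$,
  $L_g = \mathbb E[(1 - D(F_g))^2]$ against toolbox-style empirical series
  $F_e$.
* **Classifier** — Kipf-Welling convolutions over
  $D^{-1/2}(A + I)D^{-1/2}$ with the series as node features, per-ROI
  feature pooling, and a small perceptron; trained on both $(A_e, F_e)$ and
  $(A_g, F_g)$ with cross-entropy.

Training alternates discriminator, generator ($L_g + L_{rec}$), and — with
the generator frozen — kernel + classifier ($L_{cls} + \lambda\lVert W\rVert_F$,
$\lambda = 10^{-5}$), all with Adam. See
`vignettes/adversarial-fbn.Rmd` for every modelling decision and default.

## Worked example

Simulate a two-group phantom cohort (two diagnostic groups differing on the
six edges of a four-ROI community, latent correlation 0.8 vs 0.1), train,
and inspect the learned networks:

```r
library(fbngan)

spec  <- phantom_spec()                       # 16^3 grid, 8 ROIs, 64 frames
study <- simulate_study(spec, n_per_class = 10, seed = 42)

model <- fbn_model(fbn_config_for_spec(spec), seed = 7)
fit   <- train_model(model, study,
                     train_config(epochs = 20, lr_g = 2e-3, lr_d = 8e-3,
                                  lr_c = 2e-3, seed = 7))
fit
#> trained adversarial FBN model: 200 steps, 20 epochs
#>   MAE (generated vs empirical series): 1.0786 -> 0.2395
```

The printed mean absolute error between generated and empirical ROI series
falls from 1.08 to 0.24 over 200 steps — the generator has learned to
reproduce the toolbox-style series from raw volumes. Constructed networks
are symmetric with unit diagonal (and sparse: the Gaussian kernel maps
dissimilar series toward zero):

```r
g <- construct_fbn(fit$model, study$subjects[[1]]$volume, study$atlas)
round(g$fc[1:4, 1:4], 3)
#>       R001  R002  R003  R004
#> R001 1.000 0.082 0.111 0.016
#> R002 0.082 1.000 0.143 0.004
#> R003 0.111 0.143 1.000 0.007
#> R004 0.016 0.004 0.007 1.000
```

Group analysis on the constructed networks recovers planted structure: the
strongest group-difference edge lies inside the four-ROI community whose
correlation was planted to differ between the groups.

```r
cls  <- vapply(study$subjects, `[[`, "", "class")
fbns <- lapply(study$subjects,
               function(s) construct_fbn(fit$model, s$volume, study$atlas)$fc)
alt  <- altered_connectivity(fbns[cls == "A"], fbns[cls == "B"])
alt$top_edges      # strongest group-difference edges (i, j, difference)
#>   i j difference
#> 4 1 4  0.1179791
```

`cross_validate()` runs the stratified 5-fold protocol,
`roi_importance()` ranks ROIs by shielded classification accuracy, and
`fbn_cli()` (or `inst/cli/fbngan.R`) exposes
`simulate / train / construct / evaluate / analyze` subcommands for shell
pipelines over NIfTI + TSV datasets.

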