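---
title: "Additional neural matrix factorization: model, training and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Additional neural matrix factorization: model, training and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Computational drug repositioning asks which approved drugs might treat
diseases they were never designed for. The data are a binary association
matrix $R \in \{0,1\}^{m \times n}$ ($R_{ij} = 1$ iff drug $i$ is verified
to treat disease $j$), a drug–drug similarity matrix (e.g. Tanimoto scores
over chemical fingerprints) and a disease–disease similarity matrix (e.g.
text-mining similarity of clinical descriptions). Verified associations are
extremely sparse — around 1% of all pairs in the standard benchmark
collections — so a model that relies on the interaction matrix alone has
very little signal per drug. This package implements a neural matrix
factorization model that fuses the similarity matrices into the latent
representation of each drug and disease, which is what "additional" refers
to: auxiliary (side) information is added to the hidden-feature extraction.

## The model

**Hidden features.** Each drug $i$ has an interaction profile
$s_i = R_{i\cdot}$ and a similarity vector $DrugSim_{i\cdot}$. A denoising
autoencoder corrupts both (masking noise by default), encodes them into a
$k$-dimensional hidden feature

$$z_i = g(W_1 \tilde s_i + V_1 \widetilde{DrugSim}_{i\cdot} + b),$$

and decodes $z_i$ back to *both* the clean profile,
$\hat s_i = f(W_2 z_i + b_{\hat s})$, and the clean similarity vector,
$\widehat{DrugSim}_{i\cdot} = f(V_2 z_i + b_{sim})$. Reconstructing the
similarity vector is what forces similar drugs toward similar hidden
features. The per-drug reconstruction loss balances the two targets and
penalizes the weights:

$$L_i^{drug} = \alpha \lVert s_i - \hat s_i \rVert^2
  + (1-\alpha) \lVert DrugSim_{i\cdot} - \widehat{DrugSim}_{i\cdot} \rVert^2
  + \lambda \left( \textstyle\sum_l \lVert W_l \rVert^2 + \lVert V_l \rVert^2 \right).$$

Diseases get a second, symmetric autoencoder over columns of $R$ and the
disease similarity matrix, with its own balance $\beta$ and regularization
$\delta$.

**Prediction.** The treatment probability of a pair is a generalized
matrix factorization (GMF) head: the elementwise product of the two hidden
features passed through a single-layer perceptron,

$$\hat r_{ij} = F_{out}\!\left(h^\top (z_i \odot z_j^{dis})\right),$$

with a sigmoid $F_{out}$ so the score is a probability. Unlike a plain
inner product, the learned weight vector $h$ lets each latent dimension
contribute with its own sign and magnitude. The prediction loss is binary
cross-entropy. (The likelihood form is written with opposite sign in parts
of the literature; since the objective is *minimized*, the package uses the
standard negated cross-entropy — minimizing the raw log-likelihood would
drive predictions away from their targets.)

**Joint objective.** Training minimizes, over the verified positives
$R^+$ and sampled negatives $R^-$,

$$\mathcal{L} = \sum_{(i,j) \in R^+ \cup R^-}
  \left[ \mathrm{BCE}(\hat r_{ij}, r_{ij})
  + \varphi L_i^{drug} + \psi L_j^{disease} \right].$$

The encoder parameters are shared between the reconstruction terms and the
prediction term, so the hidden features are shaped by both. The
reconstruction terms are charged once per pair *occurrence* (the literal
reading of the sum), so frequently interacting drugs are reconstructed more
often.

## Hyperparameters

| symbol | meaning | default | why |
|---|---|---|---|
| $\alpha$ | drug profile vs. similarity balance | 0.7 | validated setting for this model family |
| $\beta$ | disease-side balance | 0.3 | idem |
| $\lambda$ | drug-side weight decay | 0.001 | idem |
| $\delta$ | disease-side weight decay | 0.01 | idem |
| $\varphi,\psi$ | reconstruction weights in the joint loss | 0.5 | idem |
| $k$ | hidden dimension | 128 | peak of the validated dimension sweep |
| $N$ | negatives per positive | 10 | larger $N$ increasingly mislabels unknown positives |
| noise | masking level on all encoder inputs | 0.3 | the level the reference results use |

Negative sampling draws, for every positive, $N$ unobserved cells of the
training matrix uniformly without replacement, and redraws them every epoch
(dynamic sampling, in the word2vec tradition); a static mode exists for
exact-reproducibility experiments. Sampled negatives can never collide with
training positives, and the trainer asserts this every epoch.

## Optimization choices

The reference description of this model family fixes the model
hyperparameters but not the optimizer. The package uses plain mini-batch
SGD (no momentum or adaptive steps), stepping by the batch *mean* of the
per-pair gradient so the learning rate does not depend on the batch size.
The defaults — batch size 64, learning rate 1.25, at most 150 epochs —
were chosen once on planted-factor validation data as the smallest-budget
configuration whose validation AUC had clearly plateaued; moderate batches
optimize appreciably better here than large ones at equal cost, because
the objective couples a dense reconstruction term to every sampled pair.
One interaction per multi-interaction drug is held out as a validation set
(drugs with a single interaction are never touched, so the cold-start
protocol stays clean), training stops after 25 epochs without
validation-AUC improvement, and the best-epoch parameters are kept.
Corruption masks are redrawn every epoch. All randomness flows from one
master seed through independent named streams (initialization, validation
split, corruption, negative sampling, batch shuffling), so a fit is a
deterministic function of data and seed.

Numerical details: weights initialize uniformly in
$\pm\sqrt{6/(fan_{in}+fan_{out})}$ with zero biases; predicted scores are
clipped to $[10^{-12}, 1-10^{-12}]$ before logarithms; biases are excluded
from weight decay; a non-finite batch loss aborts with a diagnostic rather
than training on. The decoder and output activations are sigmoid, so
reconstructions and scores live in $(0,1)$, matching binary profiles and
$[0,1]$ similarities; the *hidden* activation $g$ defaults to tanh. The
zero-centered hidden features matter for this architecture: with a sigmoid
hidden layer every latent coordinate is positive, the elementwise products
$z_i \odot z_j$ are all positive, and the single weight vector $h$ cannot
express signed per-dimension interactions — on planted-factor data this
caps held-out AUC well below what the same model reaches with tanh
features. Sigmoid hidden units remain available through
`anmf_control(g = "sigmoid")`. The encoders are
single-layer by design; the open choice of pre-training the autoencoders
before joint training was decided against — the joint objective already
couples the two pathways, and joint-only training keeps the procedure one
pass.

## Evaluation protocols

`make_cv_splits()` partitions verified associations (by pair, not by drug)
into ten near-equal folds; each fold's model is retrained from scratch on
the remaining nine tenths, and every unverified pair joins the test side as
a candidate. `make_new_drug_split()` implements the cold-start protocol:
drugs with exactly one verified association contribute it to the test set,
and the model must rank it from the similarity pathway alone.

Metrics: AUC via the midrank Mann–Whitney statistic (ties count ½); AUPR
via a descending-score sweep with non-interpolated step summation (AUPR is
sensitive to the interpolation convention, hence the explicit choice); and
Hit Ratio at cutoffs $n$, where each test positive is ranked among the
unverified diseases of its own drug, with pessimistic tie handling so a
constant scorer earns no hits. Per-drug ranking is the convention of the
neural collaborative-filtering lineage this model belongs to; a global
ranking pool is available behind a flag. Cross-validated results are
reported both per-fold-averaged and pooled, since both conventions appear
in the literature.

## The synthetic generator

`synthetic_dataset()` plants drug factors $U$ and disease factors $V$
(i.i.d. standard normal, $k_{true}$ columns), sets the true treatment
probability to $\sigma(UV^\top + \varepsilon - c)$ with logit-scale noise
$\varepsilon$, calibrates $c$ by root finding so the mean probability hits
the target density, and samples $R$ as Bernoulli draws (or, optionally, the
top cells). Similarities mix the $[0,1]$-mapped cosine similarity of the
planted factors with symmetric uniform noise under a `sim_signal` weight.
The default shape (593 × 313, density 0.0104) mirrors the standard
benchmark; the default observation noise (`noise_sd = 0.5`) represents a
moderate corruption of the planted signal and was fixed once, not tuned.
The generator emulates the *statistical* structure the model assumes —
low-rank propensity plus factor-correlated similarities. It does not
emulate chemistry, disease ontology structure, the long-tailed degree
distributions of curated databases, or systematic reporting bias, so
passing recovery tests here demonstrates correctness of the machinery, not
clinical performance on real collections.

A recovery experiment on a 200 × 100, $k_{true} = 8$, density 0.05,
`sim_signal` 0.8 instance (the scale used throughout the test suite to
keep runtimes in minutes) trains the default model on 80% of the positives
and ranks the held-out fifth against all unverified pairs; the test suite
requires held-out AUC at least 0.85 and at least 0.30 above a
label-shuffled control, and the similarity ablation (`fit_gmf()`, which
freezes the similarity pathway at zero) must not beat the full model in
median validation AUC over five seeds when the similarities carry signal.

## Known limitations

- Plain SGD needs hundreds of epochs at these scales; adaptive optimizers
  would converge faster but are deliberately out of scope.
- The reconstruction terms dominate the gradient early in training; the
  prediction head catches up once the autoencoders settle. Monitor
  `tidy(fit)` if training looks stalled.
- Hit-ratio values depend strongly on the ranking-pool convention; compare
  numbers across implementations only after checking it.
- The similarity matrices are consumed as given: computing them from
  SMILES strings or clinical text is outside this package's scope.
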