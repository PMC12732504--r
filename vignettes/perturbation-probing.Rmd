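---
title: "Probing single-cell decoders for perturbation structure"
author: "perturbflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probing single-cell decoders for perturbation structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`perturbflow` trains a β-variational autoencoder whose observation model
is a negative binomial (NB) per gene,

$$\mathrm{NB}(k; m, r) = \frac{\Gamma(k+r)}{k!\,\Gamma(r)}
\left(\frac{m}{r+m}\right)^{k}\left(\frac{r}{r+m}\right)^{r},$$

with mean $m$ and dispersion $r$ (variance $m + m^2/r$), capturing the
overdispersion of UMI counts. The decoder maps a latent variable
$z \in \mathbb{R}^d$ to a strictly positive normalized mean per gene,
which is multiplied by the cell's mean count (its library scale) to give
$m$; one free dispersion is learned per gene, shared across cells
(optimized as $\log r$, initialized at $r = 1$). The encoder consumes
mean-scaled, log1p-transformed counts and parameterizes a diagonal
Gaussian posterior. Training minimizes

$$\mathcal{L}_\beta = \underbrace{\mathbb{E}_{q_\phi(z|x)}
\left[-\log p_\theta(x \mid z)\right]}_{\text{NB reconstruction}}
\;+\; \beta\, \mathrm{KL}\!\left(q_\phi(z|x)\,\|\,\mathcal{N}(0, I)\right),$$

with $\beta$ annealed linearly from 0 to a small final value (default
`1e-3`), so the converged model is almost an autoencoder while the prior
still regularizes the latent scale. One reparameterized posterior sample
is used per training step; evaluation (validation loss, embeddings)
uses the posterior mean. Optimization is minibatch Adam with early
stopping on the validation loss and best-weight restoration. Because no
automatic-differentiation framework is assumed, all gradients are
hand-written reverse-mode passes over the MLP forward computations; the
unit tests verify every parameter gradient against central finite
differences.

**Activation choice.** Hidden layers default to softplus rather than
ReLU. The perturbation probe differentiates the decoder with respect to
$z$ and validates those derivatives against finite differences at
`1e-4` relative tolerance; ReLU kinks make that comparison fail on a
measurable fraction of random points, while softplus is a rectifier
with exact derivatives everywhere. ReLU remains available in
`nbvaeConfig(activation = "relu")`. The decoder output link is softplus
plus `1e-8`, guaranteeing strictly positive NB means with smooth
gradients; an identity link exists purely for analytic test doubles.

**Auxiliary heads.** Arbitrary perturbation types (a binary treatment,
a continuous developmental time) are modeled as linear heads on the
latent space: binary heads output a probability through a sigmoid and
are trained with binary cross-entropy, continuous heads with an L1
loss. Head losses are averaged over *observed* labels only, so a 10%
label fraction changes neither the gradient scale nor the objective of
unlabeled cells; a weight α (default 10 for binary, 1 for continuous —
chosen so a sparsely labeled head still shapes the latent space without
dominating reconstruction) multiplies each head's loss.

# Preprocessing conventions

Cells are kept with ≥ 200 detected genes, ≥ 500 total counts, and
< 5000 detected genes; genes are then kept when detected in ≥ 5 cells
(cells first, then genes). "Scaled by the mean count per cell" is read
literally: each cell's counts are divided by that cell's mean count
across genes (total/number of genes), then log1p-transformed; the
inverse transform (expm1, multiply by the stored scale factor, round)
recovers raw counts exactly, and raw counts are the reconstruction
targets. The alternative reading (a dataset-level mean) would be a
one-line change of the scale-factor definition.

Highly variable genes are ranked by a binned dispersion statistic —
variance/mean of the normalized values, z-scored within 20 bins of
similar mean expression — with ties broken by raw dispersion and then
identifier, so selection is fully deterministic. Genes in
`forceInclude` displace the lowest-ranked picks, keeping the selection
size exact. The train/validation/test split (82/9/9) floors the
validation and test sizes and gives the remainder to training, so each
partition deviates from its exact fraction by less than one cell; the
permutation is seeded.

# The gradient probe

For a chosen scalar output $y_i$ (a gene's normalized decoder mean, or
an auxiliary head), `outputGradient()` returns the exact reverse-mode
derivative $\nabla_z y_i(z)$. Gradients are taken at unit cell scale:
the library scale is a positive per-cell constant, so it rescales
magnitudes but never directions. Perturbations are simulated by plain
forward-Euler iteration $z_{t+1} = z_t + \delta \nabla y_i(z_t)$
(defaults $\delta = -0.001$, 400 steps; negative δ is knockdown,
positive δ overexpression); no adaptive stepping is used, and a
trajectory that reaches a non-finite state is truncated with a warning
rather than discarded. Evaluation points are either a seeded subsample
of the observed cell embeddings (high-dimensional latents cannot be
covered uniformly) or a regular lattice for 2-D latents. A density mask
drops points whose distance to their k-th nearest training latent
exceeds a quantile of that same statistic over the training latents
(defaults k = 15, quantile 0.99 — wide enough to keep essentially all
observed data while removing extrapolated regions).

Fields over gene *sets* are the mean of per-gene gradient fields for a
user-supplied list; discovery of co-regulated sets is out of scope.

For visualization, PCA projects points and vectors through the same
linear map (vectors uncentered, so the projection is exactly linear;
axis signs follow the largest-loading-positive convention), optionally
interpolated onto a regular grid by barycentric interpolation over a
Bowyer–Watson Delaunay triangulation written in-package (no R
triangulation library is assumed; the implementation is validated
against a per-triangle closed-form oracle and reproduces affine fields
exactly). UMAP, being nonlinear, cannot project vectors: instead the
perturbed endpoints $z + \delta_{display}\nabla y_i(z)$ are appended to
the data, a joint seeded embedding is fitted (via the bundled
python/umap-learn bridge), and the displayed vector is the difference
of embedded endpoint and origin. $\delta_{display}$ defaults to the
total displacement of the default flow ($\delta \times$ steps = −0.4),
since per-step displacements vanish visually.

# Alignment scoring

The empirical perturbation axis is the difference of latent group means,
$a = \bar z_{perturbed} - \bar z_{unperturbed}$; a zero-norm axis is
rejected at scoring time. The cosine score $s_i$ averages
$\cos\angle(\nabla y_i(z), a)$ over evaluation points; points with
zero-norm gradient are skipped and counted (treating them as zero would
bias scores toward orthogonality), with a warning past 50% skipped and
an error when all are. The magnitude-weighted variant
$\tilde s_i = \mathrm{avg}_z\, \nabla y_i(z)^\top a / \lVert a\rVert$
couples direction with local effect size and is unbounded; zero
gradients legitimately contribute 0 there. The default evaluation set is
all observed cells of both conditions encoded to posterior means —
restricting to one condition or one cell type yields
cell-state-conditioned rankings, which the tests exercise via a
piecewise decoder double. Ranking uses $|s_i|$, ties broken by gene
identifier.

The baseline decodes NB means at the coordinate-wise median latent of
each condition (the median of a latent cloud is otherwise undefined in
several dimensions) and scores the symmetric change
$b_i = (m_i^{(1)} - m_i^{(0)}) / \tfrac12 (m_i^{(1)} + m_i^{(0)})
\in [-2, 2]$, with $b_i = 0$ when both means vanish. Swapping condition
labels negates $a$, every $s_i$, $\tilde s_i$ and $b_i$ exactly — an
algebraic identity the acceptance tests assert.

# Enrichment and the LLM judge

The top 200 genes by $|s_i|$ (configurable) are tested for
overrepresentation against GMT gene-set collections with a one-sided
hypergeometric test (`stats::phyper`) and Benjamini–Hochberg FDR
(`stats::p.adjust`) — the same statistic hosted ORA services compute,
reimplemented in-repo so the analysis is testable offline against an
exact Fisher oracle. The background universe defaults to the genes the
model scores; sets are size-filtered (5–500 after universe
intersection) before testing.

Pathway relevance is judged by a two-stage prompt pipeline: a
first-stage relevance prompt is sent three times (combating sampling
nondeterminism), the three answers are embedded in a second-stage
verdict prompt, and the final Yes/No is parsed from the reply's first
alphabetic token (case-insensitively; a fallback scans for a standalone
yes/no; anything else is "undetermined", as are pathways whose backend
calls fail three retries). The backend is any function from prompt text
to reply text; tests and offline runs use a deterministic scripted mock,
and all prompts and raw replies are retained as JSON-lines for audit.
Prompt rendering is byte-stable and golden-file tested.

# The synthetic generator

`generateSyntheticData()` is the ground-truth substrate for every
validation: latents come from a mixture of unit-variance Gaussians at
separated centers, condition-1 cells are displaced by a known axis
$a_{true}$, per-gene means follow
$\text{libraryScale} \cdot \exp(Wz + b)$ (exponential link — a
deliberate mild mismatch with the decoder's softplus link, so recovery
does not depend on sharing the generator's functional form; softplus is
available for exact-recovery experiments), and counts are NB with
configurable dispersion. Cluster centers are drawn orthogonal to the
condition axis: cell-type identity and condition displacement are
separate latent directions, so both "cell types" shift along the axis
rather than confounding with it. Effect genes load (anti-)parallel to
the axis; the rest load orthogonally, so ground-truth alignment is ±1
versus 0 and `truthGradient()` gives every gradient in closed form.

The `knockdown` preset (3,000 cells × 300 genes, 8 latent dimensions, 3
clusters, axis norm 3) makes its 30 effect genes a *marker program*:
loading norm 0.8 (an ~11-fold change across the axis, the
knockout-like regime) and 6× baseline expression. This reflects what a
genetic-knockout contrast looks like — the condition-defining genes are
highly expressed lineage markers essentially lost in the knockout — and
it matters quantitatively: gradient magnitude scales with expression
times loading, so marker-level genes are exactly the regime in which a
fixed-step Euler flow (δ = −0.001, 400 steps) visibly transports cells
between conditions. The `treatment` and `time` presets instead model a
chemical/temporal exposure that shifts many genes moderately
(mixed-sign loadings of norm 0.4, no expression boost; treatment uses
axis norm 5 so the conditions are separable for auxiliary-head
training). Binary and continuous labels are emitted with exactly
`round(0.10 · n)` observed entries (seeded); time is the projection of
$z$ onto a designated axis plus Gaussian noise (sd 0.3). Library sizes
are lognormal around 2,000 counts per cell so that generated cells
comfortably clear the default quality filters.

What the generator does *not* emulate: gene-regulatory network
structure, batch effects, ambient RNA, doublets, or zero inflation
beyond the NB. Passing tests therefore demonstrate that the probe
recovers planted low-dimensional perturbation structure from
overdispersed counts — not that it resolves the full complexity of real
tissue atlases.

# Numerical choices and degenerate inputs

* NB log-pmf via `lgamma`, finite for all valid inputs; the pmf
  normalizes to 1 within `1e-8` over a wide (m, r) grid and approaches
  the Poisson log-pmf at large r with the analytic
  $(k(k-1) - 2km + m^2)/(2r)$ gap.
* Posterior log-variances are clamped to [−10, 10] for stability (the
  clamp is inactive at convergence).
* Finite-difference validation uses central differences at `h = 1e-4`,
  with per-point relative error measured against the gradient's max
  component.
* Empty filter results, zero-norm axes, all-zero-gradient scores,
  unknown outputs/heads, dimension mismatches, collinear point sets,
  and malformed files all raise immediate, named errors; degenerate
  duplicates in the triangulation are skipped.
* All stochastic steps (initialization, shuffling, reparameterization
  noise, subsampling, UMAP) take explicit seeds; training is
  bit-for-bit reproducible under a fixed seed and single-threaded
  numerics.

# Problem sizes used by the validation suite

The test and acceptance runs train on the presets' native 3,000 × 300
size (about a minute per model on one CPU) with latent dimension 8 and
hidden sizes 128/64, and use smaller dedicated configurations (400 ×
60, 2,000 × 150) for quick unit checks and loading-recovery
experiments; those sizes are the package's validation design, chosen so
the whole suite runs on a laptop in a few minutes. Gradient exactness
is checked at latent dimensions 2 and 32 — the two settings the
architecture defaults target.

# Known limitations

* The flow is first-order Euler; no geodesic or second-order
  correction. Step size and count are the user's responsibility, though
  the self-limiting gradient of saturating genes makes knockdown flows
  robust to overshoot.
* Alignment scores are local averages: a gene whose field aligns with
  the axis in one region and anti-aligns in another can score near
  zero globally (the evaluation-set restriction exists precisely for
  this).
* The NB β-VAE is trained per dataset; no cross-dataset integration,
  batch correction, or alternative likelihoods (ZINB, Poisson).
* The UMAP projection inherits UMAP's distortions; displayed vectors
  are qualitative. PCA projections are exact but linear.
* The LLM judge's scientific quality is entirely that of its backend;
  the package only guarantees the prompt protocol, retry policy, and
  deterministic parsing.
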