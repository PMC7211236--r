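---
title: "Discriminant analysis on the Grassmann manifold: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminant analysis on the Grassmann manifold: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmgda)
```

## The model

Many signals are better described by the *subspace* they span than by
any single feature vector: the frames of a short video, repeated
measurements of a face, or — the use case this package ships a
front-end for — the set of short-time spectrograms of one EEG
recording. A p-dimensional subspace of $\mathbb{R}^D$ is a point of
the Grassmann manifold $\mathcal{G}(p, D)$, represented here by any
$D \times p$ matrix $X$ with orthonormal columns ($X^\top X = I_p$).
Two bases related by a $p \times p$ rotation are the same point, and
every function in this package is invariant to that choice.

Subspaces are compared through the projection embedding
$\Pi(X) = X X^\top$ (the unique orthogonal projector onto the
subspace) and the projection metric

$$\delta_P(X_1, X_2) = \tfrac{1}{2}\,\lVert X_1 X_1^\top -
X_2 X_2^\top \rVert_F^2,$$

computed stably as $p - \lVert X_1^\top X_2 \rVert_F^2$. The constant
$\tfrac{1}{2}$ is kept exactly as conventionally printed for this
metric; it rescales every distance equally and has no effect on
rankings, nearest neighbours, or the optimization below. For two
lines, $\delta_P = \sin^2\theta$; for fully orthogonal subspaces it
attains its maximum $p$.

Under $\delta_P$ the Fréchet mean of a sample — the subspace
minimizing $\sum_i \delta_P(X_i, M)$ — has a closed form: the span of
the $p$ leading eigenvectors of the summed projectors
$\sum_i X_i X_i^\top$. `frechet_mean()` implements exactly this; when
eigenvalues $p$ and $p+1$ tie (relative gap below `1e-8`) the mean is
genuinely non-unique in the tied directions and the function warns
and returns the solver's order. Ties are measure-zero but arise in
designed examples (e.g. two balanced orthogonal classes).

### The supervised objective

Given labeled points, `fmgda()` learns a map $A \in \mathbb{R}^{D
\times d}$ ($p \le d < D$) to a smaller Grassmannian
$\mathcal{G}(p, d)$. Because $A^\top X$ is not orthonormal, every
mapped basis is re-orthonormalized through its QR decomposition:
with $A^\top X = QR$, the mapped point is $Q$, equivalently
$A^\top X'$ with $X' = X R^{-1}$. With class Fréchet means $M^{(k)}$
and global mean $M$, the objective is the ratio of between-class to
within-class squared distances after mapping,

$$\max_A \; \frac{d_b(A)}{d_w(A)}
 = \frac{\sum_k n_k \lVert A^\top M'^{(k)} M'^{(k)\top} A -
          A^\top M' M'^\top A\rVert_F^2}
        {\sum_k \sum_i w_k \lVert A^\top X_i'^{(k)} X_i'^{(k)\top} A -
          A^\top M'^{(k)} M'^{(k)\top} A\rVert_F^2}.$$

The within-class weight $w_k$ deserves a note: the printed form of
this objective carries the class size $n_k$ *inside* the double sum,
unlike classical LDA. The package keeps that as the default
(`within_weighting = "paper"`) and offers the classical
`"uniform"` variant, because the printed factor is plausibly
unintended; both satisfy the same consistency identities and tests
cover both.

### The optimizer

The four unknowns ($A$ and the three primed, QR-normalized
quantities) are untangled by alternating:

1. freeze the QR normalizations at the current $A$ and accumulate two
   symmetric $D \times D$ surrogates
   $\tilde B = \sum_k n_k B^{(k)} A A^\top B^{(k)}$ and
   $\tilde Q = \sum_k \sum_i w_k Q_{ik} A A^\top Q_{ik}$, whose trace
   ratio at the expansion point equals the exact objective (verified
   in the tests to $10^{-8}$ relative on random instances, and in
   fact exact to machine precision);
2. maximize $\mathrm{tr}(A^\top \tilde B A)/\mathrm{tr}(A^\top \tilde
   Q A)$ over orthonormal $A$ with the standard trace-ratio fixed
   point — iterate $\lambda \leftarrow$ current ratio, $A \leftarrow$
   top-$d$ eigenvectors of $\tilde B - \lambda \tilde Q$ — whose
   $\lambda$ sequence is non-decreasing.

Two properties of this scheme shaped the implementation:

* **The exact objective need not increase monotonically.** The
  surrogate touches the exact objective only at the expansion point,
  so a full inner maximization can overshoot into a region where the
  exact ratio is lower; empirically the exact trace dips and rises.
  `fmgda()` therefore records the full trace and returns the **best
  iterate** (including the initialization), which makes the fitted
  objective never worse than the start by construction. The
  diagnostics (`tidy()`, `autoplot()`) expose the whole trace rather
  than hiding the non-monotonicity.
* **The trace-ratio problem is ill-posed when $\tilde Q$ is
  rank-deficient**, which happens whenever $D$ far exceeds the number
  of training points times $p$: directions exist that annihilate the
  within-scatter while keeping between-scatter, so $\lambda$ grows
  without bound and the map can collapse onto the span of the class
  means, making $A^\top X$ rank-deficient for individual points. The
  package guards the $d_w \to 0$ case with a ridge
  ($\varepsilon = 10^{-10}\,\mathrm{tr}(\tilde Q)/D$, or $10^{-10}$
  for a numerically zero $\tilde Q$) and raises an explicit rank
  error naming the offending point when a QR normalization fails.
  Working at a sample size commensurate with $D$ (or reducing $D$
  with the spectrogram `resize` option) is the structural fix.

### Initialization

The map must start somewhere, and the start is part of the study
conditions because the first surrogate is built at it. A
coordinate-block start (first $d$ columns of the identity) is
deterministic but can be nearly singular against real feature bases:
smooth spectrogram features have almost-collinear leading pixel
coordinates, and $A_0^\top X$ then has condition numbers large enough
to wreck the normalization ($X' = X R^{-1}$ explodes). The default is
therefore `init = "mean"`: the top-$d$ eigenvectors of the pooled
projector sum $\sum_i X_i X_i^\top$ — equally deterministic,
data-adaptive, and well-conditioned because it spans where the data
actually live. `"identity"` and a seeded `"random"` start remain
available.

### Stopping

The outer loop stops when the exact objective changes by less than
`tol = 1e-6` (relative) or after `outer_iters = 20` alternations; the
inner solver stops at `inner_tol = 1e-8` on $\lambda$ or 50
iterations. No stopping rule is canonical for this scheme; these are
ordinary values for trace-ratio solvers, and the experiment-grid
helpers accept smaller budgets where dozens of fits are run.

## The EEG front-end

`read_bonn_directory()` reads the five-group single-channel archive
layout (folders `Z/O/N/F/S` for groups A–E, one ASCII sample per
line, 4097 samples at 173.61 Hz per segment). Each segment is

1. tiled into sub-epochs (`subepoch_len = 512` samples ≈ 2.95 s,
   `hop = 512`, giving $M = 8$ per Bonn segment — the "frames" of the
   image set);
2. turned into a log-power spectrogram per sub-epoch: Hann-tapered
   STFT with `stft_window = 128`, `stft_overlap = 64`,
   `fft_size = 128`, giving $m = 7$ frames $\times$ $n = 65$ one-sided
   bins, and $\log(\text{power} + 10^{-12})$ so silence stays finite;
3. embedded as one Grassmann point: the $M$ spectrograms are
   vectorized column-major, stacked as the columns of $Y$, and the
   first $p$ left singular vectors of $Y$ become the basis, a point
   of $\mathcal{G}(p, 455)$ at the defaults. Basis column signs are
   fixed (largest-magnitude entry positive) so the pipeline is
   bit-for-bit deterministic.

None of the STFT geometry is canonical — the source experiments do
not report their settings — so all of it is configurable and the
defaults were chosen once for tractability ($D = 455$ keeps the
$d \le 60$ grid meaningful) and documented here. Block-average
`resize` is available when other STFT settings inflate $D$.

**Choosing p.** The default `p = 5` suits recordings whose spectral
content drifts across sub-epochs (real EEG). For the *synthetic*
generator below, whose band mixtures are stationary, the spectrum
set has numerical rank close to 1: basis columns beyond the first are
noise directions, and because the Grassmann map re-orthonormalizes
$A^\top X$, a mapped noise direction is re-amplified to unit length no
matter how strongly the map attenuated it. Small $p$ is then not a
convenience but the correct model; the end-to-end experiments in the
tests use `p = 1`. This re-amplification effect is intrinsic to
subspace representations (a subspace has no notion of "weak"
directions) and is the single most important practical caveat when
picking $p$.

Note also that $d = p$ makes the target $\mathcal{G}(p, p)$ a single
point — every mapped subspace is the whole space and all distances
vanish — so the grid helper requires every tested dimension to be at
least $p$, and meaningful columns need $d > p$.

## Classification and experiment grids

`knn_predict()` is nearest-neighbour classification under
$\delta_P$, with deterministic tie-breaking (vote, then summed
distance, then label order). `stratified_split()` samples
$\mathrm{round}(r\,n_k)$ items per class (round half up) without
replacement, deterministically per seed. `run_grid()` reproduces the
standard evaluation protocol: train ratios $\{0.1, 0.2, 0.4, 0.6,
0.8\}$ by target dimensions $\{4, 6, \dots, 60\}$, several repeats
per cell, 1-NN after mapping, plus a no-reduction baseline, with
results as tidy tibbles and a ratio-by-dimension CSV writer. Splits
are assumed stratified per group because training data are drawn
from each group's instances.

## The synthetic generators

`gen_grassmann_classes()` draws K prototype subspaces (redrawn until
pairwise $\delta_P \ge$ a separation floor; mutually orthogonal
construction when the maximum $p$ is requested, since random redraws
cannot hit a measure-zero target) and perturbs members as
$\mathrm{orth}(X + \sigma G)$ with Gaussian $G$ — a simple local
spread on the manifold, adequate for fixtures though not an exact
tangent-space law.

`gen_synthetic_eeg()` emulates the *shape* of the five-group archive:
4097 samples at 173.61 Hz per segment, five classes with disjoint
dominant bands, and an ictal analogue with strong low-frequency
rhythm, Poisson-timed biphasic spikes, and doubled noise. Band
oscillations are sums of eight random-phase sinusoids drawn uniformly
within the band, scaled to a target mean power; amplitudes sit on an
integer-ADC-like scale (band power 400, noise SD 5) so the signals
survive the integer rounding of the Bonn file format. What it does
*not* emulate: 1/f background, nonstationarity, artifacts, inter-
subject variability. Passing end-to-end tests on this generator shows
the pipeline's plumbing and the learner's behaviour under clean class
structure — not performance on real EEG.

## Problem sizes used by the tests

The test suite and the acceptance script run, among others: the
Fréchet-mean sphere-grid oracle on 20 instances ($D \le 5$, $p = 1$,
$10^4$ candidates); 50 random trace-ratio pencils plus a $10^5$-sample
Monte-Carlo lower bound on $5 \times 5$ instances; supervised recovery
at $K = 3$, $D = 40$, $p = 5$, $d = 10$, 30 points per class at noise
0.05, with a 10-repeat shuffled-label chance control; and the full
five-ratio by fourteen-dimension EEG grid on 15 synthetic segments
per class with one repeat per cell and a reduced optimizer budget
(3 outer, 12 inner iterations) — sizes chosen so the whole suite runs
in about a minute while still exercising every code path at the
documented conditions.

## Reproducing the published protocol on real data

With the real five-group archive downloaded into its usual folder
layout, the identical protocol runs via `read_bonn_directory()` +
`featurize_dataset()` + `run_grid()` (or the bundled CLI script). On
real recordings the reported behaviour to look for — as a qualitative
smoke check, not an assertion — is a performance sweet spot for
target dimensions roughly between 20 and 35. The published accuracy
tables depend on unreported STFT settings, subspace dimension, and
random splits, so numeric agreement is not expected; the grid's
*structure* (and the dimension trend) is the reproducible part.

## Known limitations

* The alternating optimizer is a heuristic: no convergence proof, no
  global optimality; the best-iterate rule only guarantees
  improvement over the start.
* With $D \gg n p$ the discriminant problem is intrinsically
  under-determined; expect the separability guard, unbounded
  objectives, and possible rank errors rather than silently
  regularized answers.
* The projection metric approximates geodesic distance; no fidelity
  bound is asserted anywhere.
* Only the Stiefel-quotient representation and the projection metric
  are implemented; geodesics, exponential/log maps, and other
  Grassmann metrics are out of scope.
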