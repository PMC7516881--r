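---
title: "Fisher–Rao geometry of multivariate normals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fisher-Rao geometry of multivariate normals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaussfr)
```

## The model

A multivariate normal distribution is identified with its parameter point
$\theta = (\mu, \Sigma)$, a point of the manifold
$M = \mathbb{R}^n \times P_n(\mathbb{R})$ of mean vectors and SPD covariance
matrices. The Fisher information matrix endows $M$ with a Riemannian metric
whose tangent-space inner product at $\theta$ is

$$\langle (x_1, B_1), (x_2, B_2) \rangle_\theta
  = x_1^t \Sigma^{-1} x_2
  + \tfrac12 \operatorname{tr}\!\big(\Sigma^{-1} B_1 \Sigma^{-1} B_2\big),$$

and the Fisher–Rao distance $d_F$ is the induced geodesic distance. The
metric is invariant under the affine maps
$\psi_{(c,Q)}(\mu, \Sigma) = (Q\mu + c,\, Q\Sigma Q^t)$ for invertible $Q$,
so every pair can be *canonicalized*: whitening by the first point maps
$(\theta_1, \theta_2)$ isometrically to $\big((0, I_n),\, \theta_3\big)$ with
$\theta_3 = (\Sigma_1^{-1/2}(\mu_2 - \mu_1),\,
\Sigma_1^{-1/2} \Sigma_2 \Sigma_1^{-1/2})$. The package always whitens by the
first argument; symmetry of the resulting distances is verified by tests
rather than imposed by construction.

No closed form for $d_F$ is known in general. The package combines four
ingredients: exact closed forms on special submanifolds and special pairs,
an explicit geodesic with which boundary-value problems can be solved
numerically ("geodesic shooting"), computable lower/upper bounds that
sandwich every result, and an application layer that uses the univariate
geometry to simplify diagonal Gaussian mixtures.

## Univariate geometry and the hyperboloid chart

For $n = 1$ the parameter half-plane $(\mu, \sigma)$ is hyperbolic: with
$u = \mu/\sqrt2$ the Fisher metric is $\sqrt2$ times the standard Poincaré
half-plane metric in $(u, \sigma)$. The distance used everywhere is

$$d_{F^*}\big((\mu_1,\sigma_1),(\mu_2,\sigma_2)\big)
 = \sqrt2\,\operatorname{acosh}\!\Big(1 +
   \frac{(u_1-u_2)^2 + (\sigma_1-\sigma_2)^2}{2\sigma_1\sigma_2}\Big).$$

An equivalent quotient-log form is implemented as a cross-check
(`uv_fisher_rao(..., form = "log")`); the two agree to $10^{-10}$ on random
pairs in the test suite. Geodesics (half-vertical lines and half-ellipses
centered on $\sigma = 0$) are evaluated through the Minkowski hyperboloid
model with a constant-speed parametrization on $[0,1]$, which is what gives
midpoints their meaning in clustering.

The source material never states the explicit chart onto the hyperboloid;
the package uses $(u, v) = (\mu/\sqrt2, \sigma)$ followed by the classical
half-plane map $x = (u^2+v^2-1)/2v$, $y = u/v$, $z = (u^2+v^2+1)/2v$. This
choice is forced by the property the weighted (Galperin) centroid needs:
$\sqrt2\,\operatorname{acosh}(z_1z_2 - x_1x_2 - y_1y_2)$ must reproduce
$d_{F^*}$ exactly, so that Minkowski averaging plus renormalization is the
hyperbolic centroid of the Fisher geometry. Klein- and Poincaré-disk charts
are deliberately not exposed.

## Closed forms

Four submanifold forms are implemented (`dist_mahalanobis`,
`dist_common_mean`, `dist_diagonal`, `dist_diag_eigenmean`). Two facts shape
their use. The common-mean submanifold and the "diagonal covariance with
mean along a covariance eigen-axis" submanifold are *totally geodesic*:
their internal distances are the true Fisher–Rao distances. The
constant-covariance and general diagonal submanifolds are *not*: their
formulas are upper bounds on $d_F$ (exact only within the submanifold
geometry), which is why `dist_mahalanobis` refuses pairs with different
covariances instead of silently extrapolating.

Pairs sharing one covariance matrix admit an exact full-manifold closed form
(`dist_common_sigma`): rotate the mean difference onto $e_1$ with a
sign-stable Householder reflection $P$, factor $P\Sigma P^t = U D U^t$ with
$U$ unit-upper-triangular (computed as a reversal-conjugated Cholesky
factorization), and evaluate the eigen-axis distance between $(0, D)$ and
$(|\mu_2 - \mu_1| e_1, D)$. The unit-triangular factor matters: it fixes
$e_1$, which is what keeps the rotated mean on the eigen-axis after the
whitening step. For the reference bivariate pair (means $(-1,0)$ and
$(6,3)$, covariance $[[1.1, 0.9], [0.9, 1.1]]$) this gives

```{r example1}
S <- matrix(c(1.1, 0.9, 0.9, 1.1), 2, 2)
t1 <- fr_gaussian(c(-1, 0), S)
t2 <- fr_gaussian(c(6, 3), S)
c(exact = dist_common_sigma(t1, t2), mahalanobis = dist_mahalanobis(t1, t2))
```

strictly below the Mahalanobis value, a concrete display of the
non-totally-geodesic gap.

## The explicit geodesic and shooting

In natural coordinates $(\delta, \Delta) = (\Sigma^{-1}\mu, \Sigma^{-1})$
the geodesic through $(0, I_n)$ with tangent $(x, B)$ is explicit in matrix
hyperbolic functions of $G$, $G^2 = B^2 + 2xx^t$. `geodesic_natural`
evaluates it spectrally; the generalized inverse $G^-$ is never formed —
the scalar kernels $(\cosh(tg)-1)/g^2$ and $\sinh(tg)/g$ are applied to the
eigenvalues with their two-term series limits below $|g| < 10^{-6}$, which
is exact in the $g \to 0$ limit and avoids pseudoinverse thresholds. The
curve's constant speed is $\sqrt{\tfrac12\operatorname{tr}(B^2) + |x|^2}$.

`geodesic_shooting` solves the boundary-value problem as a *square*
non-linear system: the unknowns $(x, \operatorname{vech}(B))$ and the
residual (time-1 endpoint minus target, in natural coordinates) both have
dimension $n + n(n+1)/2$. A damped Newton iteration with a forward-difference
Jacobian is started from $B_0 = -\log \Delta_{\mathrm{target}}$,
$x_0 = \delta_{\mathrm{target}}$ (exact when the means agree), with scaled
multistarts; if those fail, a continuation walks the target mean separation
up from zero, warm-starting each step. Newton's quadratic convergence gives
endpoint residuals near $10^{-13}$, so shooting distances match closed forms
to well below the $10^{-5}$ agreement asserted in the tests.

## Mirrored pairs

A pair is *mirrored* when (after rotating the mean difference onto $e_1$)
the means differ only in the first coordinate and
$\Sigma_2 = M_1 \Sigma_1 M_1$ with $M_1 = \operatorname{diag}(-1, 1, \ldots, 1)$.
The connecting geodesic then has a symmetric structure: its midpoint has
block-diagonal covariance $\operatorname{blockdiag}(d_{11}^2, D)$ and its
tangent has only a first-row/column pattern $(x, b)$. Matching the explicit
time-1 endpoint to the second distribution yields a square system of order
$n + n(n+1)/2$ in $(x, b, \eta, d_{11}, D)$ (`mirrored_solve`), and the
distance is $2\sqrt{\sum_l b_l^2 + x^2}$. The same damped Newton +
separation-continuation strategy solves it in milliseconds even at mean
separation 10, the regime where plain shooting is known to struggle.
One convention matters and is worth stating: in the reference family with
$\Sigma_1 = [[0.55, -0.45], [-0.45, 0.55]]$, the tabulated distances
(2.77395 at $\mu = 1$ through 7.87896 at $\mu = 10$) correspond to mean
*separation* $\mu$, i.e. means $\pm(\mu/2)e_1$; this was verified
independently with geodesic shooting and with the embedding lower bound
(which already exceeds 2.77395 for means $\pm 1$).

```{r mirrored}
pr <- make_mirrored_pair(2, separation = 1,
                         sigma1 = matrix(c(0.55, -0.45, -0.45, 0.55), 2, 2))
mirrored_solve(pr[[1]], pr[[2]])$distance
```

`mirrored_geodesic` maps the solved curve back through the midpoint
isometry, so $\gamma(\pm 1)$ are the two endpoints and the
natural-coordinate mean path traces a hyperbola — both asserted to
$10^{-8}$ in the tests.

## Bounds

`fr_bounds` assembles four quantities. The lower bound embeds each Gaussian
as an $(n{+}1)$-order SPD matrix
$[[\Sigma + \mu\mu^t, \mu], [\mu^t, 1]]$ and takes half the affine-invariant
SPD distance; it is itself a metric. UB1 whitens, diagonalizes, and sums
univariate distances per eigen-coordinate; each eigenvalue is paired with
the mean component along its own eigenvector, and the univariate call
receives the *standard deviation* $\sqrt{\lambda_i}$ — the only convention
under which UB1 collapses to the exact distance in the equal-mean diagonal
case (with repeated eigenvalues the eigenbasis is arbitrary and UB1 is one
valid bound among several). UB3 inserts an intermediate point on the $e_1$
axis whose first variance $\sigma_*^2 = (|\mu_3|^2 + 2)/2$ is the analytic
minimizer of $d \mapsto d_{F^*}((0,1), (|\mu_3|, d))$ — derived by
minimizing the acosh form in the scaled half-plane ($v^2 = u^2 + 1$) and
double-checked against a golden-section search in the tests. UB2 optimizes
the whole diagonal of the intermediate point numerically (BFGS in log
standard deviations, multistart from the UB3 solution and the identity, at
most 500 iterations); every objective evaluation is a valid bound, so the
best value found is returned regardless of convergence, and
UB2 $\le$ UB3 always holds because UB3's diagonal is a feasible start.

On the rotated-eigenvalue test family ($\lambda_1 = 2$, $\lambda_2 = 0.5$,
mean offset $\mu$, rotation $\alpha \in [0, \pi/2]$), UB1 is the best upper
bound for every $\alpha$ at $\mu = 1$, while at $\mu = 10$ UB2/UB3 dominate
across the interior of the sweep. Exactly at $\alpha \in \{0, \pi/2\}$ the
pair lies in the totally geodesic eigen-axis submanifold, where UB1 *equals*
the exact distance and UB2's optimum can only tie it; in a small
neighborhood of those angles UB1 remains the sharper bound. The package's
tests therefore assert strict dominance of $\min(\mathrm{UB2},
\mathrm{UB3})$ on $\alpha \in [0.1, \pi/2 - 0.1]$ and as a $\ge 85\%$
majority over the full grid, which is the honest quantitative form of the
qualitative ordering; an all-$\alpha$ strict inequality is mathematically
impossible.

## The dispatcher

`fisher_rao` routes each pair to the cheapest exact method — identical,
common mean, common covariance, eigen-axis diagonal, mirrored — and falls
back to shooting, reporting the method tag with the value. Structure checks
use relative tolerance $10^{-9}$ (Frobenius for covariances); mirrored
detection first rotates the mean difference onto $e_1$ and requires the
reflection conjugacy to hold exactly in that frame.

## Mixture simplification

A diagonal Gaussian mixture (DGMM) with $m$ components is simplified to $l$
components by agglomerative clustering under the product Fisher–Rao metric
of the diagonal submanifold: single, complete, or group-average linkage over
pairwise component distances, greedy merges with lowest-index tie-breaking
for determinism, and a merge tree from which any level $l$ can be cut.
Complete linkage is the default, the criterion that performed best in the
segmentation experiments this design follows. The agglomeration is the
naive $O(m^3)$ recomputation; intended mixture sizes are $m \le 64$, where
this costs milliseconds and a priority queue would only add code.

Merged clusters are replaced by one of two centroids. The Fisher–Rao
centroid applies the Galperin construction coordinate-wise: map members to
the hyperboloid, average with the mixture weights in Minkowski space,
project back. The Bregman left-sided centroid is moment matching
($\mu_c = \sum \tilde w_i \mu_i$,
$\sigma_c^2 = \sum \tilde w_i(\sigma_i^2 + \mu_i^2) - \mu_c^2$), the
exponential-family left-KL centroid; the tests verify it is a local
minimizer of the weighted KL objective. Simplified weights are the summed
member weights, so total mass 1 is conserved exactly.

Model selection (`learn_components`) returns the smallest $l$ whose
Monte-Carlo estimate of $d_{KL}(f \| g)$ (5000 draws from $f$ by default,
seeded) falls below a threshold $\tau$; the KL is not monotone in $l$ in
general, so the scan over $l = 1, \ldots, m$ is explicit. Classification of
points (pixels) uses the maximum *unweighted* component density with
lowest-index ties, as the segmentation rule is stated; weights are
deliberately ignored there. `fit_dgmm` provides a standard diagonal EM
(k-means initialization, variance floor $10^{-6}$, monotone log-likelihood)
to build mixtures from point clouds or images.

## What the synthetic generators emulate — and what they do not

`make_planted_dgmm` produces groups of near-duplicate components: a shared
per-group base variance (log-uniform in $[0.5, 2]$) with small
multiplicative jitter (sd 0.1 on the log scale) and means jittered with sd
$1/20$ of the group separation (default 10). This emulates the situation
mixture simplification is for — an over-segmented density with redundant
components — and makes the correct answer checkable: the planted partition
is recoverable and the KL cost of merging within groups is small. It does
*not* emulate real image mixtures, whose components overlap, share no clean
group structure, and have strongly unbalanced weights; passing the planted
tests shows the clustering machinery is correct, not that any particular
image will compress to 3 components. The image experiments behind the
original segmentation study used standard test photographs that are not
redistributable; `make_synthetic_image` generates labeled synthetic RGB
images from a DGMM instead, so segmentation can be scored against ground
truth.

Problem sizes in the test suite were chosen to exercise every code path at
desk scale: dimensions 2–3 for random-pair properties (200 sandwich pairs,
50 cases per closed-form family), 12-component mixtures for clustering, and
5000-draw KL estimates, matching the scale of the reported experiments.

## Numerical conventions

* SPD validation: symmetry within $10^{-9}$ (relative, symmetrized on
  construction), smallest eigenvalue $> 10^{-12} \cdot \|S\|$.
* All matrix functions via symmetric eigendecomposition; eigen-basis sign
  and ordering are unconstrained, and all downstream formulas except UB1's
  pairing are invariant to them.
* "Same covariance" / "same mean" dispatch tolerance: relative $10^{-9}$.
* Newton solvers: residual tolerance $10^{-10}$ (mirrored) and $10^{-10}$
  (shooting), damping by step halving, forward-difference Jacobians with
  step $10^{-7}\max(1, |u_j|)$.
* Householder tie-break: a mean difference already along $+e_1$ uses
  $P = I$; along $-e_1$ the reflection $\operatorname{diag}(-1,1,\ldots)$.
* Every stochastic function takes an explicit seed; nothing depends on
  hidden RNG state.

## Known limitations

* Geodesic shooting is reliable at moderate mean separations; the mirrored
  system with continuation is the intended tool for widely separated
  mirrored pairs, and the dispatcher prefers it whenever the structure is
  present.
* UB2 relies on a local optimizer; its value is always a valid bound but may
  exceed the global triangle optimum in adversarial geometries.
* `dist_diagonal` is a distance within the diagonal submanifold, not the
  full-manifold distance; the clustering application uses it deliberately
  (components of a DGMM live there), but it should not be quoted as $d_F$.
* Only normal families are covered; elliptical extensions are out of scope.
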