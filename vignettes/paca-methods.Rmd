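---
title: "Methods: contrastive component analysis for case/control omics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contrastive component analysis for case/control omics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paca)
```

## The model and its assumptions

`paca` targets a specific, common situation in molecular epidemiology: a
disease cohort ("cases") and a healthy cohort ("controls") measured on the
same high-dimensional feature set (CpG methylation beta values, expression,
genotypes), where the question is not *case vs. control* but *what
structure exists among the cases that has no counterpart in controls*.
The working model is a low-rank factor decomposition

$$X = W_0 Z_{X0} + W_1 Z_{X1} + E_X, \qquad Y = W_0 Z_{Y0} + E_Y,$$

with isotropic Gaussian noise of standard deviation $\sigma$. $W_0$
($m \times k_0$, orthonormal columns) carries the shared sources of
variation — cell composition, ancestry, batch, age — and is typically
dominant; $W_1$ ($m \times k_1$) carries case-specific directions, and
$Z_{X1}$, the individual-level case-specific component, is the estimand.
Two assumptions matter:

1. **Orthogonality** ($W_0 \perp W_1$): case-specific directions are
   orthogonal to the shared ones. This licenses removal of shared
   variation by orthogonal projection. When it is mildly violated, the
   projection removes the component of $W_1$ lying in the shared span and
   recovery degrades gracefully (the generator exposes a violation knob
   for studying exactly this).
2. **More features than samples** ($m > \max(n_0, n_1)$): the CCA below
   operates on sample-space Gram matrices and needs them to carry the
   full sample geometry. The randomized variant (`fit_rpaca()`) covers
   the opposite regime.

Neither group's mean structure is modeled: each feature is centered
within each group separately before fitting. Per-group (rather than
pooled) centering is a deliberate choice — a bulk case/control mean shift
is a *location* effect, and pooled centering would convert it into a
spurious variance direction in both matrices, i.e. manufacture shared
variation that the CCA would then waste directions on. The centering
vectors are kept in the fit so new cohorts can be projected later.
Missing values are rejected at load time; imputation belongs upstream in
array QC, not inside the decomposition.

## Estimating shared variation: CCA in sample space

Classical CCA correlates feature combinations across two datasets sharing
samples. Here the datasets share *features*, so the roles are transposed:
we seek sample combinations $a \in \mathbb{R}^{n_1}$,
$b \in \mathbb{R}^{n_0}$ maximizing $a^\top X^\top Y b$ subject to
$\|Xa\| = \|Yb\| = 1$. The optimum $u_1 = Xa$ is a *feature-space*
direction: the representation in $X$ of the strongest source of variation
shared with $Y$. Successive directions are constrained orthogonal to
their predecessors, yielding $U_0 = [u_1 \dots u_r]$. The classical
solution is the top eigenvector of
$S_{XX}^{-1} S_{XY} S_{YY}^{-1} S_{YX}$ with $S_{XX} = X^\top X$ etc.;
`paca` instead whitens ($S_{XX} + \lambda I = R_X^\top R_X$ by Cholesky)
and takes the SVD of $R_X^{-\top} S_{XY} R_Y^{-1}$ — provably the same
solution, numerically stable, and the SVD delivers all $r$ directions
with the orthogonality constraints satisfied at once. The explicit
eigenproduct survives only as an independent oracle in the test suite,
where both routes are required to agree to $10^{-8}$ on canonical
correlations and to $10^{-6}$ radians on spans.

Two numerical details:

- **Ridge.** Row-centering makes every column family of the centered
  matrix sum to zero, so $S_{XX}$ is *exactly* singular — a positive
  ridge is not a luxury. The default is
  $\lambda = 10^{-8}\,\mathrm{tr}(S)/n$ per Gram matrix, far above the
  $\approx 10^{-13}$ relative level where Cholesky breaks and far below
  any data eigenvalue of interest. The centered cross-Gram vanishes along
  the same null direction, so the ridge cannot promote a spurious
  correlation. `ridge = 0` errors with advice rather than limping on.
  A useful side effect: when $X = Y$, the ridge-regularized problem's
  ordering exactly reproduces the PCA ordering of $X$, which the tests
  exploit.
- **Sign convention.** Every canonical direction and every component is
  sign-fixed so its largest-magnitude loading is positive (ties: lowest
  feature index). SVD signs are otherwise arbitrary, and serialized
  models must be reproducible bit-for-bit.

Given $\hat U_0$, the shared effect is removed by projection,
$X' = X - U_0 U_0^\top X$ (idempotent; $U_0^\top X' = 0$), and the top
$k_1$ principal components of $X'$ give the case-specific loadings
(left singular vectors) and scores (right singular vectors scaled by
singular values; a flag switches to unit-norm scores, the default keeps
the scale).

## Choosing how many directions to remove

Removing too few shared directions leaves background masquerading as
signal; removing too many costs power. `select_shared_dim()` scans
$r = 0, \dots, r_{\max}$ and tests, at each $r$, whether the case
residual still contains significant low-rank structure. The statistic is
the top-eigenvalue share $T_r = \lambda_1 / \sum_i \lambda_i$ of the
residual Gram matrix — the standard detection statistic for a
rank-one-versus-noise alternative. The null is built by pooling all
$n_0 + n_1$ samples and relabeling them into pseudo-groups of the
original sizes: when cases carry no extra structure, the labels are
exchangeable with respect to the residual spectrum. P-values use the
add-one estimator $(1 + \#\{T^{null} \ge T^{obs}\})/(1 + B)$, so the
smallest attainable p-value is $1/(B+1)$ and at least $B = 19$
permutations are required for testing at $\alpha = 0.05$.

Scanning $r_{\max}+1$ correlated tests and declaring signal when *any*
single $p_r < \alpha$ is anticonservative: the family-wise error
compounds across the scan, well beyond $\alpha$ even though the per-$r$
tests are strongly correlated. The scheme therefore
gates the decision with a Westfall–Young-style max-statistic test over
the exchangeable ensemble formed by the observed statistic vector and its
$B$ permuted versions: each scanned depth's statistic is z-standardized
against the ensemble's own column distribution, and the global p-value is
the self-inclusive rank of the observed $\max_r z_r$ among all members'
maxima. Under exchangeability this is exact (any symmetric column
standardization preserves it), and the continuous standardization avoids
the resolution loss of rank-based min-p gating, where with $B = 100$ and
eleven scanned depths up to eleven members tie at the $1/(B+1)$ floor and
genuine signal can become undecidable. The acceptance suite verifies the
resulting calibration directly (no-signal declared in at least 90 of 100
null replicates) alongside full-power detection under the alternative.
When the gate passes, `chosen_r` is the smallest $r$ at which
significance *persists* ($p_r < \alpha$ at $r$ and $r+1$, or at
$r_{\max}$ alone). Persistence matters: genuine case-specific structure
stays significant as further shared directions are removed, whereas an
isolated noise dip at an intermediate $r$ does not. Without it, a single
spurious $p_r$ just under $\alpha$ early in the scan would truncate the
search short of the real signal and hand downstream PCA a residual still
dominated by unremoved shared variation. When the gate fails, the result
is the explicit `no-signal` sentinel rather than a fit.

A reformulation worth noting: the whole permutation loop runs in sample
space off a single pooled Gram matrix. Per-group centering of a relabeled
split is a rank-two correction to Gram blocks, the CCA needs only Gram
matrices, and the residual spectrum after removing $j$ directions is a
sequence of rank-one downdates. Each permutation therefore costs
$O((n_0+n_1)^3)$ regardless of $m$ — this is an exact rewrite, not an
approximation, and it is what makes hundred-permutation scans on
$m = 2000$ data run in seconds.

## Randomized PACA

When samples outnumber features the Gram matrices are rank-deficient in
the wrong way and sample-space CCA is unavailable. `fit_rpaca()` draws
`n_subsamples` random case/control subsets small enough for the core fit
(default size $\lfloor 0.8\,m \rfloor$ per group, the largest round
number that respects $m > n$ with margin), fits the shared basis on each,
and aggregates the per-draw estimates by averaging the projection
operators $U_0 U_0^\top$ and taking the top-$r$ eigenvectors of the
average. Averaging projectors rather than bases sidesteps the sign and
rotation ambiguity of individual draws (it is the chordal mean of the
subspaces); the eigenvalues of the mean projector, each in $[0,1]$,
report how consistently each consensus direction recurred and are stored
in place of canonical correlations. The consensus shared variation is
removed from the full case matrix, so every case sample gets a score.

## Stratification scores and component screening

`export_score()` freezes one component as `weights` (the pure loading
direction — *not* scaled by the singular value), the training centering
vector, and the training score mean/sd. `project_score()` applies
$s_j = w^\top (x_j - \mu)$ to a new cohort (features matched by id,
reordered internally, missing features a hard error) and z-scales by the
training record, so discovery and replication scores share a scale. Which
component to export is a screening decision, not an automatic one:
`phenotype_consistency()` correlates a score against an arbitrary
phenotype table within each of two cohorts (pairwise-complete, because
real phenotype panels have ragged missingness) and summarizes cross-cohort
replication as sign-agreement and the correlation of correlation vectors.
A component capturing technical or cohort-specific variance shows poor
consistency; a portable disease axis shows high consistency — that is the
criterion for promoting a component to "the" stratification score.

`filter_features_by_association()` is a deliberately plain pre-selection
helper — a per-feature Welch t-test between groups, keeping
$p \le$ threshold. It stands in for study-specific feature panels (e.g. a
covariate-adjusted, cell-type-aware EWAS) that are outside this package's
scope, and is labeled accordingly.

## The contrastive-PCA baseline

`fit_cpca()` eigendecomposes $C_X - \alpha C_Y$ (per-group covariances,
$1/(n-1)$; the $n$-dimensional dual is used when $m$ exceeds the total
sample count). It is the natural baseline: contrastive in spirit, but its
hyperparameter $\alpha$ must trade off background suppression against
signal retention, and no single value is right when background strength
varies — precisely what the benchmark in the acceptance suite probes by
drawing shared-component scales afresh per replicate. PACA has no such
knob; its analogue ($r$) is chosen by the calibrated permutation test.

## The synthetic generator

`simulate_case_control()` draws $W_0$ as an orthonormalized Gaussian
matrix, $W_1$ orthonormal within the complement of $W_0$ (optionally
tilted into the shared span by a prescribed cosine), factor rows i.i.d.
Gaussian, and isotropic noise. Component scales are **per-entry signal
standard deviations in units of** $\sigma$: a component of scale $s$
contributes $s^2\sigma^2$ to the variance of a typical matrix entry
(factor rows are drawn with SD $s\sigma\sqrt{m}$ against unit-norm
directions). This convention makes "a shared factor at $5\sigma$,
a case factor at $2\sigma$" mean what a practitioner expects — per-feature
signal-to-noise — and puts the default case signal far enough above the
spiked-model detection threshold for recovery to be a meaningful target.
The defaults encode the motivating regime: dominant shared variation
(scale 5), subtle case-specific variation (scale 2), unit noise.

What the generator does *not* emulate: bounded beta-value distributions,
probe-wise heteroscedasticity, batch block structure, or cell-type
mixture constraints. Passing recovery tests on this generator shows the
estimator does what the model promises; it does not certify performance
on any particular array dataset.

## Reference settings used by the tests and the acceptance script

All statistical checks run at one reference setting chosen once:
$m = 2000$ features, $n_1 = n_0 = 150$, $k_0 = 5$ shared components at
scale 5, $k_1 \in \{0, 1\}$ case components at scale 2, $\sigma = 1$;
permutation scan depth $r_{\max} = 10$ (twice the shared rank — deep
enough to absorb over-splitting, shallow enough to keep power),
$B = 100$ permutations, $\alpha = 0.05$. Replicate counts are 20 for
recovery/transfer medians and 100 for null calibration. Smaller unit
tests shrink $m$ and $n$ but keep the same scale conventions. Under these
settings the permutation scheme selects $r = 5$ essentially always, PACA
recovers the case factor with $|r| > 0.99$, and plain PCA on cases stays
near the chance level.

## Known limitations

- The orthogonality assumption is structural; strong $W_0$–$W_1$ overlap
  removes real signal and nothing in the fit can detect that from data
  alone.
- The permutation null assumes exchangeability of group labels given no
  case-specific structure; grossly unequal group-wise noise scales would
  violate it.
- `chosen_r` is a test-based point decision; components of shared
  variation *weaker* than the case signal are deliberately left in place
  (removing them costs more than it buys), so residual components beyond
  the first can still mix weak background.
- Serialization stores dense matrices as JSON; at EPIC-array scale
  ($m \sim 10^5$) fit files are tens of MB. Acceptable for a portable
  interchange format, not a database.
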