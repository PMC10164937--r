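---
title: "Discriminating insect populations from wing morphometrics and barcodes"
author: "wingmorph package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating insect populations from wing morphometrics and barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingmorph)
```

## The analysis this package implements

Populations of small Diptera (biting midges, mosquitoes, sand flies) are
routinely compared through the geometry of their wings, because wings are
flat, rigid and photograph well. Two complementary descriptions are used.
Where homologous anatomical points exist, each wing is reduced to a
configuration of *landmarks* (here 11 two-dimensional points). Where a
structure is a closed cell with few homologous points, its *outline* is
digitized instead and described by elliptic Fourier coefficients. On top of
the morphometric comparison, a mitochondrial Cox1 *barcode* distance
analysis asks whether the phenotypic groups also diverge genetically.

`wingmorph` implements the full chain for both descriptions:

* size statistics (centroid size; ANOVA, pairwise permutation tests with
  Bonferroni correction; leave-one-out maximum-likelihood size
  classification),
* shape statistics (generalized Procrustes superimposition, relative
  warps, canonical variate analysis, pairwise Mahalanobis distances with
  permutation significance, leave-one-out reclassification, allometry
  quantification, UPGMA dendrograms),
* machine-learning classification (PCA exploration, Kennard–Stone
  splitting, PLS-DA with balanced-error-rate tuning, per-class ROC/AUC),
* barcode analysis (Kimura 2-parameter distances with pairwise deletion,
  within/between-population summaries, barcode gap, neighbor-joining trees
  with bootstrap support),

together with a synthetic generator that emulates a three-population study
design so that every stage can be exercised and calibrated without
specimen data.

## Size

For landmarks the size variable is the centroid size
$\mathrm{CS} = \sqrt{\sum_{i=1}^{k} \lVert x_i - \bar{x} \rVert^2}$,
the standard isometric size estimator; it is measured in mm and is
invariant to translation and rotation and homogeneous of degree one in
scale. For outlines three size variables are computed — the square root of
the enclosed area, the perimeter, and the semi-major axis of the first
Fourier ellipse — and the semi-major axis plays the role of CS in all
downstream size statistics.

Group size differences are tested two ways: a one-way ANOVA across all
groups, and for each pair of groups a permutation test whose statistic is
the absolute difference of group means. P-values use the add-one
convention $p = (\#\{d^\ast \ge d_{obs}\} + 1)/(B + 1)$ with $B = 1000$
permutations by default, so the smallest attainable p-value is
$1/(B+1)$ and a report can state "p < 0.001" rather than zero.
Significance is flagged at the Bonferroni-adjusted level
$\alpha / \binom{g}{2}$. Each pair's permutation stream is seeded from
(seed, pair index), so results do not depend on the order in which pairs
are processed.

The "validated size classification" is leave-one-out: for every held-out
specimen, a Normal density is fitted to each group's remaining sizes
(per-group mean and SD — not pooled, since there is one variable and no
reason to force equal variances) and the specimen goes to the group with
the highest density. Leave-one-out is used for every validated
reclassification in the package: with ~20 specimens per group, k-fold
schemes waste data and resubstitution is optimistically biased (a property
the test suite checks on simulated data).

## Shape from landmarks

`gpaAlign()` performs generalized least-squares Procrustes
superimposition: every configuration is centred, scaled to unit centroid
size, and iteratively rotated to the evolving consensus by the optimal
least-squares rotation; the consensus is rescaled to unit size each
iteration purely as the scale gauge. Iteration stops when the consensus
RMS change falls below `tol = 1e-10` (cap 100 iterations; a non-converged
fit is returned with a warning and `converged = FALSE`). Two policies are
worth stating:

* **No reflections.** Rotation determinants are constrained to +1. All
  wings in a study are digitized on the same body side, so a mirror-image
  match indicates a data problem and should remain visible as a large
  residual rather than be silently absorbed.
* **No tangent-space projection.** Conspecific wing-shape variation is
  tiny (Procrustes distances ≪ 0.1), where the tangent approximation and
  the sphere are numerically indistinguishable; residual coordinates are
  used directly. The reported consensus is the arithmetic mean of the
  aligned shapes, so residuals sum to zero and their sum of squares is the
  minimized Procrustes sum of squares.

`relativeWarps()` is a plain principal-component decomposition of the
aligned coordinates with no bending-energy weighting ($\alpha = 0$). This
choice makes score space exactly isometric to Procrustes residual space
(the suite verifies pairwise distances agree to 1e-9), which is what the
downstream discriminant analysis needs; deformation-grid visualization is
out of scope.

## Shape from outlines

Contours are treated as polygons: `resampleContour()` forces
counter-clockwise orientation (positive shoelace area), and places `m`
points at equal arc-length spacing starting from the anchor landmark.
`efaDecompose()` computes the Kuhl–Giardina elliptic Fourier coefficients
— the exact Fourier integrals of the piecewise-linear closed curve, not a
DFT of the samples. Normalization ("NEF") removes translation (drop the DC
term), starting point and rotation by the classic first-harmonic
canonicalization, and size by the first ellipse's semi-major axis, leaving
$a_1 = 1$, $b_1 = c_1 = 0$. Two numerical details:

* The first-harmonic procedure has a genuine 180° ambiguity that flips
  the sign of even harmonics. Among the four candidate starting-point
  rotations the implementation keeps those whose $a_1$ is the semi-major
  axis and breaks the remaining tie by the sign of the first significant
  later coefficient — a deterministic choice, verified invariant under
  random similarity transforms and start-point shifts to 1e-6.
* Because coefficients are exact polygon integrals, truncating at the
  Nyquist count $H = m/2$ still leaves an $O(1/H^2)$ reconstruction tail
  (~1e-4 relative); reconstruction error is monotone in $H$, which is the
  property the tests assert.

The default harmonic count is $H = 7$: on smooth synthetic wing-cell
contours the cumulative harmonic power beyond the 7th is below 1%, and
$4H - 3 = 25$ shape variables keep the pooled covariance comfortably
non-singular at ~20 specimens per group (the three coefficients fixed by
normalization are excluded from the feature vector).

## Discriminant statistics

`cva()` whitens by the pooled within-group covariance and diagonalizes the
between-group covariance in the whitened space; scores therefore have
identity pooled within-group covariance and the per-factor contributions
(eigenvalue fractions over the $g-1$ retained factors) sum to 100%.
Pairwise Mahalanobis distances use each pair's pooled covariance with
significance from permuting the two groups' labels (add-one convention,
per-pair seeding as above). Both routines are invariant under invertible
affine transformations of the feature space, which the suite checks with
random well-conditioned maps; if the pooled covariance is singular (p
approaching n − g), features are first reduced to principal components
covering 99% of variance — the smallest intervention that restores a
well-posed metric, logged via a message.

Allometry is quantified, not removed: `allometryR2()` regresses the first
discriminant factor (or any shape score) on CS and reports $r^2$. Removal
by residualization is deliberately left to the caller, since a large
size-shape correlation is itself a finding about the data.

The population-level dendrogram is UPGMA (average linkage) on the
Mahalanobis matrix, computed via `stats::hclust`; merge heights are
reported as half the linkage distance so that an ultrametric input is
reproduced exactly by the tree's cophenetic distances (verified in tests).

## PLS-DA

`fitPLSDA()` regresses standardized features on centred one-hot class
indicators with NIPALS-style components and classifies by the nearest
class centroid in component space. The number of components is tuned by
stratified cross-validated balanced error rate (BER, the mean over classes
of class-wise error — appropriate with unequal group sizes); the chosen
count is the smallest whose BER is within one standard error of the
minimum, a standard parsimony rule when the curve is flat past its
minimum. Folds are stratified (5 by default; with ~20 per group,
leave-one-out makes the tuning curve needlessly noisy) and the fold
assignment is seeded and stored. `kennardStoneSplit()` provides the
deterministic max-min train/test split; `aucPerClass()` computes
one-vs-rest AUC through the rank (Mann–Whitney) identity with a one-sided
Wilcoxon rank-sum p-value. AUC can be computed on resubstitution or
held-out predictions; reports should state which, and the package's own
calibration checks use held-out scores.

## Barcodes

`k2pDistance()` implements the Kimura 2-parameter estimator
$d = -\tfrac12\ln(1 - 2P - Q) - \tfrac14\ln(1 - 2Q)$ with $P$ and $Q$ the
transition and transversion proportions over comparable sites. Sites with
a gap or N in either sequence are excluded per pair (pairwise deletion,
the common default of distance-analysis software); ambiguity codes other
than N are treated as N. Non-positive logarithm arguments mean saturation
and are flagged rather than silently truncated. Standard errors of
within/between-population mean distances come from a seeded 500-replicate
bootstrap over alignment sites.

Two "barcode gap" statistics are reported, because the literature uses the
term loosely: the global gap (smallest between-population mean minus
largest within-population mean) and a per-population gap (smallest between
mean involving that population minus its own within mean). The second is
the relevant quantity when asking whether one population is set off from
the rest.

`njTree()` is a direct Saitou–Nei neighbor-joining implementation
(Q-criterion, closed-form three-taxon termination). It recovers additive
matrices exactly — topology and branch lengths — which is its defining
test. Negative branch lengths, which NJ can produce on noisy
non-additive input, are clamped to zero with the deficit moved to the
adjacent branch, the usual display convention. `bootstrapSupport()`
resamples alignment columns, rebuilds K2P + NJ per replicate, and scores
each original bipartition by its replicate frequency; replicates with
saturated distances are skipped and counted, with a warning beyond 5%.

## The synthetic generator

`simulateLandmarkDataset()` emulates a three-population wing study: group
sizes 20/22/23; 11 landmarks; centroid size drawn per group from Normal
distributions with means 1.363, 1.887 and 1.6 mm and SDs 0.074, 0.096 and
0.08 mm (population 2 the largest, population 1 the smallest — the third
population's moments are set midway, as only the extremes are typically
reported). Each wing is the group mean shape, plus a linear allometric
displacement along a fixed direction proportional to the wing's CS
deviation from its group mean, plus isotropic i.i.d. Gaussian landmark
noise in shape units, then scaled to its drawn CS and randomly rotated and
translated. Group mean shapes are the base template plus fixed
displacement fields supported on the posterior/apical landmarks, with
magnitudes (0, 0.05, 0.02) so that populations 1 and 3 are shape-similar
and population 2 divergent — making the expected dendrogram topology a
recoverable truth. Landmark noise defaults to 0.01 shape units (~1% of
size, a typical digitization error scale; no empirical anchor exists, so
it is a free parameter). The allometric slope default 0.125 /mm puts about
half the leading shape-axis variance under size control within a group;
setting the slope to `noiseSd/csSd` makes the designed shape–size shared
variance exactly 0.5, which is how the parameter-recovery checks are
constructed (with a single population, the first relative warp serves as
the shape axis).

`simulateOutlineDataset()` builds per-group template cells as radially
modulated ellipses (aspect ratios 0.55/0.72/0.58; population 2 divergent),
adds low-frequency Gaussian radial noise, scales so the first-harmonic
semi-major axis matches the drawn size (defaults 0.161/0.227/0.19 mm),
and applies a random rotation and translation. Contours whose perturbed
radius would collapse are redrawn, failing after 20 attempts.

`simulateK2PSequences()` evolves 401-bp sequences on a star phylogeny
under the K2P substitution model with a configurable
transition/transversion ratio (default 2): root-to-population branches are
solved from the requested between-population distances (least squares for
more than three populations) and tip branches carry half the
within-population divergence, so the estimator applied to the output
recovers the configured values in expectation — distances are additive in
expectation along branches.

What the generator deliberately does **not** emulate: digitization error
correlated along veins, measurement error in outline tracing, sexual
dimorphism, left/right asymmetry, rate heterogeneity across sites, indels,
or coalescent population structure. Green tests therefore certify the
statistical machinery under its stated assumptions, not the biology of any
particular dataset.

## Problem sizes used by the checks

The packaged checks run at deliberately modest sizes chosen to estimate
each quantity adequately: 2000 replicates for the permutation-test
type-I error (nominal 0.05; with B permutations and the add-one rule the
attainable rate is slightly below nominal, e.g. 0.049 at B = 999), 40–60
study-sized replicates for the all-pairs-significant and dendrogram
topology rates, 8 replicates of n = 300 for allometry recovery, and 10–20
replicates of 30-sequence alignments for the molecular summaries. The
acceptance script (`scripts/acceptance.R`) recomputes all of these from a
single command-line seed.

## Known limitations

* Relative warps are unweighted PCA; thin-plate-spline bending-energy
  decompositions and deformation grids are not provided.
* Outline analysis assumes simple (non-self-intersecting) closed
  contours; self-intersection only triggers a warning in the area
  computation.
* The permutation scheme for Mahalanobis significance permutes the two
  groups' labels and recomputes the distance; other schemes (e.g.
  residual permutation) exist and can give different p-values at small n.
* NJ is the only tree method for barcodes; likelihood and Bayesian
  phylogenetics are out of scope, as is GenBank access — sequences are
  read from local FASTA.
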