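---
title: "Models and methods behind seqrep"
author: "seqrep authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind seqrep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqrep)
```

# The scientific question

When people practise a fast sequence of finger presses for several days,
what changes in the cortical activity that produces it?  Average BOLD
activation is ambiguous: training can recruit more neurons (activity up)
or make the representation more efficient (activity down), and both can
happen at once.  A more direct probe is *pattern distinctness*: if
training builds neuronal circuits specialised for particular sequences,
then each trained sequence should evoke its own spatial activity pattern,
and a classifier should tell trained sequences apart more reliably than
untrained ones — with or without any change in mean activation.

`seqrep` implements that analysis chain end to end, together with a
generative simulation of the experiment so that every stage can be tested
against known ground truth.

# The task model

Sequences are permutations of the five digits (1 = thumb ... 5 = little
finger).  Two constraints define the valid set: each finger is used
exactly once, and no ascending or descending run of more than three
neighbouring digits may occur (so `1-2-3` is allowed, `1-2-3-4` is not).
Exhaustive enumeration shows 114 of the 120 permutations are valid; pools
are drawn uniformly from this set and partitioned at random into trained
and untrained groups of four.

A key press is recognised when one finger's force reaches 2.5 N while all
other fingers are below 2.2 N, and a finger cannot re-trigger until its
force drops below 2.2 N again.  Movement time (MT) is defined here as the
interval from the first to the fifth press *onset*.  The onset endpoint
was a genuinely open choice (onset-to-release is also defensible); we use
onsets because they are invariant to release dynamics and to the force
level at which a key is considered released.  Force traces are sampled at
200 Hz by default, resolving onsets to 5 ms.

Sequence-specific learning is tested by regressing each subject's
post-test trained-minus-untrained MT difference onto the pre-test
difference and testing the intercept against zero (`sequenceSpecificTest`);
a non-zero intercept is an advantage not explained by pre-existing
differences between the sequence sets.

# The generative pattern model

All simulations draw from one model of the activity pattern
$b_{ir}$ of condition $i$ in run $r$ across $V$ voxels:

$$ b_{ir} = c + s_i + u_r + \varepsilon_{ir} $$

* $c$ — a *common* pattern shared by all conditions, i.i.d. Gaussian per
  voxel with variance $v_{common}$;
* $s_i$ — a *sequence-specific* pattern confined to a random
  $d$-dimensional subspace ($d \le K-1$ for $K$ conditions);
* $u_r$ — a *run effect* drawn once per run and shared by all trials in
  that run;
* $\varepsilon$ — independent trial noise with variance $v_{trial}$.

Components are spatially unstructured (i.i.d. across voxels).  That is a
deliberate baseline: it matches the "spatially random patterns"
assumption under which the dimensionality simulations are interpretable,
and it means passing tests say nothing about spatially correlated noise,
physiological artifacts or motion — real-data properties the generator
does not emulate.

The geometry of the specific patterns is controlled explicitly, because
it is the quantity the dimensionality analysis infers:

* `random` — independent latent coordinates per condition: unique but
  unstructured patterns;
* `evenly_spaced` — a regular simplex (all pairwise distances equal), the
  idealisation of four fully distinct patterns;
* `scaled_1d` — four scalar multiples of one pattern, the idealisation of
  conditions that differ only in intensity (e.g. difficulty or force).

Latent coordinates are scaled so the voxel-wise variance of the specific
component, averaged over conditions, equals $v_{specific}$ exactly; the
subspace basis is orthonormal, which makes the simplex and rank
invariants exact rather than asymptotic.

Scaling note: the decomposition analysis of real data attributes about
99% of pattern variance to the common component and under 1% to the
specific component, so the simulation defaults use $v_{common} = 100$
against specific variances of order 1 — classifiers must operate in a
regime where the discriminative signal is a sliver of total variance.

# Timing and the GLM

The simulated session mirrors the scanning protocol: 8 runs of 110
volumes at TR 2.72 s; per run, 16 trials of 13.5 s (4 per condition) and
4 rest phases of 13.5 s, randomly ordered on a 13.5 s slot grid.  (The
protocol's TR of 2.72 s and its 13.5 s trial grid are mutually
inconsistent by 2%; we keep both as printed and do not resolve the
discrepancy.)  Each trial contributes its condition's pattern times a
13.5 s boxcar convolved with the canonical double-gamma HRF (response
peak ~5 s, undershoot ~15 s, ratio 1/6, truncated at 32 s).  The
convolution is evaluated in closed form — the boxcar response is a
difference of gamma CDFs — rather than numerically, which is exact and
removes the dominant cost of the simulation.

Estimation follows the standard unsmoothed single-subject pipeline:

* high-pass filtering at 1/128 Hz by residualisation against a
  discrete-cosine basis, applied identically to data and design so that
  filtering commutes with fitting (no autocorrelation model is used);
* one regressor per condition per run plus a per-run intercept;
* per-voxel least squares, optionally robust.

The robust option shares one weight per volume across voxels: the weight
is a Tukey bisquare of the volume's cross-voxel mean squared residual,
standardised as its excess ratio over the median volume.  The bisquare
window is wide (zero weight only beyond ~40 times the median) because a
gross artifact contaminates the initial OLS fit and inflates the
residuals of perfectly good task volumes severalfold; a conventional
narrow window would discard exactly the volumes that carry the task
signal.  Two reweighting iterations are used.  On simulated data with one
large artifact volume this recovers estimates close to those obtained
with oracle weights, while leaving clean data essentially untouched.

A finite-impulse-response variant (`buildFirDesign`) models 9 one-TR bins
per condition and run.  An SVD of the bin-by-(observation x voxel) matrix
(per-bin mean removed) yields temporal components of the trial response;
the first component carries the canonical response shape and its
per-voxel weights can replace canonical betas as classifier input.

# Classification

The classifier is Gaussian LDA with a shared covariance: class means over
training runs, pooled within-class covariance of the residuals
(denominator $n - K$, the unbiased within-class estimator), regularised
as $\Sigma_{reg} = \Sigma + 0.01 \cdot \overline{\mathrm{diag}\,\Sigma}
\cdot I$.  Test patterns go to the class with maximal likelihood under
equal priors (the design is balanced); exact ties — measure zero but
possible — break deterministically to the lowest class index.
Cross-validation is leave-one-run-out, giving $K \times R = 32$ test
classifications in the standard design.

Accuracies are z-transformed with the normal approximation to the
binomial, $z = (a - 0.25)/\sqrt{0.25 \cdot 0.75 / n}$ with $n = 32$: the
total number of cross-validated classifications.  That choice of $n$
reproduces the standard within-subject threshold pairing — $z = 1.64$
corresponds to 37.5% accuracy (truncated to one decimal).

The same classifier applied to z-standardised behavioural features (mean
MT, mean peak force, error rate per condition and run, alone or in any of
the seven combinations) serves as a control: if behaviour alone
classifies sequences equally well in both sessions, pattern-based
differences are not a behavioural artifact.

# Dimensionality analysis

For four conditions the grand-mean-centred matrix of class means has rank
at most three, so at most three pattern components can carry
discriminative signal.  The reduced-dimension classifier projects, per
cross-validation fold, the training and test patterns onto the top-$d$
right singular vectors of the centred training class means and runs the
same regularised LDA in that subspace.  Ordering components by singular
value is our reading of "most informative": the singular value measures
the between-class signal a component carries.

The signatures are diagnostic of geometry: for `scaled_1d` truth, one
component suffices and extra components only add noise
($a(1) \gtrsim a(3)$); for `evenly_spaced` truth, accuracy rises with
every added component.  Observed curves are interpreted against simulated
reference curves (`simulateAccuracyCurves`) matched to the data: a
bisection on a scalar multiplying the specific-pattern norms calibrates
the simulation until the mean accuracy of the `matchDim`-component
classifier equals the observed accuracy within 0.005.  Simulation draws
are reused across bisection steps (common random numbers), which makes
the calibrated quantity deterministic and effectively monotone in the
signal scale; up to 40 iterations are allowed.  Whether matching is done
at $d = 1$ or $d = 3$ is left as a parameter: published descriptions of
this procedure state both conventions, so the package fixes neither.

# Variance-component decomposition

`decomposePatterns` estimates the voxel-wise variance of each model
component by the method of moments on raw cross-products.  With
$m(i,r;j,r')$ the mean over voxels of $b_{ir} b_{jr'}$:

| pair class                      | expectation                           |
|---------------------------------|---------------------------------------|
| $i \ne j,\; r \ne r'$           | $v_{common}$                          |
| $i = j,\; r \ne r'$             | $v_{common} + v_{specific}$           |
| $i \ne j,\; r = r'$             | $v_{common} + v_{run}$                |
| $i = j,\; r = r'$               | $v_{common} + v_{specific} + v_{run} + v_{trial}$ |

and the four averages solve linearly for the variances.  Raw products are
used deliberately: the common component is itself a parameter of
interest, and removing the mean pattern would absorb it.  Negative
solutions (possible at low signal-to-noise) are clipped to zero with a
warning, and the unclipped values are kept in the returned object.  This
moment estimator is a concrete, testable stand-in for likelihood-based
pattern-component estimators; it is unbiased in expectation but a single
realisation carries fluctuation from the random geometry of the specific
patterns (their mutual inner products), so recovery tests average over
replicate datasets.  The headline ratio is $v_{specific}/v_{trial}$,
which tracks classification accuracy monotonically.  The decomposition is
run separately per condition set (trained / untrained).

# Searchlight, ROIs and group inference

Cortical surface geometry is abstracted to coordinates plus per-voxel
area weights (`VoxelGeometry`); the default is a flat sheet with 2.3 mm
spacing, and mesh-derived node coordinates plug into the same interface.
A searchlight neighbourhood is the $p = 160$ nearest voxels of each
center (ties by index), matching the fixed-voxel-count searchlight whose
radius on a uniform sheet is close to the analytic
$\sqrt{160/\pi}$-cell disc radius.  Cross-validated accuracy is assigned
to the center, yielding an accuracy map; the area of cortex above an
accuracy criterion is the sum of area weights over suprathreshold
centers.

ROI accuracy uses random-subspace averaging: repeated draws of 160 voxels
from the (up to 800 most activated) ROI voxels, averaging accuracy over
5000 draws by default.  Selecting voxels by mean activation does not bias
pattern analyses under the null because the classifier is independent of
the mean activity level.

Group-level inference is a one-sample (or paired) t test per voxel across
subject maps with cluster-based family-wise error control.  The
cluster-forming threshold is $t$ at one-sided $p$ (default 0.002; with 15
degrees of freedom, $t > 3.39$).  Family-wise error over clusters is
controlled by a sign-flip permutation null of the maximum suprathreshold
cluster area — chosen over Gaussian-field theory because it is
assumption-free and testable at desk scale; its error control is verified
empirically over hundreds of null simulations in the test suite.

# The end-to-end experiment

`runExperiment` wires everything together for a synthetic cohort
(default N = 16, mirroring a random-effects group analysis): per subject
and condition set, simulate time series, estimate betas, classify (full
and reduced-dimension), decompose, optionally searchlight; then contrast
the condition sets at the group level.  The trained set defaults to
evenly spaced geometry with higher specific variance and the untrained
set to random geometry with lower specific variance — the representational
change that training is hypothesised to produce — so the default
experiment exhibits the headline effects: higher accuracy for trained
sequences and a larger accuracy gain from added pattern components.
Everything is deterministic given the master seed; per-subject seeds are
derived from it and all tables are written as plain TSV so results are
diffable.

# Problem sizes and numerical choices

Simulation-backed checks in the test suite use deliberately modest sizes
chosen to make Monte-Carlo error small relative to the tested effect:
null calibration uses 200 datasets of 160 voxels (the searchlight size);
variance recovery uses 100 replicates of 10^4 voxels; dimensionality
signatures use 25--30 replicates of 60 voxels; family-wise-error
calibration uses 200 null group datasets with 150 permutations each.
Tolerances are stated in the tests as multiples of the relevant
Monte-Carlo standard error.  Degenerate inputs are errors, not silent
results: an exactly zero within-class covariance cannot be regularised, a
zero-norm average time course cannot normalise a set, and a zero
trial-noise variance has no defined noise ratio.

# Known limitations

* The generator's noise is white in space and time; real BOLD noise is
  neither, and absolute accuracies here do not transfer to real data.
* The variance decomposition estimates scalar variances only, not the
  full second-moment structure between specific patterns.
* The surface abstraction has no folding, no node-to-voxel mapping, and
  no atlas-based ROI definitions.
* Only linear classifiers are provided; the scientific claims concern
  linear decodability.
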