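---
title: "Methods: window-contrast phMRI activation and resting-state degree analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: window-contrast phMRI activation and resting-state degree analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `phmri`, the choices
that were genuinely open when the package was designed, and what the
synthetic-data generator does and does not emulate. Everything quantitative
stated here is computed by the test suite or the acceptance script; nothing
is quoted from elsewhere.

## The activation model

A phMRI session is a single uninterrupted 4D acquisition: a pre-injection
baseline followed by a long post-injection period. The analysis is a
*window contrast*, not an event-related GLM: the drug response is slow,
sustained and has no repeatable event structure, so the informative
comparison is between a late response window and the baseline window.

Per voxel, with window means $\bar y_B$ and $\bar y_R$ over the unflagged
acquisitions of the baseline and response windows:

* percent change $\Delta = 100\,(\bar y_R - \bar y_B)/\bar y_B$ (undefined,
  and marked `NA`, if $\bar y_B \le 0$);
* a two-tailed Welch two-sample t-test between the two windows' acquisition
  values. Welch rather than pooled variance because the post-drug state has
  no reason to share the baseline's variance.

The mass-univariate problem (thousands of voxels per subject) is controlled
with a rank-based step-up filter: sort the $V$ p-values ascending and keep
all ranks up to the largest $i$ with
$P_{(i)} \le i\,q / (V\,c(V))$, using $q = 0.2$ and $c(V) = 1$. The filter
is stated as an inequality over ranks; we read it as the standard *step-up*
rule (largest qualifying rank wins), which the test suite verifies against
an exhaustive brute-force evaluation over all ranks on 1,000 random
p-vectors. A voxel must additionally pass a magnitude gate
$|\Delta| \ge 1\%$. Two readings of the "1%" figure are defensible — a
minimum effect size, or a $p \le 0.01$ alpha gate on the t-test — so the
magnitude reading is the default and the alpha reading is available via
`significance_mask(gate = "alpha")`. The filter runs over the whole
in-brain voxel population per subject by default; `per_region = TRUE`
applies it within each atlas region instead ($V$ is whichever population
the filter is run over).

Significant voxels keep their percent-change values, all others are set to
zero, and group composites average these zeroed maps in atlas space: each
composite voxel is inverse-mapped through the subject's affine transform,
interpolated trilinearly, and averaged over subjects. Out-of-field
contributions are treated as *missing*, not zero — counting them as zero
would dilute composite edges for subjects whose field of view ends there.

### Dose-response statistics

Volume of activation (VOA: significant voxels per region, by sign) is
compared across dose groups with a Kruskal–Wallis test (tie-corrected H).
For small designs the p-value is the exact permutation probability by full
enumeration of group assignments; at the usual study scale (27 subjects in
four groups) the chi-square approximation is used and flagged
`approximate`. Post-hoc contrasts use the Wilcoxon rank-sum test, exact by
enumeration of all $\binom{n_a+n_b}{n_a}$ assignments of the pooled
midranks whenever $\min(n_a, n_b) \le 10$ — which covers the 6-vs-7 design,
where complete separation gives the exact two-sided $p = 2/1716$. The
two-sided p is twice the smaller tail, capped at 1; midranks handle ties in
both the exact and the normal-approximation paths.

The effect size reported alongside is $\omega^2 = (z^2 - 1)/N$ computed
from the normal-scale rank-sum statistic $z$ (with continuity correction),
a rank-biserial-consistent variance-explained estimate. The raw $z$ is also
reported, because $\omega^2$ conventions differ between toolchains.

The same step-up rule applied across the per-region post-hoc p-values
yields the "FDR boundary": the largest p declared significant
(`region_fdr_cutoff()`, default $q = 0.05$).

Time courses (region-averaged percent change per acquisition) are compared
between two groups with a classical two-way repeated-measures ANOVA
(group between subjects, acquisition within, `aov` with an
`Error(subject)` stratum) plus per-timepoint contrasts at the Šidák level
$\alpha_m = 1 - (1-\alpha)^{1/m}$; the comparison family `m` defaults to
all timepoints supplied, since the analysis has no principled subfamily.

## The connectivity model

Resting scans are preprocessed in this order: motion-outlier flagging
(robust z of the global in-mask mean), optional slice-timing interpolation
(off by default — the generator does not simulate slice offsets), band-pass
0.01–0.1 Hz, detrending, Gaussian smoothing (FWHM 0.8 mm), and nuisance
regression on [intercept, six motion parameters, one indicator per flagged
outlier, mean white matter, mean CSF]. Spike *regression* rather than
deletion keeps the time axis intact for filtering. The band-pass is a
zero-phase forward–backward Butterworth of order 4: no filter family is
canonical for this step, and zero phase preserves timing.

Node series are region averages of the residual images; edges are all
pairwise Pearson correlations, Fisher-Z transformed. Group edges are
one-sample t-tests of the subject z-values against zero, mapped to a signed
standard-normal scale by $Z = \Phi^{-1}(F_t(t))$ — exact under normality of
the subject z-values, so the null rate of $|Z| \ge 2.3$ is
$2\Phi(-2.3) \approx 2.1\%$ regardless of group size (verified by
simulation in the test suite). A zero-variance (constant-across-
subjects) edge is guarded with a small $\varepsilon$ in the denominator so
it maps to a large finite Z rather than `NaN`.

The thresholded network is the binary undirected graph on
$|Z| \ge 2.3$; degree centrality is the adjacency row sum. Thresholding
*before* degree analysis is the default (`threshold_before_degree`),
because degrees of an unthresholded weighted graph are not what a degree
count means; the cutoff is configurable for the alternative reading that
2.3 was only a display threshold.

Two interpretation questions had no unique answer and are resolved as
explicit design choices:

* **"K-nearest-neighbors clustering"** of a connectivity matrix is
  ambiguous (k-NN is a classifier). We build a k-nearest-neighbour graph on
  the rows of the Z matrix under correlation distance and return its
  connected components (`k = 5` default, deterministic); a spectral variant
  on the same graph is behind `method = "spectral"`.
* **Paired degree comparisons between two animal groups** only make sense
  paired *by region*: each region contributes its degree under condition A
  and condition B. `compare_degrees()` does exactly that, gates on
  Shapiro–Wilk normality of the paired differences at $\alpha = 0.05$
  (paired t if tenable, Wilcoxon signed-rank otherwise), and skips
  subregions with fewer than 3 member regions.

The node set is *whatever atlas regions have voxel support* — empty regions
are dropped with a warning and recorded — rather than any fixed count;
published parcellations of this kind variously yield 166, 171 or 173 nodes
depending on which regions survive masking, and hard-coding any of them
would be wrong for other atlases.

## What the generator emulates — and what it does not

`simulate_phmri_subject()` produces, per voxel,
$y_t = L\,(1 + (\text{drift}_t + a_v r_t + \eta_{vt} + s_t)/100)$ with
baseline level $L = 1000$ arbitrary units (multiplicative, so percent
change is scale-invariant by construction), a linear ramp $r_t$ from the
injection acquisition (default 50) to a plateau over 100 acquisitions,
stationary AR(1) noise $\eta$ (marginal SD 1%, lag-1 coefficient 0.3), and
global intensity spikes $s_t$ at flagged acquisitions
(probability 0.02 per acquisition). Defaults mirror a 35-minute,
350-acquisition session with analysis windows 5–45 and 300–345, a four-arm
design (6/7/7/7 subjects), and the inverted-U amplitude map
0 / 0.5 / 2 / 0.5 percent — the middle dose strongest, and the effect scale
a few percent, as typical for awake-rodent drug challenges. The ramp
parameters are free choices: no pharmacokinetic time constant is available
for this compound, so the only constraint honoured is that the response
has plateaued well before the response window begins. The drift slope
defaults to 0: the windows-contrast analysis is run on raw (undetrended)
scans, and a nonzero default drift would bias every null contrast by a
fixed amount — drift is available as a parameter when the detrending step
itself is under study. Noise SD 0 is allowed for noise-free exactness
tests.

The resting generator draws node courses from a specified covariance
(eigen square root, so PSD matrices with zero eigenvalues are legal) and
gives every voxel its region's course plus independent observation noise
(SD 0.3 against unit node variance). The hypoconnectivity study used in the
test suite plants four 11-region modules at within-module correlation
0.45 (between 0) for the vehicle condition and scales all off-diagonals by
0.3 for the drug condition. The 0.45 figure comes from a power
consideration, fixed before the tests were run: after band-pass filtering
to 0.01–0.1 Hz at TR 1 s, 150 timepoints carry roughly $2\,BW\,T \approx
27$ effective degrees of freedom, so the subject-to-subject SD of a null
edge z is about $1/\sqrt{24} \approx 0.2$ and a 7-subject one-group t
crosses $|Z| = 2.3$ near $\bar z \approx 0.09 \times \sqrt{27/147}$-scaled
boundaries — vehicle edges at $z = \operatorname{atanh}(0.45) = 0.48$ sit
far above the detection boundary and drug edges at
$\operatorname{atanh}(0.135) = 0.14$ well below it, so the planted
direction is recoverable without being trivial.

Not emulated: pulse sequences and k-space physics, physiological
(cardiac/respiratory) noise structure, spatially correlated noise,
deformable anatomy, slice-timing offsets, and anatomically shaped regions
(the atlas is a Voronoi partition of an ellipsoid — region *geometry* is
irrelevant to every statistic tested, only membership matters). Passing
tests therefore demonstrate the statistical machinery on data satisfying
the model's assumptions; they do not certify performance under structured
physiological confounds.

## Numerical choices

* **Windows** are 1-based inclusive acquisition ranges; 5–45 and 300–345
  contain 41 and 46 acquisitions.
* **Degenerate voxels**: zero variance in both windows gives $p = 1$ when
  the means agree (nothing to detect) and 0 otherwise; a non-positive
  baseline mean marks the voxel invalid (`NA`), excluded from $V$.
* **Smoothing** is separable Gaussian with
  $\sigma = \text{FWHM}/(2\sqrt{2\ln 2})$ per axis in voxel units, kernel
  truncated at $3\sigma$ and renormalised at boundaries, so constants are
  preserved exactly; FWHM 0 is the identity.
* **Registration** maximises normalized correlation over the 9-parameter
  family (translation, rotation, per-axis log-scale; no shear) with a
  coarse-to-fine schedule and staged parameter blocks (translation →
  translation+scale → all nine) under Nelder–Mead. The final level runs on
  the *unsmoothed* images: smoothing does not commute with scaling, and a
  smoothed-only schedule leaves a small scale bias. Convergence below a
  normalized correlation of 0.2 is an error, not a silent bad fit.
* **Trilinear resampling** maps target voxels through the inverse
  transform; out-of-field samples are `NA` (missing), never zero. Exactness
  holds for identity transforms, grid hits and affine-in-space images, and
  is tested as such.
* **Ties**: midranks throughout; the exact enumeration paths inherit tie
  handling from the midranks. Region rankings order by p-value with region
  id as the stable tie-break.
* **Determinism**: all generators run under a private RNG stream seeded by
  the caller (`.Random.seed` is saved and restored), so identical seeds
  give bit-identical data and the caller's RNG state is untouched.

## Problem sizes used by the tests

The suite runs the null false-positive study at 200 subjects of ~5,000
in-brain voxels and 350 acquisitions; the dose-response study at the full
6/7/7/7 design on a 20-region atlas of ~2,600 voxels; the null edge-rate
check at 11,175 edges (150 nodes, 10 subjects); and the hypoconnectivity
study at 48 regions, 7 subjects per condition, through the full voxel-level
preprocessing chain. These sizes keep each property at full statistical
strength (the quantities under test are rates and medians, not image
resolution) while the whole suite completes in minutes.

## Known limitations

* Affine-only registration; deformable anatomy is out of scope.
* The AR(1) noise model means the Welch test's independence assumption is
  mildly violated within windows — deliberately so, since the windows are
  far apart; the false-positive control is verified on exactly this
  noise.
* The exact Kruskal–Wallis path is enumeration-bound; large unbalanced
  designs fall back to the chi-square approximation (flagged in output).
* Degree centrality is the only graph metric; no betweenness, modularity
  optimisation or small-world statistics.
* The repeated-measures ANOVA is the classical sphericity-assuming
  decomposition; with a 350-point time factor, per-timepoint Šidák
  contrasts are the interpretable output and the omnibus interaction
  should be read with that caveat.
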