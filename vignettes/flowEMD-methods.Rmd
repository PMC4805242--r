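---
title: "Comparing cytometry samples with the Earth Mover's Distance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing cytometry samples with the Earth Mover's Distance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(flowEMD)
```

## The problem

Flow cytometry measures a handful of fluorescence intensities on tens of
thousands of cells per sample. Many biological questions reduce to "how
different are two samples?" — for instance, how much did a basophil
population shift its CD203c/CD63 expression after allergen stimulation,
relative to the unstimulated control? Statistics built on p-values (the
probability-binning statistic, chi-square tests) answer a different
question: *is there any difference at all?* At cytometry sample sizes even
trivial shifts are overwhelmingly "significant", and once two populations
barely overlap such statistics saturate — moving a population twice as far
changes them hardly at all. A *metric* on distributions is needed: a score
that grows proportionally with the magnitude of the change and stays small
for small perturbations such as instrument drift.

The Earth Mover's Distance (EMD) is that metric. Viewing each sample as a
pile of unit mass spread over marker space, `emd(P, Q)` is the minimum total
work — mass times distance — needed to reshape `P` into `Q`. On unit-mass
distributions it equals the Mallows / 1-Wasserstein distance and satisfies
the metric axioms: identity, symmetry, and the triangle inequality.

## Signatures: probability binning

Comparing raw event clouds directly is wasteful; `flowEMD` first summarizes
each sample as a *signature* — a set of bins, each carrying the mean
position of its events (centroid \(m_j\)) and the fraction of events it
holds (weight \(w_{m_j}\), summing to 1). Bins come from recursive median
splits: at each node, the channel with the largest sample variance is
selected (ties broken toward the lower channel index) and the events are
split in half at that channel's median. Splitting continues while both
children would keep at least `stop_threshold` events; the default
`stop_threshold = "auto"` uses \(2\ln N\), so a 20 000-event sample gets
bins of roughly 20–40 events each. The result is a set of hyper-rectangular
bins that are small where the data are dense and large where they are
sparse.

Two conventions make binning deterministic and reproducible on new data:

* **Lower-median splits.** With \(n\) events at a node, the first
  \(\lceil n/2 \rceil\) events in sorted order go left and the stored split
  value is the lower median (the \(\lceil n/2\rceil\)-th order statistic).
  When a stored schema is applied to a *different* sample
  (`apply_schema()`), events route by "value \(\le\) split goes left".
  For continuous (tie-free) data, re-applying a schema to its own building
  sample reproduces the build partition exactly; with ties, events equal to
  the split value all route left, which can move occupancy by the number of
  tied events.
* **Variance ties** pick the lowest channel index; with all channels at
  zero variance the node becomes a leaf (a root-level zero-variance sample
  yields a single-bin schema and a warning).

Signature granularity is deliberately not critical: the package's test
suite checks that EMD values move by only a few percent as the threshold
ranges from \(\ln N\) to \(4\ln N\).

## Computing EMD

Given signatures \(P = \{(p_i, w_{p_i})\}_{i=1}^m\) and
\(Q = \{(q_j, w_{q_j})\}_{j=1}^n\) with unit total mass, and the ground
distance matrix \(D = [d_{ij}]\) of Euclidean distances between centroids,
the package solves the transportation linear program: find flows
\(f_{ij} \ge 0\) minimizing \(\sum_{ij} d_{ij} f_{ij}\) subject to row sums
\(w_{p_i}\), column sums \(w_{q_j}\), and grand total 1. The EMD is the
optimal cost divided by the total flow (equal to the cost at unit mass).

The solver (`src/transport_simplex.cpp`) is a transportation simplex:

* **Initialization** by the matrix-minimum rule — cells are allocated in
  increasing cost order (provably cycle-free), then the basis is completed
  to a spanning tree with zero-flow cells, again preferring cheap cells.
  This starts close to optimal and keeps pivot counts near-linear in
  \(m + n\).
* **Pricing** by the MODI (u–v) duals recomputed by breadth-first search
  over the basis tree; the entering cell has the most negative reduced
  cost. After a run of more than \(m + n\) consecutive degenerate pivots
  the entering rule switches to Bland's (first negative), which guards
  against cycling.
* **Termination** when no reduced cost is below `-1e-10`; the returned
  objective is contractually within `1e-8` of the LP optimum, and the test
  suite verifies this against an independent dense two-phase simplex
  written separately in R, plus the closed-form 1D distance below.

Ground distances are computed per dimension (`outer` differences squared
and summed) rather than via the expanded-square identity, so coincident
centroids get a ground distance of exactly 0 and `emd(P, P)` is exactly 0.

Zero-weight bins are dropped before solving. Signatures whose weights do
not sum to 1 (within `1e-9`) are rejected unless `normalize = TRUE` is
passed — silent renormalization would hide upstream mistakes.

`emd_1d_exact()` provides the unbinned gold standard in one dimension: the
integral of the absolute difference of the two empirical CDFs, which equals
the mean absolute difference of matched order statistics for equal sample
sizes. Binned EMD on 10 000-event 1D samples agrees with it to well under a
percent at default binning.

## Baseline comparison measures

The classical alternatives are implemented for side-by-side comparisons,
each binned with a schema built from the control sample (or a supplied
schema):

* **Chi-square (`chi_square`)** — the symmetric form
  \(\sum_i (c_i - t_i)^2 / (c_i + t_i)\) over bin fractions, omitting bins
  empty in both samples; bounded above by 2.
* **Probability-binning statistic (`pb_statistic`)** — the same chi-square
  centered and scaled by its approximate null moments,
  \(\mu_0 = (B-1)(1/n_c + 1/n_t)/2\) and
  \(\sigma_0 = \sqrt{2(B-1)}\,(1/n_c + 1/n_t)/2\) (each used bin
  contributes an approximately scaled \(\chi^2_1\) term under the null),
  clipped at 0. Two samples from the same distribution score near 0 with
  spread near 1; identical samples score exactly 0 (their raw chi-square,
  0, lies below the null mean, hence the clip). Because the chi-square is
  bounded, the statistic *plateaus* once distributions separate — the
  saturation EMD avoids.
* **Mahalanobis distance (`mahalanobis_distance`)** — distance between
  sample means in units of the pooled covariance; blind to shape changes
  that leave the mean in place. A ridge option covers singular covariances.
* **MFI delta (`mfi_delta`)** — the signed difference of channel medians
  (lower median for even counts), the classical single-marker readout.

## The separation demonstration

`cmd_shift_series()` regenerates the canonical contrast. A minor subpopulation
(fraction \(\pi = 0.2\) by default) moves away from a standard-normal main
population in steps of 2 SD; at each step the sample is compared with an
unshifted reference. EMD grows linearly — asymptotically it transports
\(\pi\) of the mass over distance \(s\), so the slope approaches \(\pi\) —
while the PB statistic saturates.

One binning choice matters here and is deliberate: the PB statistic in this
demonstration is binned coarsely (`pb_stop_threshold = n/32`, i.e. roughly
16–32 bins, putting the outermost control-bin boundary near 2 SD), matching
how the statistic is used for univariate comparisons and yielding its
characteristic plateau beginning once the subpopulation passes about
2 SD. Under the fine \(2\ln N\) *signature* binning (~660 bins at
\(N = 20\,000\)) the outermost boundary sits near 3.6 SD and saturation
completes only around \(s \approx 6\). EMD signatures keep the fine
binning; EMD's linearity is insensitive to this choice.

```{r shift-series, eval = FALSE}
tab <- cmd_shift_series(list(seed = 42))
tab
#   shift        emd        pb
#       0 0.01435266   0.43...
#       2 0.40819721 214.5...
#       4 0.80972964 423.0...
#       6 1.21624887 431.6...
#       8 1.59681238 423.2...
```

## Classification workflow

`score_cohort()` turns a paired control/stimulated cohort into per-subject
scores; `fit_linear_svm()` fits a linear maximum-margin separator on the
raw scores (no feature normalization), with a soft margin (`C = 1`) for
overlapping score distributions and an effectively hard margin (`C = 1e5`)
for separable ones. For one-dimensional separable scores under a hard
margin the package uses the closed form — the threshold is the midpoint of
the gap between the closest opposing scores; otherwise it delegates to
libsvm (via e1071, tolerance `1e-7`). Points exactly on the separator go to
the positive side; that and the seed-mandatory random mode keep every run
reproducible.

`repeated_subsample_validate()` implements repeated sub-sampling
validation: every split trains on `train_per_class` subjects per class and
counts misclassifications on the rest. Exhaustive mode enumerates all
training combinations (e.g. all \(\binom{10}{5}^2 = 63\,504\) splits of a
10 + 10 cohort); random mode draws `n_reps` splits and then adds targeted
splits so every subject is held out at least once. The headline "best"
validation error is the *minimum* over splits; because that statistic is
optimistic (with tens of thousands of splits even weakly informative scores
can find one lucky perfect split), the mean error rate over splits is
always reported alongside it.

## The synthetic-data generator

All tests run on synthetic data with the structure the workflow assumes:

* `sample_mixture()` — Gaussian mixtures with per-component means, SDs and
  weights; component counts are multinomial and rows are shuffled.
* `shift_series()` — the moving-subpopulation experiment above
  (defaults: \(\pi = 0.2\), \(N = 20\,000\); the minor fraction is a free
  parameter, fixed once at 0.2 as a typical activated-subset size, and all
  slope statements are relative to it).
* `gen_cohort()` — paired control/stimulated samples for two classes on
  two channels (emulating CD203c/CD63). Responders shift a fraction
  \(\pi\) of stimulated events by `effect` on both channels; *instrument
  drift* is a small translation applied to the stimulated samples of both
  classes, so only responders differ from their controls beyond drift.
  Defaults used throughout the validation analyses: 10 subjects per class,
  `effect = 3` SD, `drift = 0.1`, 2 000 events per sample — sizes at which
  every analysis runs in seconds to a couple of minutes on one core while
  leaving sampling noise well below the effects being measured.

The "deliberately degraded" single-channel MFI readout used in the
classification-recovery analysis computes the median shift from only the
first 8 events of each sample. This models a noisy low-count readout: the
median of 8 events has a sampling SD near 0.44 while the class-mean MFI
separation at these cohort settings is about 0.32, so the degraded scores
overlap heavily and no split of the exhaustive protocol classifies its
holdout perfectly — in contrast to the EMD scores, which separate the
classes completely.

What the generator does *not* model: fluorescence spillover/compensation,
heavy-tailed or autofluorescent populations, acquisition-time trends,
gating errors, or rare (<0.1%) subsets. Passing tests therefore demonstrate
correctness of the algorithms under clean Gaussian-mixture conditions, not
robustness to every artifact of real cytometry data.

## Numerical choices and degenerate inputs

* Transforms: `asinh(x / cofactor)` (default cofactor 150) is the default
  scale; the Logicle biexponential is available with explicit
  `(T, W, M, A)` and is inverted by vectorized bisection (60 halvings,
  monotone to machine precision). Logicle parameter auto-estimation is out
  of scope. Transforming twice is an error, not a silent no-op.
* Gates are closed intervals; a gate that removes every event raises an
  error reporting the surviving count.
* Samples with a single event produce one-bin signatures; zero-variance
  samples produce single-leaf schemas with a warning; binned statistics
  require at least two bins.
* Among tied optimal transport plans only the objective value is
  contractual; the returned plan is whichever optimum the solver reaches.

## Limitations

* EMD here is the equal-mass (balanced) transport problem; partial/unequal
  mass transport and entropic (Sinkhorn) approximations are out of scope.
* Euclidean ground distance is computed in whatever units the centroids
  carry; channels should be transformed to comparable scales before
  comparison, as no per-channel rescaling is applied.
* The FCS reader covers list-mode files (versions 2.0–3.1, integer/float/
  double, both byte orders) without compensation or FCS writing.
* The exhaustive validation protocol is quadratic in per-class combination
  counts; beyond the configurable cap (default `1e5` splits) use random
  mode.
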