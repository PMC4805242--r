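# flowEMD

Quantifying differences between cytometry samples with the Earth Mover's
Distance (EMD).

## The problem

Flow cytometry readouts often need a *magnitude* of change between two cell
populations — e.g. how far a basophil population shifted its CD203c/CD63
expression after allergen stimulation, relative to the unstimulated
control. Test statistics built on p-values (probability binning,
chi-square) saturate once two populations barely overlap and explode for
trivially small shifts at large N. `flowEMD` instead scores sample pairs
with a true metric on distributions.

## The method

Each sample (an N × d event matrix, optionally asinh- or
Logicle-transformed and rectangularly gated) is summarized as a
*signature*: bins from recursive median splits along the maximum-variance
channel (stopping at 2 ln N events per bin by default), each represented by
its centroid m_j and event fraction w_mj. For signatures
P = {(p_i, w_pi)} and Q = {(q_j, w_qj)} with unit mass and Euclidean
ground distances d_ij = ‖p_i − q_j‖₂, the package solves the
transportation linear program

    minimize   Σ_ij d_ij f_ij
    subject to f_ij ≥ 0,  Σ_j f_ij = w_pi,  Σ_i f_ij = w_qj,  Σ_ij f_ij = 1

with a transportation simplex written in C++, and reports
EMD(P,Q) = Σ d_ij f_ij / Σ f_ij — the minimum work per unit mass to
reshape one distribution into the other, equal to the Mallows
(1-Wasserstein) distance. Alongside it the package implements the baseline
measures it is compared against (probability-binning statistic T(χ),
symmetric chi-square, Mahalanobis distance, MFI deltas), a linear-SVM
classification workflow with exhaustive or repeated random sub-sampling
validation, Gaussian-mixture generators for synthetic cohorts, and a small
CLI (`inst/cli/flowemd`).

## Worked example

A minor subpopulation (20% of events) moves away from a standard-normal
main population in 2-SD steps; each mixture is compared with an unshifted
reference (N = 20 000 events per sample):

```r
library(flowEMD)
tab <- cmd_shift_series(list(seed = 42))
tab
#   shift        emd          pb
# 1     0 0.01435266   0.4387892
# 2     2 0.40819721 214.5434512
# 3     4 0.80972964 423.0035644
# 4     6 1.21624887 431.5948235
# 5     8 1.59681238 423.1973425
```

EMD grows linearly with the separation — the slope approaches the moving
fraction 0.2, since that much mass travels the extra distance — while the
p-value-based probability-binning statistic saturates once the
subpopulations no longer overlap (shift ≥ 4): more biological separation,
no more signal.

Scoring a cohort and classifying it:

```r
co <- scored_cohort(paste0("S", 1:6), rep(c("CF", "ABPA"), each = 3),
                    c(0.01, 0.02, 0.03, 0.5, 0.6, 0.7))
fit_linear_svm(co, C = 1e5)
# svm_separator: f(x) = w.x + b, C = 100000; positive side -> 'ABPA'
#   1D threshold: 0.265
```

`repeated_subsample_validate()` evaluates such thresholds over every (or
many random) train/validation splits and reports the best and mean
validation misclassification counts.

See `vignettes/flowEMD-methods.Rmd` for the model, parameter choices and
limitations.

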