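---
title: "Methods: directed connectivity of resting-state networks with gpdcnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: directed connectivity of resting-state networks with gpdcnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpdcnet)
```

## The model

The unit of analysis is a multichannel time series: `T` timepoints of `N`
network time courses, sampled at the repetition time (TR, default 2 s).
Directed influence is modelled by a vector autoregression of order `p`,

$$x_t = \sum_{k=1}^{p} A_k x_{t-k} + e_t, \qquad e_t \sim N(0,
\mathrm{diag}(\sigma_1^2, \dots, \sigma_N^2)),$$

whose coefficients carry the Granger-causal structure: `A_k[i, j]` is the
lag-`k` effect of channel `j` on channel `i` (source = column, target =
row, stated in every output header to prevent silent transposition).
Estimation is equation-wise ordinary least squares (`mvar()`), with
channels z-scored first so the innovation variances are comparable across
networks. The residual covariance uses the small-sample divisor
`T_eff - N p - 1`.

Generalized partial directed coherence weights the Fourier-transformed
coefficient matrix $\bar A(f) = I - \sum_k A_k e^{-i 2 \pi f k}$ by the
innovation standard deviations:

$$|\pi_{ij}(f)| = \frac{|\bar A_{ij}(f)| / \sigma_i}
{\sqrt{\sum_k |\bar A_{kj}(f)|^2 / \sigma_k^2}},$$

so that $\sum_i |\pi_{ij}(f)|^2 = 1$ for every source `j` and frequency —
an identity the tests verify to `1e-8` on random stable models, and which
self-terms participate in (they reflect autoregression and are excluded
from the group statistics, not from the normalization). The spectrum is
evaluated on 129 evenly spaced frequencies on `[0, Nyquist]`, fine enough
that band-averaging error is negligible for these smooth spectra, and
averaged over 0.01–0.1 Hz — the conventional low-frequency window of
resting-state BOLD — to give one directed `N x N` edge matrix per
subject-session.

The VAR order is chosen by the multivariate Akaike criterion
$\ln\det\hat\Sigma_p + 2 p N^2 / T_\mathrm{eff}$, all candidate orders
fitted on the common sample window implied by `p_max` (default 6), ties to
the smaller order. On band-pass-filtered series the AIC typically selects
`p_max`, because the filter itself induces long autocorrelation; this is
expected and harmless for the edge matrices, which are band-averaged.

## What the synthetic generator emulates

`study_spec()` / `generate_study()` produce the study design the pipeline
is validated against: two groups (21 patients, 19 controls) by two
sessions (before/after an intervention), `T = 400` samples per session at
TR 2 s, six networks (ECN, VN, SMN, RFPN, DMN, SN) driven by a stable
VAR(1) base graph. The designated edge `SMN -> DMN` is multiplied by 0.3
in patients at baseline (the deficit) and by a further 3.0 after the
intervention (the training gain), restoring it to 0.9 of the control
value. Controls keep the base graph in both sessions.

Choices worth stating:

* **Effect sizes are calibration choices.** No effect size is available
  for the group difference this design mirrors, so deficit 0.3 / gain 3.0
  were fixed once as values that a between-group t test at `n = 21/19`
  detects reliably but not trivially, and never revisited.
* **Per-subject biological variability.** Each subject carries a
  log-normal multiplier (sd 0.15 on the log scale) on the designated edge,
  shared across their two sessions. Without it, all subjects in a cell
  would share one true causal strength and the clinical correlation would
  have no between-subject signal to recover.
* **Clinical scores** (Role Physical, Bodily Pain; 0–100 scale) are
  linear in the *true* band-averaged GPDC of the designated edge of that
  subject-session's generating graph, plus Gaussian noise (slopes 150 and
  110 score-units per GPDC unit, noise sd 8 and 6). With zero noise the
  correlation between score and true strength is exactly 1 — the exactness
  check the tests use.
* **Innovations are Gaussian and node-independent** (diagonal noise
  covariance): GPDC's variance weighting presumes meaningful per-node
  innovation variances, and nothing more structured is warranted.
* **Motion outliers come in bursts.** Simulated FD/DVARS exceed the
  censoring thresholds on ~2% of frames, grouped into short episodes as
  real head motion is; episodic outliers leave long contiguous clean runs,
  which the VAR stage needs.
* **HRF convolution is off by default.** The canonical double-gamma
  convolution (`convolve_hrf()`) is available, but hemodynamic smoothing
  confounds VAR coefficient recovery, and the analysis operates on ICA
  time courses after band-pass filtering anyway.
* **Voxel rendering** paints node series into peak-normalized Gaussian
  blobs on a 12×14×12 grid — desk-scale geometry for the ICA and cluster
  stages.

What the generator does **not** emulate: scanner artifacts, physiological
noise spectra, spatially correlated noise, hemodynamic variability across
regions, or non-stationarity. Passing tests therefore demonstrate the
statistical machinery is correct and calibrated on its stated model, not
that real BOLD data satisfy that model.

## Preprocessing

Band-pass filtering is a fourth-order Butterworth applied forward and
backward (zero phase), the standard realization in resting-state
pipelines; FFT masking was rejected for its spectral ringing. The
implementation initializes each pass at its steady state and uses
odd-reflection padding, which removes the boundary step transients
(verified to agree with the reference scientific-Python implementation to
`1e-12`). Repeated filtering is idempotent for in-band content; energy at
the band edges is attenuated again on each pass, as for any realizable
filter.

Confound regression projects channels onto the orthogonal complement of an
intercept plus nuisance regressors; CompCor-style regressors are the top
principal components (default `k = 5`, common aCompCor practice) of the
variance-normalized noise-compartment series. Motion censoring flags
frames whose FD strictly exceeds 0.5 mm or standardized DVARS strictly
exceeds 1.5 — strict inequality, reading "exceeds" literally, so a frame
exactly at threshold is retained. Censored frames are kept but flagged;
the VAR stage fits on the longest contiguous clean run, since lagged
regression requires contiguity.

## Group ICA

Spatial ICA is temporal-concatenation group ICA: per-image voxelwise
demeaning with one global variance scale (per-voxel z-scoring would
distort the spatial profiles being recovered), PCA reduction, and a
symmetric fixed-point ICA with tanh contrast. The component count defaults
to the minimum-description-length estimate computed from the eigenvalues
of the concatenated data's temporal covariance (voxels as observations);
exact rank deficiencies — e.g. the one-per-image constraint introduced by
voxelwise demeaning — are absorbed by eigenvalue flooring with a warning.
Stability is handled by multiple random restarts, keeping the restart
whose components are most consistently matched (greedy maximal absolute
correlation) across all restarts; full bootstrap-based stability analysis
is intentionally out of scope. Subject time courses and maps come from
dual regression, chosen over other back-reconstruction variants for being
simple and well characterized. Components are labelled against binary
templates by goodness of fit — mean map value inside the template minus
mean outside — assigned greedily, ties to the lower component index, with
a warning when a best score is not positive.

## Voxelwise network statistics

Within-network connectivity maps are Fisher r-to-z transformed
(`atanh`, defined only for `|r| < 1`). The repeated-measures design is
decomposed into its two estimable contrasts: the condition effect is the
voxelwise paired t of (after − before) across subjects, and the
interaction is the two-sample pooled-variance t of those differences,
patients minus controls. Inference is cluster-level: voxels with `|t|`
above the two-tailed `p = 0.005` quantile form clusters under
26-connectivity, cluster extent is the statistic, and the familywise-error
correction is a permutation null of the maximal extent — sign-flipping of
the difference maps for the condition effect, group-label permutation for
the interaction — with corrected
`p = (1 + #{null >= observed}) / (1 + n_perm)`. Permutation was chosen
over random-field theory because it is exactly valid on small synthetic
grids with arbitrary smoothness. Zero-variance voxels get `t = 0` and are
masked; a single-subject input degenerates to a fully masked map, never a
crash.

## Surrogate edge detection

Per-subject, per-edge detection compares the observed band-averaged GPDC
against surrogates in which every channel is independently
phase-randomized (amplitude spectra preserved, Hermitian symmetry
maintained), with the rank-based p-value `(1 + #{surrogate >= observed}) /
(1 + n_surrogates)` and detection at `p <= alpha`; `(1 + n) * alpha >= 1`
is enforced so the level is attainable. Calibration holds for stationary
inputs, so the pipeline runs detection on the *unfiltered* series: a
band-pass-filtered series is no longer circularly stationary and
empirically inflates the null detection rate. Band specificity is already
supplied by the band-averaging of the GPDC itself. The per-subject
detection maps are averaged into edge-occurrence frequency matrices.

## Edge-wise group inference

Three test families run on the directed off-diagonal edges (self-edges
reflect autoregression and are excluded): one-sample t against zero,
two-sample pooled-variance t between groups (Welch available by flag;
pooled is the classical default this type of analysis historically used),
and paired t on session differences. Each family is corrected by
Benjamini–Hochberg FDR at `q = 0.05` *within that family* — one test, one
contrast, `N(N−1)` edges; that is the narrowest defensible family and the
choice is recorded in the provenance record. All tests are two-tailed.
Clinical correlations are Pearson with the exact t-based p (`df = n − 2`),
either on session levels or on per-subject (after − before) differences in
both variables; `r^2` is reported alongside `r`.

## Numerical choices and degenerate inputs

* Singular lagged-regressor Gram matrices fall back to a logged ridge
  jitter of `1e-8`; identifiability (`T_eff > N p + 1`) is checked first.
* Zero-variance edges give `p = 1` with a note; constant variables make
  the correlation error out rather than return `NaN`.
* Unstable graphs are rejected at simulation time with the spectral
  radius in the message; `simulate_var` discards a 500-sample burn-in so
  retained samples are effectively stationary.
* All randomness flows from explicit integer seeds; a global pipeline
  seed fans out to stage seeds through a counter-based derivation that
  keeps every derived seed a valid 32-bit integer. Rerunning a
  configuration reproduces byte-identical tabular outputs.

## Problem sizes used in validation

The shipped tests validate calibration and recovery at desk scale, chosen
to exercise each property with adequate Monte-Carlo resolution: 100 random
models for the normalization identity; 100 seeds for AIC order recovery;
50 replicate studies for planted-pattern recovery and for null FDR
calibration; 200 null simulations with 500 permutations each (20 subjects,
12×14×12 grid) for cluster-FWE calibration; 50 null subjects with 99
surrogates each for detection calibration; 1000 simulations at `n = 21`
for the correlation null. The acceptance script uses moderately smaller
replicate counts for its summary quantities; both are the package's own
choices of resolution.

## Known limitations

* GPDC, like any VAR-based measure, cannot distinguish direct influence
  from influence mediated by an unmodelled intermediate network.
* Band-pass filtering before VAR fitting induces long autocorrelation and
  drives the AIC to its upper bound; estimates remain usable because the
  downstream quantity is band-averaged, but order interpretation is lost.
* The equal-variance two-sample test is the default for fidelity to
  classical practice, not because equal variances are guaranteed.
* The synthetic clinical link is linear by construction; the pipeline's
  Pearson correlation would understate a monotone nonlinear coupling.
* One reporting ambiguity is inherited from the study design this
  emulates: a session-difference correlation can be reported against
  either score's difference; the package computes both (`RP_differences`,
  `BP_differences`) rather than resolving the ambiguity.
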