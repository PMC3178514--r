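---
title: "Multimodal functional network connectivity: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal functional network connectivity: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfnc)
```

## The problem

EEG and fMRI observe the same underlying neural populations through very
different channels: volume-conducted scalp potentials at millisecond
resolution, and hemodynamically blurred, slowly sampled BOLD signals at
millimetre resolution. *Functional network connectivity* (FNC) moves the
unit of analysis from voxels or channels to whole networks: spatially
coherent patterns, each with one time course, extracted by spatial
independent component analysis (ICA). The multimodal extension implemented
here (mFNC) runs the chain in both modalities separately —

1. extract functional networks per modality by multi-restart spatial ICA
   with consensus clustering,
2. infer directed interactions between the network time courses by
   conditional Granger causality on a vector autoregressive (VAR) model,
3. match networks *across* modalities in the spatial domain by
   empirical-Bayes EEG source inversion that uses the fMRI spatial patterns
   as source-covariance priors (NESOI),

and then combines the two directed graphs over the matched nodes. Networks
visible to only one modality (electrically silent metabolic activity, or
transient neuroelectric activity without a metabolic correlate) stay in the
combined graph as modality-specific nodes.

## Models

### Network interactions

The time courses of the networks are modeled as a stationary VAR(p)
process,
$$S(t) = \sum_{m=1}^{p} A_m S(t-m) + E(t),$$
with $k \times k$ lag matrices $A_m$ and white innovations $E(t)$ with
covariance $\Sigma$. A single long series is fit by the
Levinson–Wiggins–Robinson recursion on the sample autocovariances
(`fit_var(method = "lwr")`); trial data are pooled by lag-trimmed stacked
least squares, treating each trial as an independent realization of one
process. The order $p$ minimizes the multivariate BIC
$\ln\det\hat\Sigma(p) + k^2 p \ln(N_\mathrm{eff})/N_\mathrm{eff}$.

Directed influence is Geweke's conditional measure,
$$F_{j \to i} = \ln\frac{\hat\Sigma^{(-j)}_{ii}}{\hat\Sigma_{ii}},$$
the log ratio of target-$i$ residual variances without and with the
candidate source's lags, all other channels included in both models. Edge
significance is a block F-test on all $p$ lag coefficients of the candidate
source, with the per-edge threshold $\alpha/(n(n-1))$ (Bonferroni over
ordered pairs, self-influences excluded); the nominal level defaults to
$\alpha = 0.01$.

### Cross-modal matching

Each EEG component topography $Y$ (a channel vector) is inverted under the
two-level Gaussian model
$$Y = X\Phi + \varepsilon,\qquad \varepsilon \sim N(0, \gamma_0 I),\qquad
  \Phi \sim N\!\left(0, \textstyle\sum_i \gamma_i Q_i\right),$$
where $X$ is the lead field and each covariance component $Q_i$ encodes one
fMRI network: the map is z-scored, entries with $|z|$ below 3 are zeroed,
and $Q_i = \mathrm{diag}(z^2)$. One aggregated multiple-sparse-priors (MSP)
component — Gaussian-smoothed patches spanning every dipole not covered by
any fMRI prior — guarantees the priors sample the whole source space. The
nonnegative hyperparameters $\gamma$ are estimated by restricted maximum
likelihood, implemented as EM on the sensor-space second moment, which
increases the variational free energy (a lower bound on the log evidence)
monotonically at every step; the trace is checked for monotonicity in every
test. Convergence is declared at a relative free-energy change below
`reml_tol` ($10^{-6}$) or after `reml_max_iter` (256) iterations.

Matching uses trace-weighted normalized contributions
$\rho_i = \gamma_i\,\mathrm{tr}(X Q_i X^\top) / \sum_j \gamma_j\,
\mathrm{tr}(X Q_j X^\top)$ (raw $\gamma$ are not comparable across
components of different scale). The argmax prior wins; when MSP wins — ties
break toward MSP, the conservative call — the EEG component is
EEG-specific. fMRI components never matched are fMRI-specific.

### Graph metrics

On the thresholded directed graph, `causal_density()` reports the number of
significant links (and its normalized fraction of $n(n-1)$), and
`causal_flow()` reports per-node out-degree minus in-degree, labelling
positive flows "source" and negative flows "sink".

## The synthetic benchmark

The simulator reproduces a fully specified EEG–fMRI study on a disc of
2452 dipoles/voxels (a 70×70 grid with 200 mm field of view at slice height
18 mm, two "white-matter" holes calibrated once so exactly 2452 cells
survive) inside a concentric three-sphere head model (radii 0.87/0.89/1,
conductivities 1 : 1/80 : 1, scalp radius 1 ≙ 100 mm). Sixty-two electrodes
sit on a quasi-uniform spiral over the upper hemisphere; the lead field is
the analytic Legendre-series solution with per-degree radial transfer
coefficients, adaptively truncated (relative tolerance $10^{-8}$) and
average-referenced.

Four sources with patch sizes 90/30/32/100 dipoles interact through a
VAR(2) process: every node is a damped AR(2) oscillator with its own
resonance (pole radius 0.35; angles $\pi(0.25, 0.40, 0.55, 0.70)$, about
6–18 Hz at the 50 Hz neural rate), and coupling $c$ sets the four true
edges S1→S3, S2→S3, S3→S2 and S3→S4. 18 000 samples (360 s) are kept after
a 1000-sample burn-in. EEG sees S1–S3: 40 trials of 55 samples,
physiological noise per source (SNR 5 by default), projection through the
lead field, a single-scalar scalp renormalization, channel-wise measurement
noise at SNR 1, and the average reference. fMRI sees S1, S3 and S4: gamma
HRF convolution (shape 6, scale 0.9 s, so the peak sits at 4.5 s; kernel
support 13 × TR = 19.5 s sampled at the 20 ms neural step), per-source
physiological noise, patch-weighted voxel series subsampled every 75 steps
to 240 volumes at TR 1.5 s, and spatially uniform measurement noise at
SNR 0.2 referenced to the mean signal variance of the volume.

### Deliberate design choices, and why

Several points are genuinely open in this construction; the package commits
to the following, each configurable:

* **Innovation distribution.** The VAR innovations are unit-variance
  Laplace by default. The decomposition stage *assumes* statistically
  independent, non-Gaussian sources; a Gaussian-driven linear system has
  exactly Gaussian marginals, making the spatial decomposition
  unidentifiable in principle (and, in pilot runs, unusable in practice:
  topography recovery fell from ≈0.95 to ≈0.35 correlation). Only zero
  mean, unit variance and whiteness are required of the innovations by the
  interaction model, so the heavier-tailed choice is free.
* **Distinct node rhythms.** With identical self-dynamics on every node,
  strong coupling makes the network time courses nearly collinear — after
  hemodynamic smoothing the BOLD courses of the coupled sources correlate
  above 0.9 — and spatially distinct networks with collinear courses are
  fundamentally inseparable by any decomposition. Distinct resonances per
  node (also the standard construction in the causality-simulation
  literature) bound the correlations at every coupling in the study range.
* **Scalp renormalization by one scalar.** Channel-wise standardization
  would rescale every topography by an 8-fold-varying diagonal and thereby
  decouple the data from the lead-field geometry that the source inversion
  relies on; a single global scalar sets the signal scale without touching
  geometry. Source courses are standardized per trial (which also gives
  their concatenation the across-trial scale variability that the
  fixed-point contrast feeds on).
* **Volume-referenced fMRI measurement noise.** Scanner noise is spatially
  uniform; its variance is set relative to the mean signal variance over
  the acquired volume (the active patches cover ~9 % of the disc), not to
  each voxel's own normalized variance — the latter buries the 32-voxel
  source irrecoverably at SNR 0.2, while noise injected into the source
  courses themselves leaves nothing for the spatial stage to average away.
* **EEG ICA arrangement.** For fMRI, independence is imposed across voxels
  (the classic spatial ICA). For EEG, independence across 62 channel
  samples is statistically vacuous; independence is therefore imposed
  across time — the standard EEG convention — with the topographies as
  mixing columns. Both arrangements return the same component container
  (maps and courses in fixed slots).
* **Dimension reduction.** Before the fixed-point iteration the whitened
  problem is reduced to the principal dimensions standing clearly above
  the noise floor (eigenvalue > 2 × the median eigenvalue; the median
  estimates the floor, and is ~0 for exactly low-rank data, which then
  keeps every structural dimension). At low SNR the rule loses dimensions
  and the run fails its classification — degradation of the decomposition
  under EEG noise is exactly the failure mode expected of the method.
* **Estimation mode.** The pipeline default is symmetric fixed-point
  estimation, which never dropped below three recovered components across
  pilot seeds; deflation (which stalls data-adaptively at the first
  non-converging unit) is retained, exposed, and exercised in the tests.
* **Scoring.** A replicate passes classification when the assignments
  cover each modality's visible sources exactly, the two jointly visible
  sources are paired across modalities, the EEG-only source is
  EEG-specific and the fMRI-only source is fMRI-specific. A jointly
  visible true edge is one truth item, detected if either modality shows
  it between correctly classified components. Runs failing classification
  contribute zero sensitivity, and every edge they report counts against
  specificity — the strict reading of "only the correct results among the
  correct groups".

### What the generator does *not* emulate

No volume conduction artifacts beyond the linear lead field, no
ballistocardiogram or gradient residue, no HRF variability across regions,
no spatial autocorrelation in the scanner noise, no head-geometry error,
and sources that are exactly patch-uniform. Passing the simulation suite
therefore demonstrates the internal consistency of the chain under its own
generative assumptions — not robustness to the full messiness of real
recordings.

## Numerical choices

* Lead-field series: per-degree 5×5 boundary systems are column-equilibrated
  (raw entries span ~$a^{n}$ to $a^{-(n+2)}$ and are numerically singular at
  high degree); truncation doubles adaptively from order 60 until the scalp
  potentials move by less than $10^{-8}$ relative.
* FastICA stopping: direction change below $10^{-4}$ (up to sign), the
  classic criterion; Gaussian directions keep wandering and fail it, which
  is what makes deflation stall data-adaptively.
* ReML: EM updates clamp at zero (the boundary of the nonnegative cone);
  the sensor-noise hyperparameter keeps a $10^{-10}$-relative floor so the
  model covariance stays invertible on noiseless topographies. EM is slower
  than scoring-based updates but guarantees the monotone free energy that
  the test suite asserts on every inversion.
* Consensus clustering: average-linkage on absolute spatial correlation,
  cut at 1 − 0.8; clusters recurring in at least half the restarts survive;
  near-identical centroids are merged; centroid time courses are refit by
  least squares against the data, which (unlike the whitened-space
  components) does not force orthogonality on correlated network courses.
* Ties: the component-to-source assignment is greedy best-first with
  exclusion and a 0.1 minimum absolute correlation; source-map quantiles
  keep $\lceil qd \rceil$ dipoles with ties resolved in index order;
  matching ties break toward MSP.

## Problem sizes in the test and acceptance runs

The packaged checks run the full-size benchmark (2452 dipoles, 62
channels, 18 000 samples): 32 default-condition replicates for order
selection, matching and free-energy checks; a reduced robustness grid
$c \in \{0.1, 0.7\} \times \mathrm{SNR} \in \{2, \infty\}^2$ with 32
replicates per cell for the monotonicity checks (the full study grid is
4 × 6 × 6 with 256 replicates per cell; `mc_grid()` runs it unchanged if
asked); 500 null
datasets for the familywise calibration; and $T = 10^6$ samples for the
brute-force Granger oracle. The robustness grid uses 5 ICA restarts per
modality (the showcase analysis uses 20); three strong components are
stable across far fewer restarts than real-data components would be.

## Known limitations

* Residual cross-talk between estimated components inflates the EEG false
  positive rate at strong coupling: with $N_\mathrm{eff} \approx 2100$ the
  block F-test detects even a few percent of leaked variance. Specificity
  therefore drops as coupling grows — the union graph usually contains the
  whole true edge set plus occasional leakage edges, rather than matching
  it exactly.
* Granger causality on hemodynamically smoothed, subsampled series is
  fragile by nature: the neural lag (20 ms) is far below the volume time
  (1.5 s), detection rides on the interplay of smoothing and noise, and a
  noise-free BOLD series is nearly deterministic at the volume scale,
  leaving no innovation variance for the test. The fMRI graph is
  correspondingly sparse and contributes mainly the fMRI-only edge.
* The EEG decomposition identifies its rotation from modest
  non-Gaussianity; at physiological SNR below ~2 the component subspace
  itself degrades and classification fails — consistent with the intended
  failure mode, but meaning all downstream quantities should be read
  conditionally on classification success.
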