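---
title: "Mixture modeling of mass spectra by signal partitioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture modeling of mass spectra by signal partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msgmm)
library(ggplot2)
set.seed(1)
```

## The model

A profile-mode proteomic mass spectrum is a vector of ion counts $y_n$
registered at mass-to-charge values $x_n$ (Da), $n = 1,\dots,N$.  Each
peptide or protein species contributes a narrow, approximately Gaussian
component, so after baseline removal the signal is modeled as a scaled
Gaussian mixture

$$ y_n \approx \eta\, \Delta_n \sum_{k=1}^K \alpha_k\, f_k(x_n; \mu_k,
\sigma_k), $$

where $f_k$ is the Gaussian density, the mixing proportions $\alpha_k$ sum
to one, $\eta = \sum_n y_n$ is the total ion current, and $\Delta_n$ is the
width of the detector bin centered at $x_n$ (`compute_bin_widths()`).  Over
a short fragment the bin widths are effectively constant and the model
takes the locally scaled form

$$ y_n \approx \sum_k w_k f_k(x_n), \qquad w_k = s\,\alpha_k, \qquad
s = \frac{\sum_n y_n}{\sum_n \sum_k \alpha_k f_k(x_n)}, $$

which by construction conserves the fragment's total intensity exactly
(`local_scale()`).  Note the unit convention this implies: $w_k$ carries
counts × Da, so the $w_k$ of a whole-spectrum model sum to the ion count
itself only on a ~1 Da grid; the invariant that holds on any grid is that
the predicted signal $\hat y_n$ sums to the observed signal.

## EM for binned counts

The intensities are counts over dense bins, so bin probabilities are well
approximated by density × width, and maximum likelihood fitting reduces to
a *multiplicity-weighted* EM: every grid point enters the E- and M-steps
with weight $y_n$, and the objective is the weighted log-likelihood
$\sum_n y_n \log \sum_k \alpha_k f_k(x_n)$ (`em_binned()`).  An exact
within-bin-integral EM variant exists for coarsely binned data; we use the
dense-bin form throughout because profile grids are dense relative to peak
widths (tests verify fitted parameters move by <0.1% under 2× grid
refinement).

Numerical choices:

* **Initialization** is deterministic: component means at
  intensity-weighted quantiles of the fragment, equal proportions,
  $\sigma$ = span/(4K).  Fits are therefore reproducible without seeds.
* **Stopping**: relative objective change below `tol = 1e-8` or 5000
  iterations.
* **$\sigma$ floor**: half the median grid spacing, preventing collapse
  onto single grid points.
* **Component collapse**: a proportion below 1e-12 drops the component
  (with a message) and renormalizes the rest.
* **Model order** per fragment is chosen by BIC,
  $-2\ell + (3K-1)\log\sum_n y_n$, over $K = 1,\dots,K_\max$, ties toward
  smaller $K$ (`fit_fragment()`).  BIC with the count-weighted likelihood
  means resolution improves with total ion counts: two components 1.5σ
  apart under one apex are resolved reliably at count scales of
  averaged spectra (thousands per peak) but not at tens of counts —
  which is the expected statistical behavior, not an implementation
  artifact.

## Partitioning by splitters

Fitting one EM to a whole spectrum with hundreds of components is
impractical: initialization is fragile and iteration cost and convergence
degrade.  The package instead partitions the signal:

1. **Candidate peaks**: local maxima of a moving-average-smoothed trace
   (`detect_candidate_peaks()`).  Any peak detector could stand in; this
   one is isolated in a single function for substitution.
2. **Clear peaks**: candidates of sufficient *quality* — the ratio of peak
   height to the higher of the two neighboring valleys — spaced at least
   `min_gap` apart (greedy selection in descending quality,
   `select_splitting_peaks()`).
3. **Splitters**: a mixture fit of the *splitter-segment* (the signal
   within `halfwidth` of a clear peak).  Truncation corrupts the fit near
   the fragment edges only, so just the components whose means fall in the
   central half are retained — the reliable part (`fit_splitter()`).  If
   none lands there the peak is demoted.
4. **Segments**: splitter signals are subtracted, negative residuals
   clipped at zero, and the residual is cut at splitter-support midpoints
   (`subtract_splitters()`).  Segments whose residual falls below 1e-3 of
   the mean intensity per point are dropped as empty.
5. **Aggregation**: every retained splitter and segment component enters
   the whole-spectrum model with the local weight from its own fragment
   fit; global proportions are recomputed as $w_k / \sum_j w_j$
   (`decompose_spectrum()`).

Defaults: `quality_thr = 3`, `min_gap` = 50 grid spacings, `halfwidth` =
25 grid spacings, `k_max = 6` per fragment (segments additionally cap
$K$ at the number of candidate peaks they contain plus two).  These
thresholds are deliberate package defaults — the qualitative rules they
implement ("high quality, neither too close nor too far") admit a range
of sensible values, and all are exposed in `partition_config()`.  The
segment list is an embarrassingly parallel work queue; segments are
fitted sequentially here, and the aggregated result is independent of
processing order.

Baseline removal precedes decomposition (`remove_baseline()`): a running
quantile (default 10th percentile over 200 Da windows), smoothed by a
moving average and iterated on the residual until the increment is
negligible — iteration makes the operator idempotent and able to follow
curved baselines.  The baseline algorithm itself is a package choice; any
standard correction can be applied upstream instead (`baseline = FALSE`).

## From components to peaks

EM spends some components on noise and residual baseline.  Post-processing
turns a model into a peak list (`postprocess_model()`):

* **Weight filtering** drops components below `weight_thr` (default 1e-3)
  of the total weight.
* **Merging** groups components by single linkage on their means with the
  tunable distance MZ-thr (default 3e-4, relative — ToF peak widths grow
  with m/z; absolute-Da mode available) and replaces each group with one
  moment-matched Gaussian, preserving the modeled signal's zeroth, first
  and second moments exactly.
* **Peaks** are the component means; peak intensity is the component apex
  height $w_k/(\sigma_k\sqrt{2\pi})$.

Filtering precedes merging so dust components cannot drag merged means.
Both thresholds are operating-point knobs: sweeping them traces the
sensitivity/FDR trade-off (`roc_sweep()`), and the `benchmark` pipeline
command reports each detector at its F1-optimal operating point, which is
the standard convention when comparing peak detectors that each expose
such a knob.

For skewed peaks (common in reflectron-mode ToF data) a single species is
better modeled by two Gaussians; the mean of the taller-narrower component
estimates the species m/z better than the signal's apex
(`higher_narrower_mz()`), because the apex is dragged toward the skew
shoulder while the narrow component's mean is not.

## Evaluation

Detected peaks are matched to ground truth one-to-one, greedily by
smallest relative distance within a tolerance (default 0.3%, the
conventional threshold for low-resolution MALDI-ToF).  Reported indexes:
FDR (fraction of detections matching no truth; defined 0 for zero
detections), sensitivity S (fraction of truths detected), and their
combination $F_1 = 2(1-\mathrm{FDR})S / ((1-\mathrm{FDR})+S)$.  Peak
position accuracy uses the absolute relative error
$|\hat m - m|/m$.  Greedy one-to-one matching is a design choice: the
alternative (many-to-one) inflates sensitivity when one detection covers
several truths.

## The simulator

`sample_truth()` + `render_spectrum()` + `generate_dataset()` emulate a
virtual-mass-spectrometer design: each species has an m/z position
(uniform with minimum spacing), a prevalence (probability of appearing in
a given sample), a mean and SD of peak intensity, and a ToF-like width
$\sigma_i = 10^{-3}\, m_i$ — a resolving power $m/\mathrm{FWHM}$ of about
400, the middle of the 300–1000 band typical of linear-mode MALDI
profiling, under which neighboring species overlap appreciably and
"hidden" components are common (the regime mixture modeling targets;
narrower widths can be requested for high-resolution experiments).  A rendered spectrum is the sum of
Gaussian peaks of the present species, times a log-normal per-spectrum
factor (unit mean, `multiplicative_sd = 0.2`) modeling the random amount
of analyte ionized, plus an exponentially decaying baseline and zero-mean
Gaussian noise whose SD grows linearly with m/z, clipped at zero counts.
Defaults (baseline 20 counts decaying over 3000 Da; noise SD 1 growing by
1e-4/Da; log-normal intensities with median 50) give single-spectrum
signal-to-noise ratios from ~10 for the faintest species to several
hundred for the strongest, which is the regime of the low-resolution
serum profiling data this design mimics.

What the simulator does *not* emulate: detector saturation and dead time,
m/z-dependent peak shape asymmetry (except through the explicit
two-Gaussian skew construction used in the skewness experiments), isotope
envelopes (species are single Gaussians unless composed manually), and
calibration drift between spectra.  Passing tests on simulated data
therefore demonstrate correctness of the algorithmic machinery under the
model's own assumptions, not performance on any particular instrument's
output.

## Problem sizes used in the test suite

The package's validation experiments run at desk scale, chosen so the
whole suite completes in minutes while still exercising every code path
at realistic resolution: recovery experiments use 50 species over the
960–11,169 Da range at 1 point/Da with 10 averaged replicate spectra;
benchmark comparisons use datasets of 100, 200 and 300 species at the
same resolution; resolution and skewness experiments use 50–100 seeded
replicates of single fragments at count scales typical of averaged
spectra (peak apexes of ~10³ counts).

## Known limitations

* Components are Gaussian; strongly non-Gaussian peak shapes are
  represented as multi-component groups rather than by shape-specific
  densities.
* BIC model-order selection is a package choice where several rules are
  defensible; it is isolated in `fit_fragment()` for substitution.
* Very wide residual-baseline structure inside a long segment can absorb
  a low, wide component; the weight filter usually removes it, but a
  conservative baseline correction upstream is the better remedy.
* The m/z grid must be strictly increasing and shared across spectra to
  be averaged; no resampling/alignment is provided.
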