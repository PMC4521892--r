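# msgmm — whole-spectrum Gaussian mixture modeling of proteomic mass spectra

`msgmm` decomposes profile-mode proteomic mass spectra (MALDI-ToF
profiling, MALDI imaging, and similar) into Gaussian mixture models at the
whole-spectrum scale, and turns those models into peak lists.  It is aimed
at analysts who need peak detection and quantification that can see
components *hidden* under overlapping neighbors, and accurate m/z
estimates for skewed peaks — situations where maxima-based peak pickers
fall short.

## The model and the algorithm

After baseline removal, a spectrum of counts $y_n$ at m/z values $x_n$ is
modeled as a scaled Gaussian mixture

$$ y_n \approx \eta \Delta_n \sum_{k=1}^{K} \alpha_k f_k(x_n;\mu_k,\sigma_k),
\qquad \sum_k \alpha_k = 1, $$

with $f_k$ Gaussian densities, $\eta = \sum_n y_n$ the total ion current
and $\Delta_n$ the detector bin widths.  Locally (over a signal fragment)
this reduces to $y_n \approx \sum_k w_k f_k(x_n)$ with $w_k = s\alpha_k$
and a scale $s$ that conserves the fragment's total intensity exactly.
Fitting uses an EM algorithm for binned counts: each grid point enters
with multiplicity $y_n$ and the objective is the weighted log-likelihood
$\sum_n y_n \log \sum_k \alpha_k f_k(x_n)$.

One EM over a whole spectrum with hundreds of components is impractical,
so the signal is **partitioned**: high-quality, well-spaced "clear" peaks
are selected; a local mixture is fitted around each and its reliable
central components (the **splitter**) are subtracted from the signal; the
residual **segments** between splitters are decomposed independently
(model order per fragment by BIC); and all components are aggregated into
the whole-spectrum model.  Post-processing (a component weight threshold
and moment-matched merging with a tunable distance MZ-thr) turns the
model into a peak list; peak positions are the component means.  Detection
quality against a known truth is scored by FDR, sensitivity S and
$F_1 = 2(1-\mathrm{FDR})S/((1-\mathrm{FDR})+S)$ with one-to-one matching
at 0.3% relative m/z tolerance.

The package also ships a virtual-mass-spectrometer style simulator
(species with prevalence, intensity distribution and ToF-like widths;
baseline, heteroscedastic noise, per-spectrum multiplicative factor) so
every claim can be tested against ground truth.

## Worked example

Simulate a 12-species dataset, decompose the averaged spectrum, choose the
weight threshold by an ROC-style sweep, and score the peaks:

```r
library(msgmm)

truth <- sample_truth(12, mz_range = c(2000, 3500), seed = 7,
                      min_spacing = 25, prevalence_range = c(1, 1))
grid <- seq(2000, 3500, by = 0.5)
ds   <- generate_dataset(truth, M = 5, grid, noise_model(), seed = 8)

corrected <- ds$spectra |> average_spectra() |> remove_baseline()
model <- decompose_spectrum(corrected)
model
#> <msgmm_model: 103 Gaussian components>
#>   weighted log-likelihood: -27845.8
#>   total ion current: 17765.7

sweep <- roc_sweep(function(wt) postprocess_model(model, weight_thr = wt),
                   truth, grid = 10^seq(-3, -1.5, length.out = 6))
sweep
#> # A tibble: 6 x 6
#>   parameter   fdr sensitivity    f1 n_detected ok
#>       <dbl> <dbl>       <dbl> <dbl>      <int> <lgl>
#> 1   0.00398 0            1    1             12 TRUE
#> 2   0.00794 0            1    1             12 TRUE
#> 3   0.0158  0            1    1             12 TRUE
#> 4   0.0316  0            0.75 0.857          9 TRUE
#> 5   0.00200 0.5          1    0.667         24 TRUE
#> 6   0.001   0.824        1    0.3           68 TRUE

best  <- sweep$parameter[which.max(sweep$f1)]
peaks <- postprocess_model(model, weight_thr = best)
performance_indexes(match_peaks(peaks, truth, tol = 0.003))
#> # A tibble: 1 x 7
#>     fdr sensitivity    f1 n_detected    tp    fp    fn
#>   <dbl>       <dbl> <dbl>      <int> <int> <int> <int>
#> 1     0           1     1         12    12     0     0
```

The raw model spends ~100 components on 12 species plus noise and residual
baseline; the weight filter removes the dust, and at its F1-optimal
operating point every species is recovered with no false detections.
`tidy(model)` and `glance(model)` give broom-style component and summary
tables, `autoplot(model, corrected)` overlays the fitted components on the
signal, and `higher_narrower_mz()` provides the improved m/z estimator for
skewed peaks.

A shell entry point wrapping the same pipeline lives at
`inst/cli/msgmm.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "msgmm.R", package = "msgmm"))')" \
    simulate --dir out --n-species 200 --seed 7
```

with subcommands `simulate | decompose | peaks | evaluate | benchmark`.

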