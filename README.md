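# qt2map — quantitative MRI T2 mapping of cartilage repair tissue

`qt2map` is an R package for assessing the quality of tissue that forms
after surgical repair of osteochondral lesions (reparative microfracture,
MFS, versus regenerative bone-marrow-derived cell transplantation, BMDCT),
from routine multi-echo spin-echo MRI. It is aimed at radiology-physics and
musculoskeletal-imaging researchers who have a 5-echo T2-mapping
acquisition and delineated volumes of interest (VOIs), and want per-voxel
T2 maps, per-VOI tissue composition, and arm-level statistics.

## The method

Magnitude MRI noise is Rician, which biases T2 estimates at low SNR. The
package fits in the noise-corrected power domain:

* the noise scale is estimated from the automatically segmented air
  background, `sigma^2 = (1/2E) * sum_i <M_i^2>_back`;
* the unbiased power signal `P_i = M_i^2 - 2 sigma^2` is fitted with the
  model `P_i = A0^2 exp(-2 TE_i / T2)` by weighted least squares (weights
  from the Rician power variance, evaluated at a first-pass fit);
* fit quality is gated per voxel on SNR >= 5, R^2 >= 0.5, reduced chi^2
  <= 10, T2 in 5-100 msec, a first-echo intensity floor and a long-TE
  intensity ceiling;
* class thresholds `Ta`/`Tb` are the first/third quartiles of pooled
  control-cartilage T2, and each VOI is quantified as fractions of
  fibrocartilage (`T2 < Ta`), hyaline-like tissue (`Ta <= T2 <= Tb`) and
  remodeling tissue (`T2 > Tb`);
* arms are compared with exact Mann-Whitney / Fisher tests.

A synthetic multi-echo ankle phantom with known ground truth (tissue T2
distributions, per-patient lesion compositions, Rician noise) exercises the
whole pipeline; see the methods vignette in `vignettes/` for model details,
parameter rationale and limitations.

## Worked example

Simulate one "patient", fit the map, derive thresholds from the control
VOI and quantify the treated lesion:

```r
library(qt2map)

spec <- phantom_spec(shape = c(96, 96, 3), sigma_rice = 30, seed = 7)
ph   <- generate_phantom(spec)

noise <- estimate_sigma(ph$series)      # air segmented automatically
#> Rician noise estimate: sigma = 30 (10152 background voxels)

map <- t2map(ph$series, noise)
map
#> T2 map: 96 x 96 x 3 voxels, sigma = 30
#>   valid: 8651 (31.3%); QC-excluded: 16593; low-signal/bone: 2402; out of range: 2

tx   <- load_voi(ph$truth$voi_tx,   map, label = "TX")
ctrl <- load_voi(ph$truth$voi_ctrl, map, label = "CTRL")
thr  <- pooled_quartiles(t2_distribution(ctrl, map))
thr
#> Tissue thresholds: Ta = 25 msec, Tb = 46 msec

composition(tx, map, thr)
#> Tissue composition (n = 966, 852 mm^3):
#>   fibrocartilage  (T2 < 25):        17.0%
#>   hyaline-like    (25 <= T2 <= 46): 55.6%
#>   remodeling      (T2 > 46):        27.4%
```

The derived thresholds sit at the generator's control-cartilage quartiles
(25/45 msec by construction; the upper one lands at 46 here from fit noise
in a single small phantom), and the estimated lesion composition matches
this patient's generating weights (0.178 / 0.554 / 0.267) to about one
percentage point. `run_pipeline()` does the same for a whole two-arm
cohort and emits per-patient CSV tables plus a Mann-Whitney comparison;
`inst/cli/qt2map.R` wraps simulate/fit/analyze/compare/run for shell use,
reading 4-D NIfTI series with a JSON sidecar of echo times.

Single voxels can be inspected with the fitting interface:

```r
te  <- c(13.8, 27.6, 41.4, 55.2, 69)
fit <- t2fit(c(640, 410, 268, 180, 135), te, sigma = 30)
fit
#> T2 fit: A0 = 971.4, T2 = 32.36 msec (ricepower weights)
#>   SNR = 156, R^2 = 0.9986, reduced chi^2 = 0.0892
#>   voxel valid
coef(fit); fitted(fit); residuals(fit); plot(fit)
```

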