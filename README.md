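# myoarch

Quantitative mapping of ventricular myocardial architecture from ex-vivo
diffusion tensor cardiovascular magnetic resonance (DT-CMR).

The package is written for researchers studying myocardial remodelling —
for instance right-ventricular dilation after chronic pulmonary valve
regurgitation — who need to turn diffusion-weighted volumes of excised
hearts into the field's standard architecture read-outs and group
statistics, and to validate that measurement chain end-to-end against
synthetic data with known ground truth.

## What it computes

Per voxel, the diffusion tensor `D` is estimated from the Stejskal-Tanner
signal model `S(g) = S0 · exp(−b gᵀ D g)` by ordinary least squares on
log-signals. Its eigensystem `(λ1 ≥ λ2 ≥ λ3, e1, e2, e3)` and fractional
anisotropy

```
FA = sqrt(3/2) · ||λ − mean(λ)|| / ||λ||
```

feed three angles measured against a local wall-attached frame
(circumferential **c**, longitudinal **l**, radial **r**), built per
60-odd epicardial tangential-plane sectors around each of three analysed
short-axis slices:

* **helical angle** — inclination of e1's tangential-plane projection
  against **c**, positive for the sub-endocardial counterclockwise helix,
* **intrusion angle** — `asin(e1 · r)`, the out-of-plane tilt of the
  fibres,
* **E3 angle** — tilt of the tertiary eigenvector (the sheetlet normal)
  against the tangential plane.

Angles are pooled into per-region histograms (LV free wall, septum, RV
free wall) and binned into 10% transmural-depth intervals with medians
and interquartile ranges. FACT streamline tractography (FA threshold
0.15, inner-product threshold 0.75, 4 cm length cap) visualizes the
primary-eigenvector field. Two-group comparisons use Kolmogorov-Smirnov
tests on pooled distributions, Mann-Whitney U per depth bin on
per-subject medians, and Wilcoxon rank-sum on morphometrics.

A synthetic biventricular phantom (truncated-ellipsoid LV shell plus
crescent-shaped RV) generates DT-CMR datasets with prescribed fibre and
sheet-normal fields, so every recovered angle has a known truth value.

## Worked example

```r
library(myoarch)

# a noiseless phantom with the normal-heart transmural helix profile
spec <- phantom_spec()                      # control medians by default
phantom <- build_phantom(spec)
an <- analyse_subject(phantom$dwi, phantom$scheme,
                      phantom$geometry$zone_map, spec$voxel_size)

print(an$tensors)
print(an$frames)

# median helical angle per transmural third of the RV free wall
for (w in list(c(0, 100/3), c(100/3, 200/3), c(200/3, 100))) {
  r <- region_median(an$maps, "rv", w[1], w[2])
  cat(sprintf("RV depth [%2.0f%%, %3.0f%%): median helical %6.1f deg (n = %d)\n",
              w[1], w[2], r$median_deg, r$n))
}

# streamlines through the RV free wall
seeds <- seed_regions(phantom$geometry$zone_map, an$frames, n_per = 5)
tracks <- track_many(an$tensors, seeds$rv_rightmost,
                     phantom$geometry$myocardium, tract_config(),
                     spec$voxel_size)
print(tracks[[1]])
```

```
tensor field: 113250 voxels (113250 valid, 0 clamped, 0 degenerate)
  median FA 0.670, median MD 9.00e-04 mm^2/s
sector frames: 276 sectors over slices (apical 10, equatorial 24, basal 38)
  residual long-axis misalignment 0.00 deg; 28 fallback, 0 invalid sectors
RV depth [ 0%,  33%): median helical   33.1 deg (n = 648)
RV depth [33%,  67%): median helical    8.3 deg (n = 712)
RV depth [67%, 100%): median helical  -13.1 deg (n = 748)
track: 109 points, 31.5 mm, terminated mask / length
```

The phantom prescribed its RV helix piecewise-constant at
(33.3, 8.4, −13.3)° over the endocardial / midwall / epicardial thirds
(`reference_helix_medians("control")`); the pipeline returns those
plateaus to within a fraction of a degree. `run_study()` scales this to
a full two-group recovery experiment (e.g. 7 normal-profile vs 7
dilated-profile subjects) and emits comparison tables shaped like a
transmural-thirds summary: group medians, IQRs, difference and p-value
per region.

A thin command-line wrapper is installed under `exec/`:

```sh
myoarch phantom --out out/phantom --seed 7
myoarch run     --out out/study   --seed 7
```

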