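# rmarct

Regional model-based metal artifact reduction (rMAR) for low-energy
virtual monochromatic images (VMIs) from dual-energy / spectral CT — plus
a dual-layer spectral-CT simulator that generates artifact-bearing phantom
series with ground truth, so the whole pipeline is testable without
scanner data.

## Who this is for

Low-energy VMIs (40–70 keV) carry the best iodine contrast and soft-tissue
differentiation, and the worst metal artifacts: beam hardening and photon
starvation around implants produce streaks that grow steeply as the
reconstruction energy drops. High-energy VMIs are clean but flat. If you
work with spectral CT slices (medical physics, image-quality research,
MAR algorithm development), `rmarct` corrects the low-energy slices using
only reconstructed images — no projection data, no vendor access.

## The method

Every VMI is a pixelwise linear combination of two material basis images
(MBIs), water `f_w` and bone `f_b` in g/cm³:

```
f_vmi(E) = (1000/ρ_w) · [ (m_w(E)/m_w(E))·f_w + (m_b(E)/m_w(E))·f_b ] − 1000
```

with `m(E)` mass attenuation coefficients. Two VMIs at distinct energies
determine the bases exactly; artifacts in the VMIs propagate linearly into
them and stay put. rMAR exploits this:

1. decompose the series (default 70/140 keV) into `f_w`, `f_b`;
2. find the **optimal** (least-artifact) and **worst** energy by a
   normalized total-variation cost over artifact images extracted with a
   coarse sinogram-interpolation MAR;
3. segment the artifact region `f_M1` with row-wise sorting-and-thresholding
   (median ± 10 HU, two passes with 4-px and 1-px erosion elements);
4. fit a quadratic `basis = a0 + a1·HU + a2·HU²` from the optimal VMI's CT
   numbers to each basis on the artifact-free pixels (bone excluded);
5. replace the bases inside `f_M1` with the model's prediction, and
   re-synthesize VMIs at any energy. Pixels outside `f_M1` are
   bit-identical to the input — the correction cannot invent structure
   elsewhere.

## Worked example

Simulate the bundled two-rod solid-water phantom (200 mm cylinder, two
10 mm titanium rods) through the physics pathway, correct it, and measure
the mean |ΔCT| (ROI mean minus the true solid-water value, 15 HU) at
70 keV over three ROIs placed in the strongest artifact zones:

```r
library(rmarct)

ph  <- make_phantom(default_phantom_spec(n_px = 256))
sim <- simulate_series(ph, mode = "physics", seed = 1)
res <- run_rmar(sim$series)
res
#> <rmar_result> optimal 140 keV, worst 70 keV
#>   artifact mask 10700 px (63.7% of support), metal 84 px

res$curve
#>   index energy_kev     cost cost_norm
#> 1     1         70 475212.1 1.0000000
#> 2     2         80 436829.2 0.9192299
#> 3     3        100 403668.9 0.8494499
#> 4     4        120 391652.8 0.8241640
#> 5     5        140 381563.7 0.8029335

rois <- artifact_rois(sim)
mean(abs(sapply(rois, function(r)
  delta_ct(series_at(sim$series, 70), r, 15)$delta_ct)))   # uncorrected
#> [1] 22.81
mean(abs(sapply(rois, function(r)
  delta_ct(series_at(res$series, 70), r, 15)$delta_ct)))   # after rMAR
#> [1] 1.42
```

The artifact cost falls monotonically from 70 to 140 keV (the optimal
energy here is 140 keV), and the correction removes ~94% of the ROI CT
number error at 70 keV while leaving every pixel outside the artifact mask
untouched. A series without detectable metal passes through unchanged.

A thin CLI wraps the same functions:

```sh
inst/cli/rmar simulate --out series.vmic --truth truth.vmic --seed 1
inst/cli/rmar run --in series.vmic --out-dir out/
inst/cli/rmar eval --in out/corrected.vmic --energy 70 --ref 15 --out eval.csv
```

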