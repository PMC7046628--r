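# spheroclear

Quantitative evaluation of optical-clearing and embedding protocols for
confocal imaging of 3D cell cultures (spheroids, organoids, chip-based
co-cultures).

Light scattering limits whole-mount confocal imaging of ~300 µm spheroids
to the first 50–70 µm; clearing protocols (refractive-index matching in
glycerol, hyperhydration, commercial reagents, ...) extend that depth but
also shrink or swell the sample and quench fluorophores.  Choosing a
protocol therefore needs numbers, not impressions.  `spheroclear`
computes, from calibrated multi-channel z-stacks:

* **Shrinkage/swelling** — spheroid diameter from a maximum-intensity
  projection (Otsu mask, largest component, mean of the two
  principal-axis extents) and the relative change against a pre-fixation
  reference: `100 · (post/pre − 1)`.
* **Depth-resolved intensity** — per-section mean intensity in one fixed
  central circular ROI (default 100 µm), the depths of 50% and 90%
  signal loss (d50 = L·ln 2, d90 = L·ln 10 for an exponential decay with
  attenuation length L), on a **normalized depth** scale
  (depth ÷ post/pre size ratio) so protocols with different shrinkage are
  comparable.
* **Depth-resolved SNR** — per section,
  SNR = µ_signal / σ_background, with µ_signal the mean inside an
  automatic (Otsu) nuclear mask and σ_background a single scalar from the
  shallowest sections; and the **Rose-criterion cutoff**, the depth up to
  which SNR > 5 holds (censored as "> max depth" when it never fails).
* **3D nuclei counts** — median filter (3 px), local adaptive threshold
  (10 px range), hole filling (1 px), multi-scale Laplacian-of-Gaussian
  seed detection (seed range 9–25 px by default), seeded 3D watershed;
  total and marker-positive counts, and object-level precision / recall /
  F-score against ground truth.
* **Group statistics** — Kruskal–Wallis + Dunn for size metrics, one-way
  ANOVA + Tukey for count metrics, Lilliefors normality screening,
  α = 0.05.

A synthetic spheroid simulator (`generate_spheroid()`,
`generate_protocol_panel()`, `generate_uniform_phantom()`) produces
multi-channel stacks with exponential depth attenuation, protocol
shrinkage, rim-restricted marker expression, optional z-compensation
(per-slice gain ramp), Gaussian PSF and background noise — plus
ground-truth labels, so every stage of the pipeline is testable without
access to raw microscope data.

## Worked example

```r
library(spheroclear)

# a 300-um spheroid, 200 nuclei, cleared with L = 150 um attenuation,
# imaged with z-compensation that cancels the attenuation
cfg <- simulation_config(seed = 1, zcomp_slope = zcomp_slope_for(150))
sim <- generate_spheroid(cfg)

d <- measure_diameter(max_projection(sim$stack, "tracker"))
relative_change(300, d)
#> <spheroid_measurement> 300.9 um (reference 300.0 um): +0.3%

decay_depths(z_profile(sim$stack, "nuclei"))
#> <decay_metrics> max 14.4; 50% loss at not reached; 90% loss at not reached

rose_cutoff(snr_profile(sim$stack, "nuclei"))
#> <rose_cutoff> 262.5 um

params <- segmentation_params(seed_range_px = c(5, 13))  # 8-px nuclei
cr <- count_nuclei(sim$stack, "nuclei", "marker", params)
cr
#> <count_result> 200 nuclei, 103 marker-positive (fraction 0.515)
evaluate_segmentation(cr$nuclear, sim$truth)$f_score
#> [1] 1
```

With compensation the central-ROI intensity profile is flat through the
whole stack, so neither the 50% nor the 90% crossing is ever reached
(both censored), the Rose criterion holds essentially to the spheroid
bottom (262.5 µm of 316 µm stack depth), and all 200 simulated nuclei
are recovered (F-score 1) together with the marker-positive fraction.
Rerunning with `zcomp_slope = 0` shows the uncompensated regime: SNR
decays exponentially with depth and deep-layer nuclei are lost.

The four pipeline stages are also available as subcommands driven by one
YAML config (`inst/cli/spheroclear.R`):

```sh
Rscript inst/cli/spheroclear.R generate config.yaml
Rscript inst/cli/spheroclear.R analyze  config.yaml
Rscript inst/cli/spheroclear.R segment  config.yaml
Rscript inst/cli/spheroclear.R report   config.yaml
```

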