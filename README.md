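# capstall

Quantitative analysis of **targeted capillary photothrombosis** experiments:
single cortical capillaries occluded on demand by two-photon excitation of a
circulating photosensitizer (Rose Bengal) at 1000 nm, monitored with
line-scan two-photon microscopy and label-free angiography. The package is
written for researchers running (or simulating) such experiments who need
the full measurement chain as tested, reusable code.

## What it computes

* **Photophysics** — multiphoton excitation order by OLS on the log-log
  power sweep (slope ≈ 2 ⇒ two-photon absorption); two-photon cross
  sections by the reference-ratio method,
  σ_s = σ_r · (F_s φ_r C_r)/(F_r φ_s C_s); and the focal fluence
  E_pulse / (π (0.61 λ/NA)²) compared against the ~1 J/cm² ablation
  threshold.
* **Line-scan hemodynamics** — RBC passages detected as slanted dark
  streaks in kymographs (rows = time, columns = axial position), per-event
  speed from a Radon-style shear-projection orientation estimate, windowed
  flux/speed traces with motion-artifact rejection, and the flux–speed
  correlation.
* **Stall calling** — no-flow events from zero-flux window runs; a vessel
  is BLOCKED when a terminal no-flow run ≥ 15 s reaches the trace end and a
  later verification scan also shows no flow.
* **Angiography** — perfusion maps by high-pass temporal filtering of frame
  stacks; stallograms (vessel ROI normalized to local background, baseline
  1 = indistinguishable from background); longitudinal occlusion tracking
  across pre/0 h/2 h/4 h/24 h sessions.
* **Distance maps** — exact anisotropic Euclidean distance transform from
  tissue to the nearest vessel voxel, with before/after histogram-shift
  summaries quantifying how an occlusion lengthens tissue–vessel distances.
* **Group statistics** — incidence rates and the pooled two-proportion
  z-test, z = (p₁−p₂)/√(p̂(1−p̂)(1/n₁+1/n₂)), for blockage and hemorrhage
  outcomes.
* **Synthetic data** — seeded generators for every input modality
  (kymographs, angiogram stacks, trial tables, power sweeps) with retained
  ground truth, used throughout the tests as parameter-recovery oracles.

## Worked example

```r
library(capstall)

# a 30 s synthetic line scan: 800 Hz, 15 µm of capillary, 10 RBC/s at ~1 mm/s
spec <- kymo_spec(line_rate = 800, n_lines = 24000, rbc_rate = 10,
                  rbc_speed = 1, noise_sd = 0.05, seed = 1)
k  <- generate_kymograph(spec)
ev <- detect_passages(k)
ht <- compute_hemo_trace(ev, k, window_s = 1)
c(detected = nrow(ev), truth = nrow(attr(k, "truth")),
  flux = mean(ht$flux_cps), speed = median(ht$speed_mm_s, na.rm = TRUE))
#> detected     truth      flux     speed
#>  266.000   289.000     8.870     0.924

# the group-level result from the replayed contingency table
two_proportion_ztest(57, 95, 12, 82)[c("p1", "p2", "z", "p_value")]
#> $p1 [1] 0.6       $p2 [1] 0.1463415
#> $z  [1] 6.170893  $p_value [1] 6.79053e-10
```

The detected count sits slightly below truth because shadows that overlap
at the reference column merge (a physical resolution limit, not a bug);
speed and flux recover the generator's settings. The z-test shows a 60 %
blockage rate under the photosensitizer versus 14.6 % in the dye-only
control — a p-value at the 10⁻⁹ scale, i.e. the occlusions are driven by
the photosensitizer, not by generic laser exposure.

The `analysis/` directory holds six numbered drivers
(`01_photophysics.R` … `06_group_stats.R`) that run each stage of the
pipeline on synthetic data and write their tables under `results/`.
`inst/extdata/trials_replay.csv` is the replayed trial table: blockage
counts 57/95 and 12/82 (57 reconstructed from the reported 60 % of 95
trials); its hemorrhage counts are synthetic placeholders at similar rates
in both groups, since those counts are not published as numbers.

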