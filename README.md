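# ablatrack

Lesion depth tracking from M-mode all-optical ultrasound during laser
thermal ablation.

Ablated tissue is markedly more echogenic than native tissue, so a
pulse-echo ultrasound probe aligned with the ablation beam sees the
lesion as a bright, growing band beneath the tissue surface on an M-mode
image (rows = depth, columns = time). `ablatrack` implements the full
monitoring chain for researchers developing such image-guided ablation
systems:

* **Simulation** — a seeded pulse-echo A-line simulator
  (`simulate_sequence()`) with known surface position and lesion-depth
  trajectory, covering both the non-contact regime and the contact
  regime (above-surface ejecta echoes, carbonisation contrast steps).
* **Image formation** — 4th-order Butterworth band-pass (10–40 MHz,
  zero-phase), Hilbert envelope, global log compression, and
  time-of-flight depth axes (`process_sequence()`).
* **Segmentation** — spatially regularised fuzzy c-means. FCM minimises
  `J = Σ_n Σ_m μ_mn^p ||i_n − v_m||²` by alternating
  `μ_mn ∝ ||i_n − v_m||^(−2/(p−1))` and
  `v_m = Σ μ_mn^p i_n / Σ μ_mn^p`; a spatial step re-weights each
  pixel's memberships by their neighbourhood sums
  (`h_mn = Σ_{k∈N_n} μ_mk`, `μ′_mn ∝ μ_mn h_mn`), suppressing isolated
  misclassifications. Iteration stops when the largest centroid change
  is below 0.02; morphological opening/closing extracts the ablation
  region (`segment_lesion()`).
* **Tracking** — surface detection from the pre-ablation window, largest
  sub-surface component, per-frame depth of the deepest masked pixel,
  and a post-laser median as the final depth (`track_lesion()`).
* **Statistics** — a from-scratch two-tailed Wilcoxon signed-rank test
  for paired imaging-vs-reference depth tables, with exact enumeration
  for small samples and a tie-corrected normal approximation
  (`wilcoxon_signed_rank()`).
* **Orchestration** — `run_pipeline()` / `run_grid()` drive
  simulate → process → segment → track reproducibly from a YAML config,
  writing a depth-trace CSV, summary JSON and run log.

## Worked example

```r
library(ablatrack)

acq  <- acquisition_config(aline_rate = 10, num_samples = 640, rng_seed = 1)
scen <- ablation_scenario(laser_power = 4.5, laser_duration = 20,
                          pre_window = 8, post_window = 8,
                          surface_depth = 1.2, max_lesion_depth = 2.0,
                          growth_time_constant = 6)

sq  <- simulate_sequence(scen, config = acq)   # 360 frames, ground truth attached
mm  <- process_sequence(sq)                    # dB M-mode image
seg <- segment_lesion(mm)                      # spatial FCM + morphology
tr  <- track_lesion(mm, seg$mask, pre_window_frames = 80,
                    post_window_frames = 80)

c(recovered = tr$final_depth_mm, truth = tail(sq$truth$depth_trace, 1))
#> recovered     truth
#>  1.917300  1.928749
```

The recovered final depth (median over the 8 s post-laser window) agrees
with the simulator's ground truth within ~0.01 mm here; the end-to-end
test suite enforces ±0.1 mm across plateaus of 0.5–2.0 mm. The paired
agreement test on a measurement table:

```r
res <- wilcoxon_signed_rank(depth_imaging_mm, depth_reference_mm)
res$Z; res$p      # signed-rank deviate and two-tailed p-value
```

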