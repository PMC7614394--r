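---
title: "Monitoring laser ablation lesions with M-mode all-optical ultrasound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring laser ablation lesions with M-mode all-optical ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ablatrack)
```

## The measurement problem

Thermal laser ablation coagulates and eventually carbonises tissue. The
damaged region is markedly more echogenic than native tissue, so a
pulse-echo ultrasound probe aimed along the ablation axis sees a growing
bright band under the tissue surface. Concatenating successive A-lines
into an M-mode image (rows = depth, columns = time) turns lesion growth
into a visible boundary, and segmenting that boundary gives a per-frame
lesion depth — feedback a clinician can use to stop ablating at the
intended depth. `ablatrack` implements the entire computational chain,
plus a seeded simulator that provides ground truth for validating every
stage without any measurement hardware.

## A-line simulation

`simulate_aline()` uses a linear pulse-echo convolution model: each
discrete reflector at depth $d$ contributes a Gaussian-modulated
sinusoidal pulse delayed by its round-trip time $2d/c$, and Gaussian
receiver noise is added last. The default pulse has a 20 MHz centre
frequency and 100% fractional bandwidth at $-6$ dB, placing its spectrum
inside the 10–40 MHz processing band. The default scatterer field
(`tissue_scatterer_field()`) is a bright surface reflector plus sparse
discrete sub-surface scatterers every 0.05 mm — sparse rather than
speckle-dense so that echo positions are exactly checkable; a
Rayleigh-amplitude option emulates speckle statistics when wanted.

Lesion growth follows a saturating monotone law
$$d(t) = d_\infty(P)\,\bigl(1 - e^{-(t-t_\mathrm{on})/\tau}\bigr),$$
with the plateau scaling linearly in laser power, anchored at a
reference power: $d_\infty(P) = d_{\max} \cdot P / P_{\mathrm{ref}}$.
No quantitative growth law is established for this setting; this is the
simplest monotone saturating form consistent with depth increasing with
both power and exposure time, and the plateau is an explicit calibration
knob (`calibrate_plateau()` pins a power/duration pair to a measured
depth), not a claim about tissue. The time constant defaults to
$\tau = 15$ s so a 60 s exposure reaches ~98% of its plateau while a
30 s exposure reaches ~86% — reproducing the qualitative separation of
depths across 30/45/60 s exposures. An optional post-exposure relaxation
(< 5%, off by default) emulates tissue shrink-back on cooling.

Scenario phenomenology follows the two ablation regimes: in the
non-contact regime nothing ever appears above the tissue surface; the
contact regime adds Poisson-timed transient reflectors above the surface
(ejected material crossing the beam) and an optional carbonisation step
that multiplies the lesion's echogenicity gain (default 2x) at a
configurable onset time. All randomness is derived from the acquisition
seed: identical configurations are bit-identical.

## M-mode image formation

`process_sequence()` applies, per A-line: a 4th-order Butterworth
band-pass at 10–40 MHz, envelope detection via the analytic signal, and
log compression to dB. Three numerical choices matter:

* **Zero-phase filtering.** The band-pass is applied forward-backward
  (squaring its magnitude response), so echo peaks keep their arrival
  times and depth estimates carry no group-delay bias. Records are
  padded by odd reflection so start-up transients decay inside the
  padding, not the data.
* **Global log normalisation.** The dB image is normalised to the
  maximum over the *whole acquisition*, never per frame — the method
  relies on brightness increasing over time, and per-frame
  normalisation would erase exactly that contrast. The default dynamic
  range is 40 dB.
* **Depth axis.** `sample_to_depth()` uses the round-trip time-of-flight
  law $d = c\,k/(2 f_s)$ with zero-based sample indices and a default
  (configurable) speed of sound of 1540 m/s, the conventional soft-tissue
  value.

## Lesion segmentation

`segment_lesion()` runs the chain: moving-average denoising (3x3 box
with border truncation), spatially regularised fuzzy c-means, selection
of the highest-centroid cluster, then morphological opening and closing
(square element, radius 1) to drop specks and fill pinholes.

FCM minimises
$J = \sum_n \sum_m \mu_{mn}^p \lVert i_n - v_m\rVert^2$ by alternating
the membership update
$\mu_{mn} \propto \lVert i_n - v_m\rVert^{-2/(p-1)}$ with the centroid
update $v_m = \sum_n \mu_{mn}^p i_n / \sum_n \mu_{mn}^p$. The spatial
step re-weights each pixel's memberships by the summed memberships of
its neighbours, $h_{mn} = \sum_{k \in N_n} \mu_{mk}$ and
$\mu'_{mn} \propto \mu_{mn} h_{mn}$, which suppresses isolated
misclassifications without touching coherent regions. Iteration stops
when the largest centroid change falls below 0.02.

Where the procedure left genuine freedom, the package fixes it as
follows:

* **Three clusters** by default: background / coupling fluid, normal
  tissue, lesion. The lesion is the highest-centroid cluster.
* **Fuzziness $p = 2$**, the community default.
* **Intensities are min-max normalised to $[0,1]$** before clustering,
  making the 0.02 convergence threshold scale-free; a corollary is that
  labels are exactly invariant under increasing affine rescaling of the
  image (a tested property).
* **Initialisation is deterministic** — centroids at evenly spaced
  intensity quantiles; coincident initial centroids are nudged apart by
  $10^{-6}$ of the intensity range.
* **Ordering:** memberships, then one spatial pass, then centroids,
  once per iteration; final labels use the *regularised* memberships.
* **Borders:** the spatial window truncates at image borders (sums run
  over existing neighbours only). One consequence worth knowing: for
  memberships that are spatially uniform but unequal across clusters,
  the spatial step is *not* the identity — it sharpens towards the
  dominant cluster (e.g. $(0.7, 0.3) \to (0.49, 0.09)/0.58$). Only
  memberships equal across clusters are a fixed point.
* **A window of 0 disables the spatial step** (plain FCM); a window of
  1 is deliberately not the identity either, since $h$ then equals the
  pixel's own membership and $\mu' \propto \mu^2$.

A single spatial pass per iteration repairs *ambiguously* misclassified
pixels but, by design, cannot flip a pixel whose intensity makes it
extremely confident in the wrong cluster — that is what the preceding
moving-average denoising and the subsequent morphological opening are
for.

## Depth tracking

The tissue surface is detected once from the quiet pre-ablation window
(per-column intensity argmax, aggregated by median) and then frozen:
the depth reference does not re-track during ablation. Mask pixels at or
above the surface are discarded — this is what rejects contact-regime
ejecta — and the largest connected sub-surface component is kept. Per
frame, lesion depth is the time-of-flight depth of the deepest remaining
mask row minus the surface depth; frames with no sub-surface mask read
zero. The final lesion depth is the *median* over the whole post-laser
quiet window, where contrast has stabilised: a median over ~80 frames is
insensitive to single-frame segmentation glitches, which a single-frame
reading would not be.

Two accuracy limits follow from the design: the traced boundary is
quantised to the scatterer spacing (0.05 mm by default) and biased
slightly by the pulse envelope tail (~0.04 mm at default bandwidth).
Both sit comfortably inside the ±0.1 mm recovery tolerance the
end-to-end tests enforce, but they are why recovered depths trail truth
by a few hundredths of a millimetre.

## Paired agreement testing

`wilcoxon_signed_rank()` implements the paired two-tailed signed-rank
test from first principles: zero differences dropped, average ranks for
ties, and either exact enumeration of all $2^n$ sign configurations
(default for $n \le 15$) or the normal approximation with tie-corrected
variance. No continuity correction is applied by default. One empirical
note: at $n = 12$ the uncorrected normal $p$ can differ from the exact
$p$ by up to ~0.04, while the continuity-corrected form stays within
~0.014; the test-suite property asserting exact/normal agreement within
0.02 therefore uses the corrected form.

## Simulation scale

End-to-end validation runs use a reduced acquisition scale — 10 Hz
A-line rate, 8 s pre/post quiet windows, 640-sample records (~4.9 mm) —
rather than the full 100 Hz / 10 s protocol geometry the simulator
defaults to. Depth recovery is insensitive to frame rate (the final
depth is a median over a quiet window, and lesion growth is slow
relative to either rate), so the reduced scale exercises the identical
code path at a fraction of the cost; a full-scale run is a one-line
configuration change.

```{r example}
acq <- acquisition_config(aline_rate = 10, num_samples = 640, rng_seed = 1)
scen <- ablation_scenario(laser_power = 4.5, laser_duration = 20,
                          pre_window = 8, post_window = 8,
                          surface_depth = 1.2, max_lesion_depth = 2.0,
                          growth_time_constant = 6)
sq <- simulate_sequence(scen, config = acq)
mm <- process_sequence(sq)
seg <- segment_lesion(mm)
tr <- track_lesion(mm, seg$mask, pre_window_frames = 80,
                   post_window_frames = 80)
c(recovered = tr$final_depth_mm,
  truth = tail(sq$truth$depth_trace, 1))
```

```{r mmode-figure, fig.width = 6, fig.height = 4}
image(mm$time_axis, mm$depth_axis, t(mm$image), ylim = rev(range(mm$depth_axis)),
      col = gray.colors(64, 0, 1), xlab = "time (s)", ylab = "depth (mm)",
      main = "M-mode image with traced lesion boundary")
lines(mm$time_axis, tr$surface_depth_mm + tr$depth_mm, col = "green")
```

## What the simulator does and does not establish

The simulator reproduces the acquisition geometry and the lesion
phenomenology — a bright surface, a growing high-echogenicity band,
carbonisation contrast steps, ejecta artefacts, quiet windows — under a
known ground truth, which is precisely what is needed to verify the
processing, segmentation and tracking code. It deliberately omits
diffraction, frequency-dependent attenuation, nonlinear propagation,
fully developed speckle and transducer transfer functions. Passing the
end-to-end recovery tests therefore demonstrates that the *algorithms*
recover known truth through a realistic signal chain; it does not by
itself establish accuracy on tissue data, which is what the paired
signed-rank comparison against an independent reference measurement is
for.

Known limitations: the growth law and its power scaling are calibration
devices, not tissue physics; surface detection assumes the surface is
the brightest pre-ablation feature; the tracker reports a single depth
per frame and does not estimate lateral lesion extent or detect
carbonisation onset.
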