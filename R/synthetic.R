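#' Acquisition configuration for pulse-echo A-line simulation
#'
#' Bundles the digitisation and transducer parameters of the all-optical
#' ultrasound console: sampling rate of the digitiser, A-line repetition
#' rate, record length, the band-limited excitation pulse, and the assumed
#' speed of sound used for time-of-flight depth conversion.
#'
#' @param sample_rate Digitiser rate in samples/second. Default `1e8`
#'   (100 MS/s).
#' @param aline_rate A-line repetition rate in Hz. Default `100`.
#' @param num_samples Samples per A-line record.
#' @param pulse_center_freq Centre frequency of the excitation pulse in Hz;
#'   must sit inside the 10--40 MHz processing band. Default `20e6`.
#' @param pulse_fractional_bandwidth -6 dB fractional bandwidth of the
#'   Gaussian-modulated pulse (dimensionless). Default `1`.
#' @param speed_of_sound Assumed speed of sound in m/s. Default `1540`.
#' @param rng_seed Integer seed controlling all stochastic elements
#'   (noise, ejecta, speckle amplitudes).
#'
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(sample_rate = 1e8,
                               aline_rate = 100,
                               num_samples = 1024,
                               pulse_center_freq = 20e6,
                               pulse_fractional_bandwidth = 1,
                               speed_of_sound = 1540,
                               rng_seed = 1L) {
  stopifnot(sample_rate > 0, aline_rate > 0, num_samples >= 2,
            pulse_center_freq > 0, pulse_fractional_bandwidth > 0,
            speed_of_sound > 0)
  f_max <- pulse_center_freq * (1 + pulse_fractional_bandwidth)
  if (sample_rate <= 2 * f_max) {
    stop("sample_rate must exceed twice the pulse's upper band edge (",
         format(f_max, scientific = TRUE), " Hz)")
  }
  structure(list(
    sample_rate = sample_rate,
    aline_rate = aline_rate,
    num_samples = as.integer(num_samples),
    pulse_center_freq = pulse_center_freq,
    pulse_fractional_bandwidth = pulse_fractional_bandwidth,
    speed_of_sound = speed_of_sound,
    rng_seed = as.integer(rng_seed)
  ), class = "acquisition_config")
}

#' Maximum depth representable by an A-line record
#'
#' @param config An [acquisition_config()].
#' @return Depth in mm of the last sample (round-trip convention).
#' @export
max_record_depth <- function(config) {
  sample_to_depth(config$num_samples - 1L, config)
}

#' Ablation scenario description
#'
#' Defines the timeline and lesion phenomenology of one laser-ablation run:
#' quiet pre/post windows, a laser-on interval during which a sub-surface
#' high-echogenicity lesion grows, optional carbonisation (sudden contrast
#' step) and, in the contact regime, transient above-surface echoes from
#' ejected material.
#'
#' @param regime `"non_contact"` or `"contact"`.
#' @param laser_power Ablation laser power in W (3.5, 4.0, 4.5 in the
#'   emulated protocol).
#' @param laser_duration Laser-on time in s (30, 45, 60 in the protocol).
#' @param pre_window,post_window Quiet acquisition windows before laser-on
#'   and after laser-off, in s. Default 10 s each.
#' @param surface_depth Tissue surface depth below the probe in mm.
#' @param max_lesion_depth Lesion-depth plateau (mm) reached asymptotically
#'   at `reference_power`; plateaus at other powers scale linearly
#'   (see [lesion_growth_model()]).
#' @param reference_power Power (W) at which the plateau equals
#'   `max_lesion_depth`. Defaults to `laser_power`, so a single scenario
#'   grows towards its configured plateau; a power sweep should anchor
#'   this at one protocol power so depth scales across the sweep.
#' @param growth_time_constant Time constant tau (s) of the saturating
#'   growth model. Default 15 s.
#' @param lesion_echogenicity_gain Amplitude multiplier applied to
#'   scatterers inside the current lesion extent. Default 4.
#' @param carbonisation_onset Optional time (s, measured from laser-on) at
#'   which the lesion gain steps up by `carbonisation_factor`; `NULL`
#'   disables the step. Must be < `laser_duration`.
#' @param carbonisation_factor Gain step applied at carbonisation onset.
#'   Default 2.
#' @param ejecta_rate Poisson rate (events/s) of transient above-surface
#'   echoes during laser-on; contact regime only. Default 2.
#' @param relaxation_fraction Fractional shrink (< 0.05) of the lesion depth
#'   after laser-off, emulating tissue relaxation on cooling. Default 0
#'   (depth frozen).
#'
#' @return An object of class `ablation_scenario`.
#' @export
ablation_scenario <- function(regime = c("non_contact", "contact"),
                              laser_power = 4.5,
                              laser_duration = 60,
                              pre_window = 10,
                              post_window = 10,
                              surface_depth = 1.5,
                              max_lesion_depth = 2.1,
                              reference_power = laser_power,
                              growth_time_constant = 15,
                              lesion_echogenicity_gain = 4,
                              carbonisation_onset = NULL,
                              carbonisation_factor = 2,
                              ejecta_rate = 2,
                              relaxation_fraction = 0) {
  regime <- match.arg(regime)
  if (laser_power < 0) stop("invalid scenario: laser_power must be >= 0")
  stopifnot(laser_duration >= 0, pre_window >= 0, post_window >= 0,
            surface_depth >= 0, max_lesion_depth > 0, reference_power > 0,
            growth_time_constant > 0, lesion_echogenicity_gain > 0,
            carbonisation_factor > 0, ejecta_rate >= 0,
            relaxation_fraction >= 0, relaxation_fraction < 1)
  if (!is.null(carbonisation_onset)) {
    if (carbonisation_onset >= laser_duration)
      stop("carbonisation_onset must precede the end of the laser exposure")
    if (carbonisation_onset < 0) stop("carbonisation_onset must be >= 0")
  }
  structure(list(
    regime = regime,
    laser_power = laser_power,
    laser_duration = laser_duration,
    pre_window = pre_window,
    post_window = post_window,
    surface_depth = surface_depth,
    max_lesion_depth = max_lesion_depth,
    reference_power = reference_power,
    growth_time_constant = growth_time_constant,
    lesion_echogenicity_gain = lesion_echogenicity_gain,
    carbonisation_onset = carbonisation_onset,
    carbonisation_factor = carbonisation_factor,
    ejecta_rate = ejecta_rate,
    relaxation_fraction = relaxation_fraction
  ), class = "ablation_scenario")
}

#' Scatterer field
#'
#' Discrete reflectors used by the pulse-echo convolution model.
#'
#' @param positions Reflector depths in mm (all >= 0).
#' @param reflectivities Dimensionless echo amplitudes, same length as
#'   `positions`.
#' @param background_noise_sd Standard deviation of additive Gaussian
#'   receiver noise (amplitude units).
#'
#' @return An object of class `scatterer_field`.
#' @export
scatterer_field <- function(positions, reflectivities,
                            background_noise_sd = 0.01) {
  positions <- as.numeric(positions)
  reflectivities <- as.numeric(reflectivities)
  stopifnot(length(positions) == length(reflectivities),
            all(positions >= 0), all(is.finite(reflectivities)),
            background_noise_sd >= 0)
  structure(list(
    positions = positions,
    reflectivities = reflectivities,
    background_noise_sd = background_noise_sd
  ), class = "scatterer_field")
}

#' Default tissue scatterer field for an ablation scenario
#'
#' One bright surface reflector plus regularly spaced sub-surface
#' scatterers down to (almost) the bottom of the record. Sparse discrete
#' reflectors keep echo positions exactly checkable; set `rayleigh = TRUE`
#' for Rayleigh-distributed amplitudes emulating speckle statistics.
#'
#' @param scenario An [ablation_scenario()].
#' @param config An [acquisition_config()].
#' @param spacing_mm Axial spacing of sub-surface scatterers (mm).
#' @param surface_reflectivity Amplitude of the tissue-surface echo.
#' @param tissue_reflectivity Amplitude of sub-surface scatterers (their
#'   amplitude is multiplied by the lesion gain once inside the lesion).
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param rayleigh If `TRUE`, draw scatterer amplitudes from a Rayleigh
#'   distribution with mean `tissue_reflectivity` (seeded from `config`).
#' @return A [scatterer_field()].
#' @export
tissue_scatterer_field <- function(scenario, config,
                                   spacing_mm = 0.05,
                                   surface_reflectivity = 1,
                                   tissue_reflectivity = 0.1,
                                   noise_sd = 0.01,
                                   rayleigh = FALSE) {
  stopifnot(spacing_mm > 0)
  bottom <- max_record_depth(config) * 0.95
  if (bottom <= scenario$surface_depth)
    stop("record too short: tissue surface lies below the usable depth range")
  pos <- seq(scenario$surface_depth + spacing_mm, bottom, by = spacing_mm)
  refl <- rep(tissue_reflectivity, length(pos))
  if (rayleigh && length(pos)) {
    refl <- with_local_seed(config$rng_seed, {
      sigma <- tissue_reflectivity / sqrt(pi / 2)
      sigma * sqrt(-2 * log(stats::runif(length(pos))))
    })
  }
  scatterer_field(c(scenario$surface_depth, pos),
                  c(surface_reflectivity, refl),
                  background_noise_sd = noise_sd)
}

#' Lesion depth as a function of time
#'
#' Saturating monotone growth model: depth is 0 before laser-on, grows as
#' `d_plateau(P) * (1 - exp(-(t - t_on)/tau))` during the exposure, and is
#' frozen (or, with `relaxation_fraction > 0`, relaxes slightly towards a
#' shallower value) after laser-off. The plateau scales linearly with
#' power, anchored at the scenario's `reference_power`:
#' `d_plateau(P) = max_lesion_depth * P / reference_power`.
#'
#' @param power Laser power in W (>= 0).
#' @param t Time(s) in s from the start of the acquisition (vectorised).
#' @param scenario An [ablation_scenario()].
#' @return Lesion depth(s) below the surface in mm.
#' @export
lesion_growth_model <- function(power, t, scenario) {
  if (power < 0) stop("invalid scenario: negative laser power")
  t_on <- scenario$pre_window
  t_off <- t_on + scenario$laser_duration
  tau <- scenario$growth_time_constant
  plateau <- scenario$max_lesion_depth * power / scenario$reference_power
  d <- numeric(length(t))
  on <- t >= t_on & t <= t_off
  d[on] <- plateau * (1 - exp(-(t[on] - t_on) / tau))
  after <- t > t_off
  if (any(after)) {
    d_off <- plateau * (1 - exp(-scenario$laser_duration / tau))
    if (scenario$relaxation_fraction > 0) {
      shrink <- scenario$relaxation_fraction *
        (1 - exp(-(t[after] - t_off) / tau))
      d[after] <- d_off * (1 - shrink)
    } else {
      d[after] <- d_off
    }
  }
  d
}

#' Calibrate a growth plateau to hit a target depth at the end of exposure
#'
#' Inverts the saturating growth form so that
#' `lesion_growth_model(laser_power, pre + duration, .)` equals
#' `target_depth_mm` exactly, letting a power/duration grid be pinned to
#' measured depths.
#'
#' @param target_depth_mm Desired lesion depth at laser-off, mm.
#' @param duration Exposure time in s.
#' @param tau Growth time constant in s.
#' @return The `max_lesion_depth` plateau (mm) to configure.
#' @export
calibrate_plateau <- function(target_depth_mm, duration, tau = 15) {
  stopifnot(target_depth_mm > 0, duration > 0, tau > 0)
  target_depth_mm / (1 - exp(-duration / tau))
}

# Gaussian-modulated sinusoid with -6 dB fractional bandwidth `bw`.
# exp(-a t^2) attains 10^(-6/20) at the half-bandwidth point, so
# a = (pi fc bw)^2 / (4 ln 10^(6/20)).
gauss_pulse <- function(t, fc, bw) {
  a <- (pi * fc * bw)^2 / (4 * log(10^(6 / 20)))
  exp(-a * t^2) * cos(2 * pi * fc * t)
}

# Temporal half-width (s) beyond which the pulse envelope is < ~1e-6.
pulse_support_halfwidth <- function(fc, bw) {
  a <- (pi * fc * bw)^2 / (4 * log(10^(6 / 20)))
  sqrt(log(1e12) / (2 * a)) * sqrt(2)
}

# Evaluate an expression with a locally set RNG seed, restoring the
# caller's RNG state afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

#' Transient ejecta events for a contact-regime scenario
#'
#' Poisson-process events during the laser-on interval; each event places a
#' short-lived reflector above the tissue surface (ejected material
#' crossing the beam). Deterministic given the acquisition seed.
#'
#' @param scenario A contact-regime [ablation_scenario()].
#' @param config An [acquisition_config()] (its `rng_seed` drives the
#'   process).
#' @param lifetime Event visibility duration in s.
#' @return A data frame with columns `time`, `lifetime`, `depth_mm`,
#'   `reflectivity` (possibly zero rows).
#' @export
ejecta_events <- function(scenario, config, lifetime = 0.2) {
  empty <- data.frame(time = numeric(0), lifetime = numeric(0),
                      depth_mm = numeric(0), reflectivity = numeric(0))
  if (scenario$regime != "contact" || scenario$ejecta_rate <= 0) return(empty)
  with_local_seed(config$rng_seed + 7777L, {
    n <- stats::rpois(1, scenario$ejecta_rate * scenario$laser_duration)
    if (n == 0) return(empty)
    data.frame(
      time = scenario$pre_window +
        sort(stats::runif(n, 0, scenario$laser_duration)),
      lifetime = rep(lifetime, n),
      depth_mm = stats::runif(n, 0.1 * scenario$surface_depth,
                              0.9 * scenario$surface_depth),
      reflectivity = stats::runif(n, 0.2, 0.6)
    )
  })
}

#' Simulate a single raw A-line
#'
#' Pulse-echo convolution model: each reflector contributes a band-limited
#' pulse delayed by its round-trip time `2 d / c`; reflectors inside the
#' current lesion extent carry amplitude multiplied by the lesion
#' echogenicity gain (stepped higher after carbonisation onset); the
#' contact regime adds transient above-surface reflectors; Gaussian noise
#' is added last.
#'
#' @param frame_time Acquisition time of this A-line in s.
#' @param scenario An [ablation_scenario()].
#' @param field A [scatterer_field()].
#' @param config An [acquisition_config()].
#' @param seed Seed for the additive noise; defaults to `config$rng_seed`.
#'   [simulate_sequence()] passes a distinct per-frame seed.
#' @param ejecta Precomputed [ejecta_events()] table; computed on demand
#'   for contact scenarios when `NULL`.
#' @return Numeric vector of length `config$num_samples`.
#' @export
simulate_aline <- function(frame_time, scenario, field, config,
                           seed = config$rng_seed, ejecta = NULL) {
  total <- scenario$pre_window + scenario$laser_duration + scenario$post_window
  if (frame_time < 0 || frame_time > total)
    stop("frame_time outside the scenario timeline [0, ", total, "] s")

  lesion_depth <- lesion_growth_model(scenario$laser_power, frame_time,
                                      scenario)
  gain <- scenario$lesion_echogenicity_gain
  if (!is.null(scenario$carbonisation_onset) &&
      frame_time >= scenario$pre_window + scenario$carbonisation_onset) {
    gain <- gain * scenario$carbonisation_factor
  }

  pos <- field$positions
  refl <- field$reflectivities
  in_lesion <- pos > scenario$surface_depth &
    pos <= scenario$surface_depth + lesion_depth
  refl[in_lesion] <- refl[in_lesion] * gain

  if (scenario$regime == "contact") {
    if (is.null(ejecta)) ejecta <- ejecta_events(scenario, config)
    live <- ejecta$time <= frame_time &
      frame_time < ejecta$time + ejecta$lifetime
    if (any(live)) {
      pos <- c(pos, ejecta$depth_mm[live])
      refl <- c(refl, ejecta$reflectivity[live])
    }
  }

  n <- config$num_samples
  fs <- config$sample_rate
  c_ms <- config$speed_of_sound
  hw <- pulse_support_halfwidth(config$pulse_center_freq,
                                config$pulse_fractional_bandwidth)
  aline <- numeric(n)
  for (j in seq_along(pos)) {
    if (refl[j] == 0) next
    delay <- 2 * (pos[j] / 1000) / c_ms
    i0 <- max(0L, floor((delay - hw) * fs))
    i1 <- min(n - 1L, ceiling((delay + hw) * fs))
    if (i0 > i1) next
    idx <- i0:i1
    aline[idx + 1L] <- aline[idx + 1L] +
      refl[j] * gauss_pulse(idx / fs - delay, config$pulse_center_freq,
                            config$pulse_fractional_bandwidth)
  }
  if (field$background_noise_sd > 0) {
    aline <- aline + with_local_seed(
      seed, stats::rnorm(n, sd = field$background_noise_sd))
  }
  aline
}

#' Simulate a full M-mode acquisition
#'
#' Frames are spaced `1/aline_rate` apart and cover the whole timeline
#' `pre_window + laser_duration + post_window`; the returned ground truth
#' is the growth model evaluated exactly at the frame times.
#'
#' @param scenario An [ablation_scenario()].
#' @param field A [scatterer_field()]; defaults to
#'   [tissue_scatterer_field()] for the scenario.
#' @param config An [acquisition_config()].
#' @return A list of class `rf_sequence` with elements `rf` (samples x
#'   frames matrix), `frame_times` (s), `config`, `scenario`, and `truth`
#'   (class `ground_truth`: `depth_trace` mm per frame, `surface_depth`
#'   mm, `frame_times` s).
#' @export
simulate_sequence <- function(scenario, field = NULL, config) {
  deepest <- scenario$surface_depth + scenario$max_lesion_depth
  if (!is.null(field)) deepest <- max(deepest, field$positions)
  if (deepest > max_record_depth(config))
    stop("configuration error: deepest structure (", round(deepest, 2),
         " mm) exceeds the record depth range (",
         round(max_record_depth(config), 2), " mm)")
  if (is.null(field)) field <- tissue_scatterer_field(scenario, config)

  total <- scenario$pre_window + scenario$laser_duration + scenario$post_window
  n_frames <- as.integer(round(total * config$aline_rate))
  frame_times <- (seq_len(n_frames) - 1L) / config$aline_rate
  ejecta <- ejecta_events(scenario, config)

  rf <- matrix(0, nrow = config$num_samples, ncol = n_frames)
  for (k in seq_len(n_frames)) {
    rf[, k] <- simulate_aline(
      frame_times[k], scenario, field, config,
      seed = (config$rng_seed * 4096 + k) %% .Machine$integer.max,
      ejecta = ejecta)
  }

  truth <- structure(list(
    depth_trace = lesion_growth_model(scenario$laser_power, frame_times,
                                      scenario),
    surface_depth = scenario$surface_depth,
    frame_times = frame_times
  ), class = "ground_truth")

  structure(list(rf = rf, frame_times = frame_times, config = config,
                 scenario = scenario, truth = truth),
            class = "rf_sequence")
}

#' Laser fluence from pulse energy and aperture diameter
#'
#' `energy / (pi (diameter/2)^2)`, reported per square centimetre.
#'
#' @param energy Pulse energy in J (>= 0).
#' @param aperture_diameter Beam aperture diameter in m (> 0).
#' @return Fluence in J/cm^2.
#' @export
fluence_from_pulse_energy <- function(energy, aperture_diameter) {
  if (energy < 0) stop("energy must be >= 0")
  if (aperture_diameter <= 0) stop("aperture_diameter must be > 0")
  area_cm2 <- pi * (aperture_diameter / 2)^2 * 1e4
  energy / area_cm2
}
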