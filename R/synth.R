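#' Cortical column geometry
#'
#' Named layer depth intervals and column radius for the synthetic
#' generator. Defaults follow a standard rodent-cortex laminar layout:
#' layer 2/3 at 450-850 um, layer 4 at 850-1150 um, layer 5 at 1150-1650 um
#' and layer 6 at 1650-2150 um, in a cylinder of radius 200 um.
#'
#' @param layers data frame with columns `layer`, `top`, `bottom` (um);
#'   intervals must be increasing and non-overlapping.
#' @param radius column radius in um.
#' @return An object of class `column_geometry`.
#' @export
column_geometry <- function(
    layers = tibble::tibble(
      layer = c("L2/3", "L4", "L5", "L6"),
      top = c(450, 850, 1150, 1650),
      bottom = c(850, 1150, 1650, 2150)),
    radius = 200) {
  layers <- tibble::as_tibble(layers)
  stopifnot(all(c("layer", "top", "bottom") %in% names(layers)))
  if (any(layers$bottom <= layers$top)) stop("layer intervals must increase")
  if (nrow(layers) > 1) {
    o <- order(layers$top)
    if (any(layers$top[o][-1] < layers$bottom[o][-nrow(layers)])) {
      stop("layer intervals must not overlap")
    }
  }
  stopifnot_scalar(radius, "radius", positive = TRUE)
  structure(list(layers = layers, radius = radius), class = "column_geometry")
}

#' Population specification
#'
#' Describes one synthetic cell population as a spatially localized,
#' low-rank current source: `rank` spatial weight patterns (dipolar for the
#' leading pattern, quadrupolar for the second) paired with temporal
#' activation courses. `depth_range` is the depth extent the population's
#' membrane currents occupy (somata plus the dendritic arbor carrying the
#' return currents), and `dipole_extent` the vertical sink-source
#' separation within it.
#'
#' @param name population label.
#' @param depth_range length-2 um interval occupied by the sources.
#' @param n_sources number of point sources (>= 2; conservation needs 2).
#' @param rank 1 or 2 spatial-temporal product terms.
#' @param amplitude relative strength (>= 0).
#' @param temporal one of "pulse" (damped evoked response), "oscillatory"
#'   (sinusoidal drive) or "burst" (damped high-frequency burst).
#' @param frequency oscillation frequency in Hz (used by all classes; for
#'   "pulse"/"burst" it sets the intrinsic ringing frequency).
#' @param delay_ms activation latency relative to the shared drive, in ms.
#' @param dipole_extent vertical sink-source separation in um; must fit in
#'   `depth_range`.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(name, depth_range, n_sources = 120, rank = 1,
                            amplitude = 1,
                            temporal = c("pulse", "oscillatory", "burst"),
                            frequency = 50, delay_ms = 0,
                            dipole_extent = 400) {
  temporal <- match.arg(temporal)
  if (length(depth_range) != 2L || depth_range[2] <= depth_range[1]) {
    stop("invalid `depth_range`")
  }
  if (!rank %in% c(1, 2)) stop("`rank` must be 1 or 2")
  if (amplitude < 0) stop("`amplitude` must be >= 0")
  if (n_sources < 2) stop("`n_sources` must be >= 2")
  if (dipole_extent <= 0 || dipole_extent > diff(depth_range)) {
    stop("`dipole_extent` must be positive and fit inside `depth_range`")
  }
  structure(list(name = name, depth_range = as.numeric(depth_range),
                 n_sources = as.integer(n_sources), rank = as.integer(rank),
                 amplitude = amplitude, temporal = temporal,
                 frequency = frequency, delay_ms = delay_ms,
                 dipole_extent = dipole_extent),
            class = "population_spec")
}

# alpha-function envelope, peak 1 at t = tau after onset
alpha_envelope <- function(t, onset, tau) {
  u <- (t - onset) / tau
  ifelse(u > 0, u * exp(1 - u), 0)
}

# shared thalamic-like drive: a damped oscillatory transient starting at
# `onset`; populations mix a lagged copy of this into their own courses so
# that their activations are correlated, as coupled populations are.
shared_drive <- function(t, onset = 20, tau = 4, freq = 45) {
  alpha_envelope(t, onset, tau) * sin(2 * pi * freq * (t - onset) / 1000)
}

# population-specific temporal course before coupling, unit RMS
own_course <- function(spec, t, term) {
  onset <- 20 + spec$delay_ms
  f <- spec$frequency * if (term == 1) 1 else 1.7
  x <- switch(
    spec$temporal,
    pulse = alpha_envelope(t, onset + if (term == 1) 0 else 3,
                           if (term == 1) 5 else 8) *
      sin(2 * pi * f * (t - onset) / 1000),
    oscillatory = alpha_envelope(t, onset, 15)^0.25 *
      (if (term == 1) sin(2 * pi * f * (t - onset) / 1000)
       else cos(2 * pi * spec$frequency * 1.5 * (t - onset) / 1000)) *
      as.numeric(t > onset),
    burst = exp(-pmax(t - onset, 0) / (if (term == 1) 8 else 12)) *
      sin(2 * pi * f * (t - onset) / 1000) * as.numeric(t > onset)
  )
  r <- sqrt(mean(x^2))
  if (r < 1e-12) stop("degenerate temporal course (all zero)")
  x / r
}

# Dipolar spatial patterns evaluated at source depths. A rank-1 population
# is a single sink/source dipole with lobes `dipole_extent` apart. A
# rank-2 population carries two stacked sink/source modes mimicking two
# synaptic pathways terminating on different dendritic domains: a distal
# mode occupying the upper half of the dipole extent and a proximal mode
# the lower half. Because the four lobes occupy distinct depth bands the
# two modes stay near-orthogonal even after the spatial smoothing inherent
# in CSD reconstruction, so they are simultaneously the population's
# principal axes and the spatially sparse directions a component analysis
# can recover - while the summed activity is a sum of two products, not a
# single one.
spatial_pattern <- function(spec, z, term) {
  lo <- spec$depth_range[1]; hi <- spec$depth_range[2]
  ctr <- (lo + hi) / 2
  ext <- spec$dipole_extent
  if (spec$rank == 1) {
    s <- ext / 5
    return(exp(-(z - ctr - ext / 2)^2 / (2 * s^2)) -
             exp(-(z - ctr + ext / 2)^2 / (2 * s^2)))
  }
  s <- ext / 14
  if (term == 1) {
    exp(-(z - ctr + ext / 6)^2 / (2 * s^2)) -
      exp(-(z - ctr + ext / 2)^2 / (2 * s^2))
  } else {
    exp(-(z - ctr - ext / 2)^2 / (2 * s^2)) -
      exp(-(z - ctr - ext / 6)^2 / (2 * s^2))
  }
}

#' Build the point sources of one population
#'
#' Places `n_sources` point sources uniformly at random in the population's
#' depth range within the column radius (keeping a small lateral clearance
#' from the electrode axis so point-source potentials stay finite), and
#' assigns each a current equal to a sum of `rank` spatial-weight x
#' temporal-course products. Each spatial weight is mean-subtracted over the
#' sources, so the population's net current is exactly zero at every time
#' sample. Deterministic given `seed`.
#'
#' @param spec a [population_spec()].
#' @param geometry a [column_geometry()].
#' @param seed integer seed.
#' @param dt sampling interval in ms.
#' @param duration record length in ms.
#' @param coupling target squared mixing weight of the shared drive
#'   (pairwise activation correlation between populations is approximately
#'   `coupling` at the optimal lag); 0 disables coupling.
#' @param amp_scale overall current scale in nA.
#' @param clearance_um minimum lateral distance from the column axis.
#' @return A [point_source_set()] with per-population conservation.
#' @export
build_population <- function(spec, geometry, seed, dt = 0.1, duration = 90,
                             coupling = 0.3, amp_scale = 100,
                             clearance_um = 30) {
  stopifnot(inherits(spec, "population_spec"),
            inherits(geometry, "column_geometry"))
  depth_max <- max(geometry$layers$bottom)
  if (spec$depth_range[1] < 0 || spec$depth_range[2] > depth_max) {
    stop(sprintf("population '%s' lies outside the modeled column (0-%g um)",
                 spec$name, depth_max))
  }
  n <- spec$n_sources
  nt <- round(duration / dt)
  t <- (seq_len(nt) - 1) * dt
  with_local_seed(seed, {
    z <- stats::runif(n, spec$depth_range[1], spec$depth_range[2])
    # uniform on the annulus [clearance, radius]
    rr <- sqrt(stats::runif(n, (clearance_um / geometry$radius)^2, 1)) *
      geometry$radius
    th <- stats::runif(n, 0, 2 * pi)
    pos <- cbind(rr * cos(th), rr * sin(th), z)

    drive <- shared_drive(t)
    drive <- drive / sqrt(mean(drive^2))
    lag_n <- round(spec$delay_ms / dt)
    drive_lag <- c(rep(0, lag_n), drive)[seq_len(nt)]

    gam <- sqrt(max(0, min(1, coupling)))
    courses <- matrix(0, spec$rank, nt)
    for (k in seq_len(spec$rank)) {
      b <- sqrt(1 - gam^2) * own_course(spec, t, k) + gam * drive_lag
      courses[k, ] <- b / sqrt(mean(b^2))
    }
    if (spec$rank == 2) {
      # orthogonalize the second course against the first so the two
      # product terms are genuinely distinct activation modes
      b2 <- courses[2, ] -
        sum(courses[2, ] * courses[1, ]) / sum(courses[1, ]^2) * courses[1, ]
      courses[2, ] <- b2 / sqrt(mean(b2^2))
    }

    currents <- matrix(0, n, nt)
    term_amp <- c(1, 0.5)
    for (k in seq_len(spec$rank)) {
      w <- spatial_pattern(spec, z, k)
      w <- w - mean(w)                      # exact current conservation
      nw <- sqrt(sum(w^2))
      if (nw < 1e-12) stop("degenerate spatial pattern")
      w <- w / nw
      currents <- currents +
        (spec$amplitude * term_amp[k] * amp_scale) * (w %o% courses[k, ])
    }
    point_source_set(pos, currents, dt,
                     groups = rep(spec$name, n), conserve = TRUE)
  })
}

#' Synthesize a multi-population ground-truth dataset
#'
#' Builds every population's sources, forward-models each population's LFP
#' (point-source potentials, then zero-phase Butterworth low-pass), and sums
#' them into the total LFP: the total equals the elementwise sum of the
#' per-population recordings exactly. Optionally adds white measurement
#' noise calibrated to the pooled standard deviation of the total LFP.
#'
#' @param specs list of [population_spec()]s (non-empty).
#' @param geometry a [column_geometry()].
#' @param array an [electrode_array()]; default 26 contacts, 50 um pitch.
#' @param sigma extracellular conductivity in S/m.
#' @param dt sampling interval in ms.
#' @param duration record length in ms.
#' @param seed integer seed; per-population seeds are derived from it.
#' @param noise_percent white-noise amplitude as percent of the pooled
#'   standard deviation of the clean total LFP.
#' @param coupling shared-drive coupling passed to [build_population()].
#' @param cutoff_hz LFP low-pass cutoff in Hz.
#' @return An object of class `ground_truth_dataset`: per-population source
#'   sets and recordings, the clean and (optionally) noisy total LFP, and
#'   the generating metadata.
#' @export
synthesize_dataset <- function(specs, geometry = column_geometry(),
                               array = laminar_array(), sigma = 0.3,
                               dt = 0.1, duration = 90, seed = 1,
                               noise_percent = 0, coupling = 0.3,
                               cutoff_hz = 500) {
  if (length(specs) == 0) stop("`specs` must be non-empty")
  if (inherits(specs, "population_spec")) specs <- list(specs)
  names(specs) <- vapply(specs, function(s) s$name, character(1))
  pops <- list()
  total <- NULL
  for (i in seq_along(specs)) {
    src <- build_population(specs[[i]], geometry,
                            seed = derive_seed(seed, i),
                            dt = dt, duration = duration, coupling = coupling)
    raw <- potential_from_points(src, array, sigma)
    lfp <- lowpass_lfp(raw, cutoff_hz = cutoff_hz)
    pops[[specs[[i]]$name]] <- list(spec = specs[[i]], sources = src,
                                    lfp = lfp)
    total <- if (is.null(total)) lfp$values else total + lfp$values
  }
  ds <- structure(
    list(populations = pops,
         lfp = potential_recording(array, total, sigma, dt),
         lfp_clean = potential_recording(array, total, sigma, dt),
         geometry = geometry, array = array, sigma = sigma, dt = dt,
         duration = duration, seed = seed, coupling = coupling,
         cutoff_hz = cutoff_hz, noise_percent = 0, noise_seed = NA_integer_),
    class = "ground_truth_dataset")
  if (noise_percent > 0) {
    ds <- add_noise(ds, noise_percent, seed = derive_seed(seed, 9999))
  }
  ds
}

#' Add calibrated white measurement noise
#'
#' Pools all values of the clean total LFP across contacts and time,
#' computes their standard deviation, and adds i.i.d. Gaussian noise with
#' standard deviation `level_percent`/100 of it, independently on every
#' electrode and sample. Ground-truth per-population recordings are left
#' noise-free; the clean total is kept alongside the noisy one.
#'
#' @param dataset a `ground_truth_dataset`.
#' @param level_percent noise level (>= 0) as percent of the pooled std.
#' @param seed integer seed for the noise draw.
#' @return The dataset with a noisy total LFP.
#' @export
add_noise <- function(dataset, level_percent, seed = 1) {
  stopifnot(inherits(dataset, "ground_truth_dataset"))
  if (!is.numeric(level_percent) || level_percent < 0) {
    stop("invalid parameter: `level_percent` must be >= 0")
  }
  if (level_percent == 0) return(dataset)
  clean <- dataset$lfp_clean$values
  pooled_sd <- stats::sd(as.vector(clean))
  noisy <- with_local_seed(seed, {
    clean + stats::rnorm(length(clean),
                         sd = pooled_sd * level_percent / 100)
  })
  dataset$lfp <- potential_recording(dataset$array,
                                     matrix(noisy, nrow(clean), ncol(clean)),
                                     dataset$sigma, dataset$dt)
  dataset$noise_percent <- level_percent
  dataset$noise_seed <- as.integer(seed)
  dataset
}

#' Translate one population in depth
#'
#' Shifts all of the named population's source depths by `shift` um
#' (positive = downward), leaving its currents unchanged — the population's
#' dynamics are untouched, only its location changes — and recomputes that
#' population's LFP and the totals. Any previously applied noise is
#' re-applied from the stored noise seed.
#'
#' @param dataset a `ground_truth_dataset`.
#' @param name population name.
#' @param shift depth translation in um.
#' @return A new `ground_truth_dataset`.
#' @export
shift_population <- function(dataset, name, shift) {
  stopifnot(inherits(dataset, "ground_truth_dataset"))
  if (!name %in% names(dataset$populations)) {
    stop(sprintf("unknown population '%s'", name))
  }
  stopifnot_scalar(shift, "shift")
  pop <- dataset$populations[[name]]
  z <- pop$sources$positions[, 3] + shift
  depth_max <- max(dataset$geometry$layers$bottom)
  if (min(z) < 0 || max(z) > depth_max) {
    stop(sprintf("shift pushes '%s' outside the modeled span (0-%g um)",
                 name, depth_max))
  }
  src <- pop$sources
  src$positions[, 3] <- z
  raw <- potential_from_points(src, dataset$array, dataset$sigma)
  lfp <- lowpass_lfp(raw, cutoff_hz = dataset$cutoff_hz)
  dataset$populations[[name]]$sources <- src
  dataset$populations[[name]]$lfp <- lfp
  total <- Reduce(`+`, lapply(dataset$populations, function(p) p$lfp$values))
  dataset$lfp_clean <- potential_recording(dataset$array, total,
                                           dataset$sigma, dataset$dt)
  dataset$lfp <- dataset$lfp_clean
  if (dataset$noise_percent > 0) {
    lvl <- dataset$noise_percent
    dataset$noise_percent <- 0
    dataset <- add_noise(dataset, lvl, seed = dataset$noise_seed)
  }
  dataset
}

#' Regular electrode subsampling
#'
#' Keeps `n` contacts at the regular stride spanning the largest extent a
#' regular subsampling allows (`floor((N-1)/(n-1))`), with the window
#' centered on the array when the stride does not reach the last contact.
#' `n = 2` keeps exactly the first and last contacts and `n = N` is the
#' identity; 13 of 26 keeps every second contact.
#'
#' @param recording a [potential_recording()].
#' @param n number of contacts to keep (2..N).
#' @return A subsampled [potential_recording()].
#' @export
subsample_electrodes <- function(recording, n) {
  stopifnot(inherits(recording, "potential_recording"))
  n_el <- length(recording$array$depths)
  if (!is.numeric(n) || n < 2 || n > n_el) {
    stop(sprintf("invalid parameter: `n` must be in 2..%d", n_el))
  }
  n <- as.integer(n)
  stride <- max(1L, (n_el - 1L) %/% (n - 1L))
  offset <- (n_el - 1L - (n - 1L) * stride) %/% 2L
  idx <- 1L + offset + (seq_len(n) - 1L) * stride
  arr <- electrode_array(recording$array$depths[idx],
                         lateral = recording$array$lateral)
  potential_recording(arr, recording$values[idx, , drop = FALSE],
                      recording$sigma, recording$dt)
}

#' Default three-population scenario
#'
#' The reference study condition of the package: two strong pyramidal-like
#' populations (a rank-2 layer 2/3 population whose currents occupy
#' 150-850 um, and a rank-2 layer 5 population at 450-1650 um — the arbor
#' reaches above the soma layer) plus one weak rank-1 layer 6 population at
#' 1150-2150 um, amplitude ratio 1 : 1 : 0.3, sampled by a 26-contact,
#' 50 um pitch laminar array for 90 ms at 0.1 ms resolution.
#'
#' @param duration record length in ms.
#' @param dt sampling interval in ms.
#' @param seed integer generator seed.
#' @return A list of class `lampop_scenario` with `specs`, `geometry`,
#'   `array`, `sigma`, `dt`, `duration`, `coupling`, `seed`.
#' @export
default_scenario <- function(duration = 90, dt = 0.1, seed = 1) {
  specs <- list(
    population_spec("L2/3", c(150, 850), n_sources = 120, rank = 2,
                    amplitude = 1, temporal = "pulse", frequency = 55,
                    delay_ms = 4, dipole_extent = 600),
    population_spec("L5", c(450, 1650), n_sources = 120, rank = 2,
                    amplitude = 1, temporal = "burst", frequency = 35,
                    delay_ms = 8, dipole_extent = 1000),
    population_spec("L6", c(1000, 2000), n_sources = 120, rank = 1,
                    amplitude = 0.3, temporal = "pulse", frequency = 25,
                    delay_ms = 12, dipole_extent = 500)
  )
  structure(list(specs = specs, geometry = column_geometry(),
                 array = laminar_array(), sigma = 0.3, dt = dt,
                 duration = duration, coupling = 0.3, seed = seed),
            class = "lampop_scenario")
}

#' Realize a scenario into a dataset
#'
#' @param scenario a `lampop_scenario`.
#' @param seed optional override of the scenario seed.
#' @param noise_percent white-noise level in percent of pooled std.
#' @return A `ground_truth_dataset`.
#' @export
realize_scenario <- function(scenario, seed = NULL, noise_percent = 0) {
  stopifnot(inherits(scenario, "lampop_scenario"))
  synthesize_dataset(scenario$specs, scenario$geometry, scenario$array,
                     sigma = scenario$sigma, dt = scenario$dt,
                     duration = scenario$duration,
                     seed = if (is.null(seed)) scenario$seed else seed,
                     noise_percent = noise_percent,
                     coupling = scenario$coupling)
}

#' @export
print.ground_truth_dataset <- function(x, ...) {
  cat(sprintf(
    "<ground_truth_dataset> %d populations, %d contacts x %d samples\n",
    length(x$populations), nrow(x$lfp$values), ncol(x$lfp$values)))
  cat(sprintf("  noise: %g%%, seed: %d\n", x$noise_percent, x$seed))
  invisible(x)
}

#' @export
print.lampop_scenario <- function(x, ...) {
  cat(sprintf("<lampop_scenario> %d populations, %g ms at %g ms\n",
              length(x$specs), x$duration, x$dt))
  invisible(x)
}
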