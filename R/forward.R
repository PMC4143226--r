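#' Point current sources
#'
#' Container for a set of point transmembrane current sources in a cortical
#' column. Positions are 3D coordinates in micrometres with depth (`z`)
#' measured positive downward from the cortical surface; currents are given
#' per source and time sample in nanoamperes.
#'
#' When `conserve = TRUE` the constructor checks that, within each labelled
#' group of sources (e.g. a cell population), the currents sum to zero at
#' every time sample. Physically, transmembrane currents of any closed set of
#' membranes must balance: what enters the extracellular medium somewhere
#' must leave it somewhere else.
#'
#' @param positions numeric matrix (sources x 3), columns `x`, `y`, `z` in um.
#' @param currents numeric matrix (sources x time samples) in nA.
#' @param dt sampling interval in ms.
#' @param groups optional character/factor vector of per-source group labels.
#' @param conserve logical; enforce per-group current conservation.
#' @return An object of class `point_source_set`.
#' @export
point_source_set <- function(positions, currents, dt, groups = NULL,
                             conserve = FALSE) {
  positions <- as.matrix(positions)
  currents <- as.matrix(currents)
  if (ncol(positions) != 3L) stop("`positions` must have 3 columns (x, y, z)")
  if (nrow(positions) != nrow(currents)) {
    stop("`positions` and `currents` disagree on the number of sources")
  }
  stopifnot_scalar(dt, "dt", positive = TRUE)
  if (!is.null(groups) && length(groups) != nrow(positions)) {
    stop("`groups` must have one label per source")
  }
  if (isTRUE(conserve)) {
    g <- if (is.null(groups)) rep("all", nrow(positions)) else as.character(groups)
    for (lab in unique(g)) {
      net <- colSums(currents[g == lab, , drop = FALSE])
      if (max(abs(net)) > 1e-8 * max(abs(currents), 1e-300)) {
        stop(sprintf("group '%s' violates current conservation", lab))
      }
    }
  }
  structure(
    list(positions = positions, currents = currents, dt = dt,
         groups = groups, conserve = isTRUE(conserve)),
    class = "point_source_set"
  )
}

#' Line current sources
#'
#' Each source is a straight segment carrying a uniformly distributed
#' current. Used for the line-source approximation of neurite segments.
#'
#' @param starts,ends numeric matrices (segments x 3), endpoints in um.
#' @param currents numeric matrix (segments x time samples) in nA.
#' @param dt sampling interval in ms.
#' @return An object of class `line_source_set`.
#' @export
line_source_set <- function(starts, ends, currents, dt) {
  starts <- as.matrix(starts); ends <- as.matrix(ends)
  currents <- as.matrix(currents)
  if (ncol(starts) != 3L || ncol(ends) != 3L) {
    stop("segment endpoints must have 3 columns")
  }
  if (nrow(starts) != nrow(ends) || nrow(starts) != nrow(currents)) {
    stop("endpoint and current matrices disagree on segment count")
  }
  len <- sqrt(rowSums((ends - starts)^2))
  if (any(len <= 0)) stop("every segment must have positive length")
  stopifnot_scalar(dt, "dt", positive = TRUE)
  structure(list(starts = starts, ends = ends, currents = currents, dt = dt),
            class = "line_source_set")
}

#' Laminar electrode array
#'
#' A vertical line of recording contacts. Depths are in micrometres below
#' the cortical surface and must be strictly increasing; `lateral` gives the
#' (x, y) position of the penetration in um.
#'
#' @param depths strictly increasing numeric vector of contact depths (um).
#' @param lateral length-2 numeric, lateral (x, y) offset of the line (um).
#' @return An object of class `electrode_array`.
#' @export
#' @examples
#' laminar_array()          # default 26 contacts, 50 um pitch from 150 um
#' electrode_array(seq(100, 1000, by = 100))
electrode_array <- function(depths, lateral = c(0, 0)) {
  depths <- as.numeric(depths)
  if (length(depths) < 1L || any(diff(depths) <= 0)) {
    stop("`depths` must be strictly increasing")
  }
  if (length(lateral) != 2L) stop("`lateral` must be length 2")
  structure(list(depths = depths, lateral = as.numeric(lateral)),
            class = "electrode_array")
}

#' @rdname electrode_array
#' @param n_contacts number of contacts.
#' @param pitch inter-contact spacing in um.
#' @param top depth of the most superficial contact in um.
#' @export
laminar_array <- function(n_contacts = 26, pitch = 50, top = 150,
                          lateral = c(0, 0)) {
  electrode_array(top + pitch * (seq_len(n_contacts) - 1), lateral = lateral)
}

#' Extracellular potential recording
#'
#' @param array an [electrode_array()].
#' @param values numeric matrix (contacts x time samples) in mV.
#' @param sigma extracellular conductivity in S/m.
#' @param dt sampling interval in ms.
#' @return An object of class `potential_recording`.
#' @export
potential_recording <- function(array, values, sigma, dt) {
  stopifnot(inherits(array, "electrode_array"))
  values <- as.matrix(values)
  if (nrow(values) != length(array$depths)) {
    stop("`values` must have one row per contact")
  }
  stopifnot_scalar(sigma, "sigma", positive = TRUE)
  stopifnot_scalar(dt, "dt", positive = TRUE)
  structure(list(array = array, values = values, sigma = sigma, dt = dt),
            class = "potential_recording")
}

contact_points <- function(array) {
  cbind(array$lateral[1], array$lateral[2], array$depths)
}

#' Extracellular potential from point sources
#'
#' Computes the potential at every contact of a laminar array generated by a
#' set of point current sources in an infinite homogeneous resistive medium:
#' each source of current \eqn{I_j} at distance \eqn{r_j} from a contact
#' contributes \eqn{I_j / (4 \pi \sigma r_j)}, and contributions superpose
#' linearly. With currents in nA, distances in um and conductivity in S/m
#' the result is in mV.
#'
#' @param sources a [point_source_set()].
#' @param array an [electrode_array()].
#' @param sigma extracellular conductivity in S/m.
#' @param min_distance smallest admissible source-contact distance in um;
#'   closer geometry is rejected as degenerate (the point-source potential
#'   diverges at the source).
#' @return A [potential_recording()].
#' @export
potential_from_points <- function(sources, array, sigma, min_distance = 1e-6) {
  stopifnot(inherits(sources, "point_source_set"),
            inherits(array, "electrode_array"))
  stopifnot_scalar(sigma, "sigma", positive = TRUE)
  pts <- contact_points(array)
  # distance matrix: contacts x sources
  d2 <- outer(pts[, 1], sources$positions[, 1], "-")^2 +
    outer(pts[, 2], sources$positions[, 2], "-")^2 +
    outer(pts[, 3], sources$positions[, 3], "-")^2
  dist <- sqrt(d2)
  if (any(dist < min_distance)) {
    stop("degenerate geometry: a source coincides with a contact")
  }
  v <- (1 / (4 * pi * sigma)) * ((1 / dist) %*% sources$currents)
  potential_recording(array, v, sigma, sources$dt)
}

#' Extracellular potential from line sources
#'
#' Closed-form potential of segments carrying uniformly distributed current,
#' summed over segments. For a segment of length \eqn{\Delta s} the on- and
#' off-axis potential follows from integrating the point-source kernel along
#' the segment, giving an inverse hyperbolic sine expression in the
#' longitudinal and radial distances.
#'
#' @inheritParams potential_from_points
#' @param sources a [line_source_set()].
#' @return A [potential_recording()].
#' @export
potential_from_lines <- function(sources, array, sigma, min_distance = 1e-6) {
  stopifnot(inherits(sources, "line_source_set"),
            inherits(array, "electrode_array"))
  stopifnot_scalar(sigma, "sigma", positive = TRUE)
  pts <- contact_points(array)
  n_seg <- nrow(sources$starts)
  n_el <- nrow(pts)
  w <- matrix(0, n_el, n_seg)
  for (j in seq_len(n_seg)) {
    a <- sources$starts[j, ]; b <- sources$ends[j, ]
    ds <- sqrt(sum((b - a)^2))
    u <- (b - a) / ds
    rel <- sweep(pts, 2, a)
    t_long <- as.vector(rel %*% u)                  # along-axis coordinate
    r_perp2 <- pmax(rowSums(rel^2) - t_long^2, 0)
    r_perp <- sqrt(r_perp2)
    on_line <- r_perp < min_distance
    inside <- on_line & t_long > -min_distance & t_long < ds + min_distance
    if (any(inside)) {
      stop("degenerate geometry: a contact lies on a line source")
    }
    val <- numeric(n_el)
    off <- !on_line
    val[off] <- asinh(t_long[off] / r_perp[off]) -
      asinh((t_long[off] - ds) / r_perp[off])
    # collinear but outside the segment: limit r -> 0 of the expression
    col_out <- on_line & !inside
    if (any(col_out)) {
      tt <- t_long[col_out]
      val[col_out] <- log(abs(tt / (tt - ds)))
    }
    w[, j] <- val / (4 * pi * sigma * ds)
  }
  v <- w %*% sources$currents
  potential_recording(array, v, sigma, sources$dt)
}

#' Low-pass filter a recording to the LFP band
#'
#' Applies a second-order Butterworth low-pass filter along time, forward and
#' backward (zero phase). The local field potential is conventionally the
#' sub-500 Hz band of the extracellular potential. Zero-phase application
#' squares the magnitude response, so the gain at the cutoff frequency is
#' 0.5 rather than the single-pass half-power 1/sqrt(2); DC gain is 1.
#'
#' @param recording a [potential_recording()].
#' @param cutoff_hz cutoff frequency in Hz; must be below Nyquist.
#' @param order filter order of a single pass.
#' @return A filtered [potential_recording()].
#' @export
lowpass_lfp <- function(recording, cutoff_hz = 500, order = 2) {
  stopifnot(inherits(recording, "potential_recording"))
  stopifnot_scalar(cutoff_hz, "cutoff_hz", positive = TRUE)
  fs <- 1000 / recording$dt     # Hz
  nyquist <- fs / 2
  if (cutoff_hz >= nyquist) {
    stop(sprintf("invalid cutoff: %g Hz is not below Nyquist (%g Hz)",
                 cutoff_hz, nyquist))
  }
  bw <- signal::butter(order, cutoff_hz / nyquist, type = "low")
  out <- t(apply(recording$values, 1, function(x) zp_filter(bw, x)))
  potential_recording(recording$array, out, recording$sigma, recording$dt)
}

# Forward-backward filtering with odd-reflection padding at both ends and
# steady-state initial conditions, so start-up transients decay inside the
# padding rather than inside the data (DC passes exactly).
zp_filter <- function(bw, x) {
  n <- length(x)
  pad <- min(n - 1L, 1000L)
  ord <- length(bw$a) - 1L
  one_pass <- function(v) {
    signal::filter(bw$b, bw$a, v,
                   init.x = rep(v[1], ord), init.y = rep(v[1], ord))
  }
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- one_pass(ext)
  y <- rev(one_pass(rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Coarse-grained current source density of point sources
#'
#' Smooths a cloud of point currents into a density on a 1D depth grid with
#' a normalized Gaussian kernel (a running average over depth). This is the
#' natural physiologically meaningful reference representation of sparse
#' simulated sources: the kernel width sets the spatial scale at which the
#' net current per unit depth is resolved. The depth integral of the map
#' approximates the total current at each time sample.
#'
#' @param sources a [point_source_set()].
#' @param grid numeric vector of evaluation depths in um.
#' @param sigma_kernel Gaussian kernel width in um (default 80).
#' @return A [csd_estimate()] with values in nA/um.
#' @export
coarse_grain_csd <- function(sources, grid, sigma_kernel = 80) {
  stopifnot(inherits(sources, "point_source_set"))
  stopifnot_scalar(sigma_kernel, "sigma_kernel", positive = TRUE)
  grid <- as.numeric(grid)
  if (nrow(sources$positions) == 0L) {
    warning("empty source set: returning a zero map")
    return(csd_estimate(grid, matrix(0, length(grid), ncol(sources$currents)),
                        lambda = NA_real_, dt = sources$dt))
  }
  d <- outer(grid, sources$positions[, 3], "-")
  k <- exp(-d^2 / (2 * sigma_kernel^2)) / (sqrt(2 * pi) * sigma_kernel)
  csd_estimate(grid, k %*% sources$currents, lambda = NA_real_,
               dt = sources$dt)
}

#' @export
print.point_source_set <- function(x, ...) {
  cat(sprintf("<point_source_set> %d sources x %d samples (dt %g ms)\n",
              nrow(x$positions), ncol(x$currents), x$dt))
  if (!is.null(x$groups)) {
    cat("  groups:", paste(unique(x$groups), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.electrode_array <- function(x, ...) {
  cat(sprintf("<electrode_array> %d contacts, %g-%g um\n",
              length(x$depths), min(x$depths), max(x$depths)))
  invisible(x)
}

#' @export
print.potential_recording <- function(x, ...) {
  cat(sprintf(
    "<potential_recording> %d contacts x %d samples (dt %g ms, sigma %g S/m)\n",
    nrow(x$values), ncol(x$values), x$dt, x$sigma))
  invisible(x)
}
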